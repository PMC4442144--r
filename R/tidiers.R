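# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname coordination_test
#' @param x A result object.
#' @param ... Unused.
#' @method tidy coordination_test
#' @export
tidy.coordination_test <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname coordination_test
#' @method glance coordination_test
#' @export
glance.coordination_test <- function(x, ...) {
  tibble(n_combinations = nrow(x),
         n_flagged = sum(x$flagged),
         n_low_power = sum(x$low_power),
         alpha = attr(x, "alpha"),
         total = attr(x, "total"))
}

#' @rdname replicate_correlation
#' @param x A result object.
#' @param ... Unused.
#' @method tidy replicate_cor
#' @export
tidy.replicate_cor <- function(x, ...) {
  tibble(estimate = x$r, p.value = x$p, n = x$n,
         method = "Pearson on log(count + pseudo), Fisher z")
}

#' @rdname replicate_correlation
#' @method glance replicate_cor
#' @export
glance.replicate_cor <- function(x, ...) tidy(x)

#' @rdname count_isoforms
#' @param x A result object.
#' @param ... Unused.
#' @method glance count_table
#' @export
glance.count_table <- function(x, ...) {
  tot <- attr(x, "status_totals")
  tidyr::pivot_wider(tot, names_from = "status", values_from = "n") %>%
    mutate(n_isoforms = nrow(x), total_reads = sum(tot$n))
}

#' @rdname switch_report
#' @param x A result object.
#' @param ... Unused.
#' @method glance switch_report
#' @export
glance.switch_report <- function(x, ...) {
  tibble(applicable = attr(x, "applicable"),
         n_switched = attr(x, "n_switched"),
         n_total = attr(x, "n_total"),
         fraction = attr(x, "fraction"))
}

#' @rdname compression_stats
#' @param x A result object.
#' @param ... Unused.
#' @method glance compression_stats
#' @export
glance.compression_stats <- function(x, ...) attr(x, "summary")
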