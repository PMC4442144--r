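# Exon-usage and coordination statistics: marginal variant frequencies per
# cluster, expected combination frequencies under independence, exact
# binomial observed-vs-expected tests with Benjamini-Hochberg correction,
# and replicate correlation.

#' Marginal exon (variant) frequencies per cluster
#'
#' The fraction of assigned reads containing each variant, per variant
#' region; fractions within a cluster sum to 1.
#'
#' @param counts A `count_table` (or tibble with `isoform_key`, `count`).
#' @param gm The [gene_model()] whose variant regions name the clusters.
#' @return A tibble of class `marginal_freqs` (`cluster_id`, `variant_id`,
#'   `count`, `freq`).
#' @export
marginal_exon_freq <- function(counts, gm) {
  if (nrow(counts) == 0 || sum(counts$count) == 0)
    abort("count table is empty", class = "ligzip_error_stats")
  vr_ids <- variant_regions(gm)$region_id
  parts <- strsplit(counts$isoform_key, "|", fixed = TRUE)
  if (any(lengths(parts) != length(vr_ids)))
    abort("isoform keys do not match the model's variant regions",
          class = "ligzip_error_stats")
  total <- sum(counts$count)
  out <- purrr::map(seq_along(vr_ids), function(j) {
    tibble(cluster_id = vr_ids[j],
           variant_id = vapply(parts, `[[`, character(1), j),
           count = counts$count) %>%
      dplyr::group_by(.data$cluster_id, .data$variant_id) %>%
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }) %>% dplyr::bind_rows() %>%
    mutate(freq = .data$count / total)
  structure(out, total = total,
            class = c("marginal_freqs", class(out)))
}

#' Expected combination frequencies under independence
#'
#' The expected frequency of each combination of variants across the chosen
#' clusters is the product of the individual variant-use fractions; the
#' complete set sums to 1. Comparing these expectations to observed
#' combination counts tests whether splicing choices in different clusters
#' are coordinated.
#'
#' @param marginals A `marginal_freqs` tibble.
#' @param clusters Character vector of cluster ids to combine (two for a
#'   pairwise expectation, three for a three-way one, ...).
#' @return A tibble (`combination_key`, `expected_freq`), combinations in
#'   cluster order joined with `|`.
#' @export
expected_combinations <- function(marginals, clusters) {
  ms <- lapply(clusters, function(cl) {
    m <- dplyr::filter(marginals, .data$cluster_id == cl)
    if (nrow(m) == 0)
      abort(paste0("cluster ", cl, " not present in marginals"),
            class = "ligzip_error_stats")
    stats::setNames(m$freq, m$variant_id)
  })
  grid <- expand.grid(rev(lapply(ms, names)), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  keys <- do.call(paste, c(rev(grid), sep = "|"))
  freq <- Reduce(`*`, lapply(seq_along(ms), function(j)
    ms[[j]][rev(grid)[[j]]]))
  tibble(combination_key = keys, expected_freq = unname(freq)) %>%
    dplyr::arrange(.data$combination_key)
}

#' Observed combination counts from a count table
#'
#' Projects isoform keys onto the chosen clusters and sums counts.
#'
#' @inheritParams marginal_exon_freq
#' @param clusters Cluster ids to project onto.
#' @return A tibble (`combination_key`, `count`).
#' @export
observed_combinations <- function(counts, gm, clusters) {
  vr_ids <- variant_regions(gm)$region_id
  j <- match(clusters, vr_ids)
  if (anyNA(j))
    abort("unknown cluster id", class = "ligzip_error_stats")
  parts <- strsplit(counts$isoform_key, "|", fixed = TRUE)
  proj <- vapply(parts, function(p) paste(p[j], collapse = "|"), character(1))
  tibble(combination_key = proj, count = counts$count) %>%
    dplyr::group_by(.data$combination_key) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop") %>%
    dplyr::arrange(.data$combination_key)
}

#' Test observed exon combinations against independence expectations
#'
#' Per combination, a two-sided exact binomial test of the observed count
#' against the expected frequency at `n = total`, with Benjamini-Hochberg
#' q-values; combinations with `q <= alpha` are flagged as deviating from
#' the no-coordination null. Combinations with expected count below 1 are
#' annotated `low_power`.
#'
#' @param observed Tibble (`combination_key`, `count`); combinations absent
#'   from it but present in `expected` are tested at count 0.
#' @param expected Tibble (`combination_key`, `expected_freq`) from
#'   [expected_combinations()].
#' @param total Total assigned reads; defaults to `sum(observed$count)`.
#' @param alpha Flagging threshold on the q-value.
#' @return A tibble of class `coordination_test`: `combination_key`,
#'   `observed`, `expected_freq`, `expected_count`, `p`, `q`, `flagged`,
#'   `low_power`.
#' @export
coordination_test <- function(observed, expected, total = NULL, alpha = 0.05) {
  if (is.null(total)) total <- sum(observed$count)
  if (total == 0)
    abort("total observed count is zero", class = "ligzip_error_stats")
  if (!all(observed$combination_key %in% expected$combination_key))
    abort("observed keys must be a subset of expected keys",
          class = "ligzip_error_stats")
  tab <- expected %>%
    left_join(observed, by = "combination_key") %>%
    mutate(count = dplyr::coalesce(.data$count, 0L))
  p <- vapply(seq_len(nrow(tab)), function(i) {
    pr <- min(max(tab$expected_freq[i], 0), 1)
    if (pr == 0) return(as.numeric(tab$count[i] == 0))
    stats::binom.test(tab$count[i], total, pr,
                      alternative = "two.sided")$p.value
  }, numeric(1))
  out <- tibble(
    combination_key = tab$combination_key,
    observed = tab$count,
    expected_freq = tab$expected_freq,
    expected_count = tab$expected_freq * total,
    p = pmin(p, 1),
    q = stats::p.adjust(pmin(p, 1), method = "BH")
  ) %>%
    mutate(flagged = .data$q <= alpha,
           low_power = .data$expected_count < 1)
  structure(out, alpha = alpha, total = total,
            method = "exact binomial vs independence expectation, BH-corrected",
            class = c("coordination_test", class(out)))
}

#' Correlation of isoform abundances between replicates
#'
#' Pearson correlation of log-transformed pseudocounted abundances over the
#' union of isoform keys, with significance from the Fisher
#' z-transformation.
#'
#' @param table_a,table_b `count_table`s (or tibbles with `isoform_key`,
#'   `count`).
#' @param pseudo_count Added to every count before the log transform.
#' @return An object of class `replicate_cor` with elements `r`, `p`, `n`;
#'   see [tidy()].
#' @export
replicate_correlation <- function(table_a, table_b, pseudo_count = 1) {
  keys <- union(table_a$isoform_key, table_b$isoform_key)
  if (length(intersect(table_a$isoform_key, table_b$isoform_key)) < 4)
    abort("fewer than 4 shared isoform keys", class = "ligzip_error_stats")
  a <- stats::setNames(rep(0, length(keys)), keys)
  b <- a
  a[table_a$isoform_key] <- table_a$count
  b[table_b$isoform_key] <- table_b$count
  r <- stats::cor(log(a + pseudo_count), log(b + pseudo_count))
  n <- length(keys)
  z <- atanh(min(max(r, -1), 1))
  p <- 2 * stats::pnorm(-abs(z) * sqrt(n - 3))
  p <- max(p, .Machine$double.xmin) # keep p in (0, 1]
  structure(list(r = r, p = p, n = n, pseudo_count = pseudo_count),
            class = "replicate_cor")
}

#' @export
print.replicate_cor <- function(x, ...) {
  cat(sprintf("<replicate_cor> r = %.4f, p = %.3g (Fisher z), n = %d isoforms\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Write a coordination test table as TSV
#'
#' The header records that expectations are deterministic products of
#' marginal exon use and the test is an exact binomial with BH correction.
#'
#' @param test A `coordination_test`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coordination_tsv <- function(test, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", attr(test, "method"), "; alpha = ",
                    attr(test, "alpha"), "; total = ", attr(test, "total")),
             con)
  utils::write.table(as.data.frame(test), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
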