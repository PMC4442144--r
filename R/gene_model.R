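# Gene models: an ordered set of transcript regions, each constitutive or
# variant (mutually exclusive cassette cluster, or alternative 3' splice
# site option set, possibly including a skip outcome).

#' Construct a gene model
#'
#' A gene model is an ordered (5'->3') tibble of transcript regions. Each
#' region is constitutive (a single sequence) or variant: a mutually
#' exclusive cassette cluster, or an alternative 3' splice-site region whose
#' outcomes may include a skip (empty sequence). Exactly one outcome per
#' variant region appears in each isoform.
#'
#' @param gene_id Gene identifier.
#' @param regions A list; each element a list with `id`, `type` (one of
#'   `"constitutive"`, `"cassette"`, `"alt3ss"`), and either `sequence`
#'   (constitutive) or `variants` (a named character vector of variant-id ->
#'   sequence; an empty string encodes the skip outcome). U is normalized
#'   to T; sequences are upper-cased.
#' @return A tibble of class `gene_model` with columns `region_id`, `type`,
#'   `variants` (list of named character vectors) and attribute `gene_id`.
#' @export
#' @examples
#' gm <- gene_model("toy", list(
#'   list(id = "L", type = "constitutive", sequence = "ACGTACGTACGTACGTACGT"),
#'   list(id = "x", type = "cassette",
#'        variants = c(x.1 = "GGGGCCCCGGGGCCCC", x.2 = "AAAATTTTAAAATTTT")),
#'   list(id = "R", type = "constitutive", sequence = "TTTTGGGGCCCCAAAA")))
#' enumerate_isoforms(gm)
gene_model <- function(gene_id, regions) {
  stopifnot(is.character(gene_id), length(gene_id) == 1, length(regions) >= 1)
  rows <- purrr::map(regions, function(r) {
    if (is.null(r$id) || is.null(r$type))
      abort("each region needs `id` and `type`", class = "ligzip_error_model")
    if (!r$type %in% c("constitutive", "cassette", "alt3ss"))
      abort(paste0("unknown region type: ", r$type), class = "ligzip_error_model")
    v <- if (r$type == "constitutive") {
      stats::setNames(as.character(r$sequence), r$id)
    } else {
      if (is.null(r$variants) || length(r$variants) == 0)
        abort(paste0("variant region ", r$id, " has no variants"),
              class = "ligzip_error_model")
      r$variants
    }
    if (is.null(names(v)) || any(!nzchar(names(v))))
      abort(paste0("variants of region ", r$id, " must be named"),
            class = "ligzip_error_model")
    v <- stats::setNames(normalize_seq(v), names(v))
    tibble(region_id = r$id, type = r$type, variants = list(v))
  })
  gm <- dplyr::bind_rows(rows)
  if (anyDuplicated(gm$region_id))
    abort("region ids must be unique", class = "ligzip_error_model")
  all_ids <- unlist(lapply(gm$variants, names))
  if (anyDuplicated(all_ids))
    abort("variant ids must be unique across the model", class = "ligzip_error_model")
  structure(gm, gene_id = gene_id, class = c("gene_model", class(gm)))
}

normalize_seq <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x) & nzchar(x)
  if (any(bad))
    abort("sequences must be over ACGT/ACGU", class = "ligzip_error_model")
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", attr(x, "gene_id"), ": ", nrow(x), " regions, ",
      sum(x$type != "constitutive"), " variant\n", sep = "")
  NextMethod()
}

gene_id <- function(gm) attr(gm, "gene_id")

# variant regions in 5'->3' order
variant_regions <- function(gm) gm[gm$type != "constitutive", , drop = FALSE]

# the chosen sequence of region `rid` given variant id `vid`
region_variant_seq <- function(gm, rid, vid) {
  v <- gm$variants[[match(rid, gm$region_id)]]
  unname(v[[vid]])
}

#' Read / write gene models as JSON
#'
#' The JSON schema is a `gene_id` string plus a `regions` array; each region
#' has `id`, `type` and either `sequence` or a `variants` object mapping
#' variant ids to sequences.
#'
#' @param path File path.
#' @return `read_gene_model()` returns a `gene_model`; `write_gene_model()`
#'   returns `path` invisibly.
#' @export
read_gene_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  regions <- purrr::map(j$regions, function(r) {
    if (!is.null(r$variants)) r$variants <- unlist(r$variants)
    r
  })
  gene_model(j$gene_id, regions)
}

#' @rdname read_gene_model
#' @param gm A `gene_model`.
#' @export
write_gene_model <- function(gm, path) {
  regions <- purrr::pmap(gm, function(region_id, type, variants) {
    if (type == "constitutive")
      list(id = region_id, type = type, sequence = unname(variants[[1]]))
    else list(id = region_id, type = type, variants = as.list(variants))
  })
  jsonlite::write_json(list(gene_id = gene_id(gm), regions = regions), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
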