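# Isoform enumeration and the expected ligation-product index: one valid
# 5'->3' ligamer chain per isoform, plus compression statistics.

#' Enumerate the isoforms of a gene model
#'
#' One isoform key per combination of variant choices: exactly one outcome
#' per variant region (a skip outcome counts as one), joined 5'->3' with
#' `|`. Keys are returned lexicographically sorted (byte order).
#'
#' @param gm A [gene_model()].
#' @param exclude Character vector of variant ids to leave out of the
#'   isoform space (e.g. a pseudo-exon known never to be used). The pool may
#'   still target such variants; exclusion only shrinks the enumerated
#'   space.
#' @return Character vector of isoform keys.
#' @export
#' @examples
#' # four clusters of 12, 48, 33 and 2 mutually exclusive exons
#' # combine to 12 * 48 * 33 * 2 = 38016 isoforms
enumerate_isoforms <- function(gm, exclude = NULL) {
  stopifnot(inherits(gm, "gene_model"))
  vr <- variant_regions(gm)
  if (nrow(vr) == 0) return("") # single constitutive isoform
  choice_sets <- purrr::map(vr$variants, function(v) {
    ids <- setdiff(names(v), exclude)
    if (length(ids) == 0)
      abort("a variant region has zero remaining variants", class = "ligzip_error_model")
    ids
  })
  grid <- expand.grid(rev(choice_sets), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  keys <- do.call(paste, c(rev(grid), sep = "|"))
  sort(keys, method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# chosen variant id per variant region for one isoform key
key_choices <- function(gm, key) {
  vr <- variant_regions(gm)
  if (nrow(vr) == 0)
    return(stats::setNames(character(0), character(0)))
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  if (length(parts) != nrow(vr))
    abort(paste0("isoform key ", key, " does not match the model's ",
                 nrow(vr), " variant regions"), class = "ligzip_error_model")
  stats::setNames(parts, vr$region_id)
}

#' Spliced sequence of one isoform
#'
#' @param gm A [gene_model()].
#' @param key An isoform key from [enumerate_isoforms()].
#' @return The isoform's mRNA sequence (DNA alphabet).
#' @export
isoform_sequence <- function(gm, key) {
  choices <- key_choices(gm, key)
  paste(vapply(seq_len(nrow(gm)), function(i) {
    v <- gm$variants[[i]]
    if (gm$type[i] == "constitutive") v[[1]]
    else {
      vid <- choices[[gm$region_id[i]]]
      if (!vid %in% names(v))
        abort(paste0("unknown variant ", vid, " in region ", gm$region_id[i]),
              class = "ligzip_error_model")
      v[[vid]]
    }
  }, character(1)), collapse = "")
}

# region offsets within one isoform; returns tibble(region_id, offset, len)
isoform_layout <- function(gm, choices) {
  lens <- vapply(seq_len(nrow(gm)), function(i) {
    v <- gm$variants[[i]]
    if (gm$type[i] == "constitutive") nchar(v[[1]])
    else nchar(v[[choices[[gm$region_id[i]]]]])
  }, integer(1))
  tibble(region_id = gm$region_id,
         offset = cumsum(c(0L, lens[-length(lens)])),
         len = lens)
}

#' Build the expected ligation-product index
#'
#' For every isoform of the model, assembles the unique valid 5'->3' chain
#' of pool ligamers (terminals, interior constitutive ligamers, and the
#' chosen variant's ligamer per variant region; a skip outcome contributes
#' no ligamer, making its neighbors adjacent), verifies that successive
#' hybridization footprints abut on that isoform, and concatenates the
#' ligamer sequences into the expected product.
#'
#' @param gm A [gene_model()].
#' @param pool A `ligamer_pool` from [plan_pool()], or any ligamer tibble
#'   whose `targets` footprints tile the model.
#' @param exclude Variant ids excluded from the isoform space (see
#'   [enumerate_isoforms()]).
#' @return A tibble of class `product_index`: `isoform_key`,
#'   `ligamer_chain` (list of ligamer ids), `product_sequence`,
#'   `product_length`, `rna_span` (first to last hybridized base, primer
#'   tails excluded), `fold_compression`, `pool_label`.
#' @export
build_product_index <- function(gm, pool, exclude = NULL) {
  stopifnot(inherits(gm, "gene_model"))
  keys <- enumerate_isoforms(gm, exclude = exclude)
  vr_ids <- variant_regions(gm)$region_id
  nreg <- nrow(gm)
  reg_index <- stats::setNames(seq_len(nreg), gm$region_id)
  # region length per choice: constitutive lengths fixed, variant looked up
  const_len <- vapply(seq_len(nreg), function(i)
    if (gm$type[i] == "constitutive") nchar(gm$variants[[i]][[1]]) else NA_integer_,
    integer(1))
  var_len <- lapply(seq_len(nreg), function(i)
    if (gm$type[i] == "constitutive") NULL else nchar(gm$variants[[i]]))

  # per-ligamer footprint info as plain vectors (local coordinates)
  nl <- nrow(pool)
  lg_region_i <- reg_index[pool$region_id]
  lg_variant <- pool$variant_id
  lg_seq <- pool$sequence
  lg_id <- pool$ligamer_id
  lg_up_start <- lg_down_end <- lg_first <- lg_last <- integer(nl)
  for (i in seq_len(nl)) {
    tg <- pool$targets[[i]]
    up <- match("up", tg$arm); dn <- match("down", tg$arm)
    lg_up_start[i] <- tg$start[up]
    lg_down_end[i] <- if (is.na(dn)) tg$end[up] else tg$end[dn]
    lg_first[i] <- min(tg$start)
    lg_last[i] <- max(tg$end)
  }
  always <- which(is.na(lg_variant))
  # variant id -> ligamer row, per region
  vmap <- lapply(seq_len(nreg), function(ri) {
    rows <- which(lg_region_i == ri & !is.na(lg_variant))
    stats::setNames(rows, lg_variant[rows])
  })

  nk <- length(keys)
  parts <- strsplit(keys, "|", fixed = TRUE)
  chains <- vector("list", nk)
  prods <- character(nk)
  spans <- integer(nk)
  vr_reg_i <- reg_index[vr_ids]
  for (ki in seq_len(nk)) {
    choice <- parts[[ki]]
    lens <- const_len
    for (j in seq_along(vr_reg_i))
      lens[vr_reg_i[j]] <- var_len[[vr_reg_i[j]]][[choice[j]]]
    off <- cumsum(c(0L, lens[-nreg]))
    sel <- always
    for (j in seq_along(vr_reg_i)) {
      li <- vmap[[vr_reg_i[j]]][choice[j]]
      if (!is.na(li)) sel <- c(sel, li)
    }
    o <- off[lg_region_i[sel]]
    ord <- order(o + lg_first[sel])
    sel <- sel[ord]; o <- o[ord]
    up_start <- o + lg_up_start[sel]
    down_end <- o + lg_down_end[sel]
    ns <- length(sel)
    if (ns > 1 && any(up_start[-1] != down_end[-ns])) {
      bad <- which(up_start[-1] != down_end[-ns])[1]
      abort(paste0("isoform ", keys[ki], " has a ligation gap between ",
                   lg_id[sel[bad]], " and ", lg_id[sel[bad + 1]]),
            class = "ligzip_error_index")
    }
    chains[[ki]] <- lg_id[sel]
    prods[ki] <- paste(lg_seq[sel], collapse = "")
    spans[ki] <- (o[ns] + lg_last[sel[ns]]) - (o[1] + lg_first[sel[1]])
  }
  out <- tibble(isoform_key = keys, ligamer_chain = chains,
                product_sequence = prods,
                product_length = nchar(prods),
                rna_span = spans,
                fold_compression = spans / nchar(prods))
  out$pool_label <- pool$pool_label[1]
  if (anyDuplicated(out$product_sequence))
    warn("product sequences are not pairwise distinct; give every variant ligamer a unique barcode")
  structure(out, gene_id = gene_id(gm),
            class = c("product_index", class(out)))
}

#' Compression statistics of a product index
#'
#' Fold compression is the covered RNA span divided by the ligation-product
#' length; a ligamer set that loops out long stretches of RNA compresses
#' the connectivity information severalfold.
#'
#' @param index A `product_index`.
#' @return The per-record tibble (`isoform_key`, `rna_span`,
#'   `product_length`, `fold_compression`, `no_compression`) of class
#'   `compression_stats`; [glance()] returns the summary medians.
#' @export
compression_stats <- function(index) {
  if (nrow(index) == 0)
    abort("empty index", class = "ligzip_error_index")
  out <- tibble(
    isoform_key = index$isoform_key,
    rna_span = index$rna_span,
    product_length = index$product_length,
    fold_compression = index$fold_compression,
    no_compression = index$fold_compression <= 1.1
  )
  structure(out,
            summary = tibble(
              median_rna_span = stats::median(out$rna_span),
              median_product_length = stats::median(out$product_length),
              median_fold_compression = stats::median(out$fold_compression)),
            class = c("compression_stats", class(out)))
}

#' Write / read a product index as FASTA
#'
#' Headers follow the fixed format `gene|isoform_key|ligamer1,ligamer2,...`.
#'
#' @param index A `product_index`.
#' @param path File path.
#' @return `write_product_fasta()` returns `path` invisibly;
#'   `read_product_fasta()` returns a tibble with `isoform_key`,
#'   `ligamer_chain`, `product_sequence`, `product_length`.
#' @export
write_product_fasta <- function(index, path) {
  gene <- attr(index, "gene_id") %||% "gene"
  headers <- paste0(gene, "|", index$isoform_key, "|",
                    vapply(index$ligamer_chain, paste, character(1),
                           collapse = ","))
  x <- Biostrings::DNAStringSet(stats::setNames(index$product_sequence, headers))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_product_fasta
#' @export
read_product_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # header: gene|isoform_key|chain -- the key itself may contain '|', the
  # chain never does, so split off the first and last fields
  parts <- strsplit(names(x), "|", fixed = TRUE)
  seqs <- unname(as.character(x))
  tibble(
    isoform_key = vapply(parts, function(p)
      paste(p[seq(2, length(p) - 1)], collapse = "|"), character(1)),
    ligamer_chain = purrr::map(parts, function(p)
      strsplit(p[[length(p)]], ",", fixed = TRUE)[[1]]),
    product_sequence = seqs,
    product_length = nchar(seqs)
  )
}
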