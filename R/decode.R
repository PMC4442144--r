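# Decoding: merge mate pairs, anchor barcodes, infer ligamer chains,
# verify arms, and tally isoform counts plus artifact statuses.

#' Merge paired-end mates by 3' overlap
#'
#' Read 2 is reverse-complemented into read 1 orientation and the overlap
#' length maximizing the number of matching bases is chosen, subject to a
#' minimum overlap and a maximum mismatch fraction; overlap bases are
#' resolved in favor of read 1. Pairs with no qualifying overlap are
#' returned with `merged = FALSE` and are later counted as unassigned --
#' the loss is explicit, not silent.
#'
#' @param reads Tibble with columns `read_id`, `r1`, `r2` (as from
#'   [simulate_reads()] or [read_fastq_pair()]).
#' @param min_overlap Minimum acceptable overlap (nt).
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap.
#' @return A tibble (`read_id`, `sequence`, `overlap_len`,
#'   `n_overlap_mismatches`, `merged`, plus list columns `overlap_mm_pos` /
#'   `overlap_mm_alt` recording where the mates disagreed and read 2's
#'   base there, so verification can weigh both observations).
#' @export
merge_pairs <- function(reads, min_overlap = 10, max_mismatch_frac = 0.1) {
  stopifnot(all(c("read_id", "r1", "r2") %in% names(reads)))
  if (any(!nzchar(reads$r1)) || any(!nzchar(reads$r2)))
    abort("empty mate sequence", class = "ligzip_error_decode")
  res <- merge_overlap_cpp(reads$r1, reverse_complement(reads$r2),
                           as.integer(min_overlap), max_mismatch_frac)
  tibble(read_id = reads$read_id,
         sequence = as.character(res$merged),
         overlap_len = res$overlap_len,
         n_overlap_mismatches = res$n_overlap_mismatches,
         merged = res$ok,
         overlap_mm_pos = res$mm_pos,
         overlap_mm_alt = res$mm_alt)
}

#' Barcode map of one or more pools
#'
#' @param pools A `ligamer_pool` or list of pools.
#' @return Tibble (`barcode`, `ligamer_id`, `pool_label`).
#' @export
barcode_map <- function(pools) {
  if (inherits(pools, "ligamer_pool")) pools <- list(pools)
  out <- dplyr::bind_rows(lapply(pools, function(p)
    dplyr::filter(p, !is.na(.data$barcode))[, c("barcode", "ligamer_id", "pool_label")]))
  if (anyDuplicated(out$barcode))
    abort("barcodes must be unique across pools for unambiguous anchoring",
          class = "ligzip_error_decode")
  out
}

#' @rdname barcode_map
#' @param map A barcode map tibble.
#' @param path Output TSV path.
#' @export
write_barcode_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.mm <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Assign merged reads to index products
#'
#' Barcode-anchored decomposition: every barcode is located as an exact
#' substring (a rescue pass allows one mismatch, which the pairwise
#' Hamming distance >= 3 of the code design keeps unambiguous); an anchor
#' is kept only when the read context flanking it matches its ligamer's
#' arms within `max_mismatch_per_segment` (this discards chance barcode
#' hits inside arms). The surviving anchors, in order, name a ligamer
#' chain that is looked up in the product index and verified arm by arm;
#' mismatches where the mates disagreed but read 2 agrees with the product
#' are not held against it. Statuses are mutually exclusive: `switched`
#' when anchors from both pool codings co-occur, `near_cognate` when a
#' barcode's flanking arms best match a different variant's ligamer than
#' the barcode claims, `assigned` when exactly one product is consistent,
#' `ambiguous` when several are, otherwise `unassigned` (including failed
#' merges). The given orientation is tried first, then the reverse
#' complement; the first consistent decomposition wins.
#'
#' @param merged Tibble from [merge_pairs()].
#' @param index A `product_index`, or a list of per-pool indexes for
#'   dual-coded experiments.
#' @param pools The `ligamer_pool` (or list of two) the index was built
#'   from.
#' @param max_mismatch_per_segment Mismatch tolerance per arm segment.
#' @return A tibble of class `assignment_table`: `read_id`, `status`,
#'   `isoform_key`, `pool_labels` (comma-separated labels observed among
#'   anchors), `seg_mismatches` (list of per-arm mismatch counts).
#' @export
assign_reads <- function(merged, index, pools, max_mismatch_per_segment = 2) {
  if (inherits(pools, "ligamer_pool")) pools <- list(pools)
  if (inherits(index, "product_index")) index <- list(index)
  if (sum(vapply(index, nrow, integer(1))) == 0)
    abort("empty product index", class = "ligzip_error_decode")
  pool_tbl <- dplyr::bind_rows(pools)
  bmap <- barcode_map(pools)

  lig_key <- paste(pool_tbl$pool_label, pool_tbl$ligamer_id, sep = ":")
  lig_seq <- stats::setNames(pool_tbl$sequence, lig_key)
  lig_up <- stats::setNames(pool_tbl$arm_up, lig_key)
  lig_dn <- stats::setNames(pool_tbl$arm_down, lig_key)
  lig_region <- stats::setNames(pool_tbl$region_id, lig_key)
  lig_variant <- stats::setNames(pool_tbl$variant_id, lig_key)
  # arm subranges within each ligamer's sequence: only the arms are
  # verified against the read (spacers and barcodes are covered by the
  # anchoring step, primer tails carry no target information)
  lig_arm_ranges <- stats::setNames(lapply(seq_len(nrow(pool_tbl)), function(i) {
    k <- pool_tbl$kind[i]
    up <- nchar(pool_tbl$arm_up[i]); dn <- nchar(pool_tbl$arm_down[i])
    sp <- nchar(pool_tbl$spacer[i]); tot <- nchar(pool_tbl$sequence[i])
    if (k == "terminal_5p") list(c(sp + 1L, sp + up))
    else if (k == "terminal_3p") list(c(1L, up))
    else list(c(1L, up), c(up + sp + 1L, tot))
  }), lig_key)

  # product lookup: pool + ordered barcoded-ligamer ids -> product row
  prod_tbl <- dplyr::bind_rows(lapply(index, function(ix) {
    tibble(isoform_key = ix$isoform_key, pool_label = ix$pool_label,
           chain = ix$ligamer_chain, sequence = ix$product_sequence)
  }))
  barcoded_ids <- split(bmap$ligamer_id, bmap$pool_label)
  prod_sig <- vapply(seq_len(nrow(prod_tbl)), function(i) {
    ch <- prod_tbl$chain[[i]]
    bc_ch <- ch[ch %in% barcoded_ids[[prod_tbl$pool_label[i]]]]
    paste(prod_tbl$pool_label[i], paste(bc_ch, collapse = ","), sep = "::")
  }, character(1))
  sig_rows <- split(seq_len(nrow(prod_tbl)), prod_sig)

  decode_one <- function(seq, approx = FALSE, alt_pos = integer(0),
                         alt_base = character(0)) {
    # locate barcode occurrences: exact in the fast path; the rescue pass
    # also accepts one mismatch, which the pairwise Hamming distance >= 3
    # of the code design keeps unambiguous
    occ <- list()
    for (bi in seq_len(nrow(bmap))) {
      bc <- bmap$barcode[bi]
      starts <- if (!approx) {
        m <- gregexpr(bc, seq, fixed = TRUE)[[1]]
        if (m[1] == -1L) integer(0) else as.integer(m)
      } else {
        m <- Biostrings::matchPattern(bc, Biostrings::DNAString(seq),
                                      max.mismatch = 1)
        Biostrings::start(m)
      }
      for (s in starts) {
        if (s < 1L || s + nchar(bc) - 1L > nchar(seq)) next
        occ[[length(occ) + 1L]] <- list(
          start = s, end = s + nchar(bc) - 1L,
          lig = bmap$ligamer_id[bi], pool = bmap$pool_label[bi])
      }
    }
    if (length(occ) == 0)
      return(list(status = "unassigned", key = NA_character_,
                  pools = NA_character_, segmm = list(integer(0))))
    occ <- occ[order(vapply(occ, `[[`, numeric(1), "start"))]
    keep <- list(); inconsistent <- FALSE
    L <- nchar(seq)
    for (o in occ) {
      k <- paste(o$pool, o$lig, sep = ":")
      ctx_ok <- function(up, dn) {
        kp <- min(nchar(up), o$start - 1L)
        kd <- min(nchar(dn), L - o$end)
        pre_ok <- kp == 0L ||
          .mm(substr(seq, o$start - kp, o$start - 1L),
              substring(up, nchar(up) - kp + 1L)) <= max_mismatch_per_segment
        post_ok <- kd == 0L ||
          .mm(substr(seq, o$end + 1L, o$end + kd),
              substr(dn, 1L, kd)) <= max_mismatch_per_segment
        pre_ok && post_ok
      }
      if (ctx_ok(lig_up[[k]], lig_dn[[k]])) {
        keep[[length(keep) + 1L]] <- o
      } else if (!is.na(lig_variant[[k]])) {
        # does another variant's ligamer explain the flanking arms?
        sibs <- lig_key[lig_region == lig_region[[k]] &
                          !is.na(lig_variant) &
                          lig_variant != lig_variant[[k]]]
        if (any(vapply(sibs, function(s2)
          ctx_ok(lig_up[[s2]], lig_dn[[s2]]), logical(1))))
          inconsistent <- TRUE
        # else: chance hit inside an arm; drop silently
      }
    }
    if (inconsistent)
      return(list(status = "near_cognate", key = NA_character_,
                  pools = NA_character_, segmm = list(integer(0))))
    if (length(keep) == 0)
      return(list(status = "unassigned", key = NA_character_,
                  pools = NA_character_, segmm = list(integer(0))))
    # drop overlapping duplicate anchors of the same ligamer (shifted
    # rescue-pass hits), keeping the leftmost
    if (length(keep) > 1) {
      drop <- logical(length(keep))
      for (j in seq_along(keep)[-1]) {
        prev <- keep[[j - 1]]
        if (!drop[j - 1] && keep[[j]]$lig == prev$lig &&
            keep[[j]]$start <= prev$end) drop[j] <- TRUE
      }
      keep <- keep[!drop]
    }
    pools_seen <- unique(vapply(keep, `[[`, character(1), "pool"))
    pools_str <- paste(vapply(keep, `[[`, character(1), "pool"), collapse = ",")
    if (length(pools_seen) > 1)
      return(list(status = "switched", key = NA_character_,
                  pools = pools_str, segmm = list(integer(0))))
    sig <- paste(pools_seen, paste(vapply(keep, `[[`, character(1), "lig"),
                                   collapse = ","), sep = "::")
    rows <- sig_rows[[sig]]
    if (is.null(rows))
      return(list(status = "unassigned", key = NA_character_,
                  pools = pools_str, segmm = list(integer(0))))
    if (length(rows) > 1)
      return(list(status = "ambiguous", key = NA_character_,
                  pools = pools_str, segmm = list(integer(0))))
    prod <- prod_tbl[rows, ]
    if (nchar(prod$sequence) != L)
      return(list(status = "unassigned", key = NA_character_,
                  pools = pools_str, segmm = list(integer(0))))
    # per-segment verification
    chain_keys <- paste(prod$pool_label, prod$chain[[1]], sep = ":")
    seg_len <- nchar(lig_seq[chain_keys])
    offsets <- cumsum(c(0L, seg_len[-length(seg_len)]))
    mmpos <- which(charToRaw(seq) != charToRaw(prod$sequence))
    # a mismatch where the mates disagreed but read 2 agrees with the
    # product is a read-1 sequencing error, not evidence against the
    # product: both observations of the overlap count
    if (length(alt_pos) > 0 && length(mmpos) > 0) {
      forgiven <- mmpos %in% alt_pos[alt_base ==
                                       strsplit(prod$sequence, "")[[1]][alt_pos]]
      mmpos <- mmpos[!forgiven]
    }
    # mismatches inside each arm subsegment, per ligamer of the chain
    segmm <- unlist(lapply(seq_along(chain_keys), function(j) {
      vapply(lig_arm_ranges[[chain_keys[j]]], function(rg)
        sum(mmpos >= offsets[j] + rg[1] & mmpos <= offsets[j] + rg[2]),
        integer(1))
    }))
    if (any(segmm > max_mismatch_per_segment))
      return(list(status = "unassigned", key = NA_character_,
                  pools = pools_str, segmm = list(segmm)))
    list(status = "assigned", key = prod$isoform_key, pools = pools_str,
         segmm = list(segmm))
  }

  n <- nrow(merged)
  status <- rep("unassigned", n)
  key <- rep(NA_character_, n)
  plab <- rep(NA_character_, n)
  segmm <- vector("list", n)
  for (i in seq_len(n)) {
    if (!isTRUE(merged$merged[i]) || is.na(merged$sequence[i])) {
      segmm[[i]] <- integer(0); next
    }
    ap <- if ("overlap_mm_pos" %in% names(merged))
      merged$overlap_mm_pos[[i]] else integer(0)
    ab <- if ("overlap_mm_alt" %in% names(merged))
      merged$overlap_mm_alt[[i]] else character(0)
    res <- decode_one(merged$sequence[i], alt_pos = ap, alt_base = ab)
    if (res$status == "unassigned") { # retry in reverse complement
      res2 <- decode_one(reverse_complement(merged$sequence[i]))
      if (res2$status != "unassigned") res <- res2
    }
    if (res$status == "unassigned") { # rescue with 1-mismatch anchoring
      res2 <- decode_one(merged$sequence[i], approx = TRUE,
                         alt_pos = ap, alt_base = ab)
      if (res2$status == "unassigned")
        res2 <- decode_one(reverse_complement(merged$sequence[i]),
                           approx = TRUE)
      if (res2$status != "unassigned") res <- res2
    }
    status[i] <- res$status; key[i] <- res$key
    plab[i] <- res$pools; segmm[[i]] <- res$segmm[[1]]
  }
  out <- tibble(read_id = merged$read_id, status = status,
                isoform_key = key, pool_labels = plab,
                seg_mismatches = segmm)
  structure(out, class = c("assignment_table", class(out)))
}

#' Tally assigned reads into an isoform count table
#'
#' Only `assigned` reads contribute counts; every other status is tallied
#' separately so that statuses sum to the number of input read pairs.
#'
#' @param assignments An `assignment_table`.
#' @param sample_label Sample name recorded on every row.
#' @return A tibble of class `count_table` (`isoform_key`, `sample`,
#'   `count`) with attribute `status_totals`; see [glance()].
#' @export
count_isoforms <- function(assignments, sample_label = "sample1") {
  counts <- assignments %>%
    dplyr::filter(.data$status == "assigned") %>%
    dplyr::count(.data$isoform_key, name = "count") %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$isoform_key) %>%
    mutate(sample = sample_label, .after = "isoform_key")
  totals <- assignments %>%
    dplyr::count(.data$status, name = "n") %>%
    tidyr::complete(status = c("assigned", "ambiguous", "unassigned",
                               "near_cognate", "switched"),
                    fill = list(n = 0L)) %>%
    mutate(sample = sample_label)
  structure(counts, status_totals = totals,
            class = c("count_table", class(counts)))
}

#' Write a count table (with status summary) as TSV
#'
#' @param counts A `count_table`.
#' @param path Output path for the counts; the status summary goes to
#'   `<path>.status.tsv`.
#' @return `path`, invisibly.
#' @export
write_count_tsv <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(attr(counts, "status_totals")),
                     paste0(path, ".status.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Template-switch report
#'
#' Counts and fraction of reads whose anchors mix the two pool codings,
#' plus the observed cross-pool barcode patterns. Template-switched
#' products are identifiable only in dual-coded experiments; with a single
#' pool the report is marked not applicable.
#'
#' @param assignments An `assignment_table`.
#' @return A tibble of class `switch_report` (`pattern`, `n`) with
#'   attributes `applicable`, `n_switched`, `n_total`, `fraction`.
#' @export
switch_report <- function(assignments) {
  n_total <- nrow(assignments)
  labs <- unique(unlist(strsplit(assignments$pool_labels[
    !is.na(assignments$pool_labels)], ",", fixed = TRUE)))
  applicable <- length(labs) > 1
  sw <- dplyr::filter(assignments, .data$status == "switched")
  pat <- sw %>% dplyr::count(pattern = .data$pool_labels, name = "n") %>%
    dplyr::arrange(dplyr::desc(.data$n))
  structure(pat, applicable = applicable, n_switched = nrow(sw),
            n_total = n_total,
            fraction = if (n_total > 0) nrow(sw) / n_total else NA_real_,
            class = c("switch_report", class(pat)))
}
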