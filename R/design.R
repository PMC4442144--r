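# Ligamer pool design: terminal and internal splint oligos, barcode
# assignment, pool planning over a gene model, and specificity / energy-gap
# screening.
#
# Convention: arm sequences are stored in the sense (target) orientation and
# a ligamer's `sequence` is arm_up + spacer + arm_down; ligation products
# concatenate ligamer sequences in target-RNA 5'->3' footprint order. The
# physical oligo is the reverse complement of the stored string, which
# leaves every Tm and delta-G unchanged and keeps design, indexing and
# decoding in one coordinate system.

ligamer_row <- function(ligamer_id, kind, region_id, variant_id, arm_up,
                        arm_down, spacer, barcode, has_5p_phosphate,
                        targets, flags = "", pool_label = "pool1") {
  tibble(
    ligamer_id = ligamer_id, kind = kind, region_id = region_id,
    variant_id = variant_id, arm_up = arm_up, arm_down = arm_down,
    spacer = spacer, barcode = barcode,
    sequence = if (kind == "terminal_5p") paste0(spacer, arm_up)
    else if (kind == "terminal_3p") paste0(arm_up, spacer)
    else paste0(arm_up, spacer, arm_down),
    has_5p_phosphate = has_5p_phosphate,
    pool_label = pool_label, flags = flags, targets = list(targets)
  )
}

# Tm of every prefix (or suffix) length of a region, lengths n_min..nchar
scan_tms <- function(region, lengths, side = c("prefix", "suffix"),
                     params) {
  side <- match.arg(side)
  L <- nchar(region)
  subs <- if (side == "prefix") substr(rep(region, length(lengths)), 1, lengths)
  else substring(rep(region, length(lengths)), L - lengths + 1, L)
  melting_temp(subs, params)
}

#' Design a terminal ligamer
#'
#' The arm anneals at one end of the profiled span and is trimmed from the
#' far side, one nucleotide at a time, until its melting temperature no
#' longer exceeds `config$tm_max`: the returned arm is the longest
#' prefix/suffix of the region whose Tm is at or below the threshold (so
#' its one-nucleotide extension, when available, exceeds it). The
#' amplification primer tail is placed on the outward side. If even the
#' full-length region stays below threshold the full arm is returned with
#' flag `"exhausted"`; a best Tm below `config$tm_floor` adds `"low_tm"`.
#'
#' @param region Target region sequence (the 5'-most or 3'-most constitutive
#'   block of the profiled span).
#' @param end `"five_prime"` or `"three_prime"`: which end of the profiled
#'   span this ligamer anchors. A five-prime terminal arm is a suffix of its
#'   region (its footprint must abut the next region), a three-prime
#'   terminal arm a prefix.
#' @param primer_tail PCR primer sequence carried verbatim.
#' @param config A [design_config()].
#' @param region_id Region identifier recorded in the target coordinates.
#' @param ligamer_id Identifier; default derived from `region_id`.
#' @return A one-row ligamer tibble.
#' @export
design_terminal_ligamer <- function(region, end = c("five_prime", "three_prime"),
                                    primer_tail = NULL,
                                    config = design_config(),
                                    region_id = "region",
                                    ligamer_id = NULL) {
  end <- match.arg(end)
  if (is.null(primer_tail))
    primer_tail <- if (end == "five_prime") config$primer_tail_5p else config$primer_tail_3p
  if (!nzchar(region))
    abort("empty region", class = "ligzip_error_design")
  check_dna(region, "region", min_len = 2)
  L <- nchar(region)
  side <- if (end == "five_prime") "suffix" else "prefix"
  lengths <- seq.int(min(2L, L), L)
  tms <- scan_tms(region, lengths, side, config$params)
  ok <- which(tms <= config$tm_max)
  flags <- character(0)
  if (length(ok) == 0) { # even the shortest arm exceeds tm_max
    pick <- 1L
    flags <- c(flags, "infeasible_tm")
  } else {
    pick <- max(ok)
    if (pick == length(lengths)) flags <- c(flags, "exhausted")
  }
  alen <- lengths[pick]
  if (tms[pick] < config$tm_floor) flags <- c(flags, "low_tm")
  arm <- if (side == "suffix") substring(region, L - alen + 1, L)
  else substr(region, 1, alen)
  start <- if (side == "suffix") L - alen else 0L
  kind <- if (end == "five_prime") "terminal_5p" else "terminal_3p"
  if (is.null(ligamer_id))
    ligamer_id <- paste0("T", if (end == "five_prime") "5" else "3", "_", region_id)
  ligamer_row(
    ligamer_id, kind, region_id, NA_character_, arm, "",
    spacer = primer_tail, barcode = NA_character_,
    has_5p_phosphate = end != "five_prime",
    targets = tibble(arm = "up", region_id = region_id,
                     variant_id = NA_character_,
                     start = start, end = start + alen),
    flags = paste(flags, collapse = ",")
  )
}

#' Design an internal ligamer
#'
#' Internal ligamers hybridize to the beginning and end of their target,
#' looping out the sequence in between, with the barcode (spacer) opposite
#' the loop. Arms are trimmed from the inside of the targets outward until
#' (1) each arm's Tm lies within `arm_tm_target` +/- `arm_tm_tolerance` and
#' (2) total length (arms + barcode) is at most `max_len`. The upstream arm
#' is fixed first at the longest feasible length that leaves room for a
#' feasible downstream arm; the downstream arm then takes the longest
#' feasible length within the remaining budget (ties broken toward a longer
#' upstream arm).
#'
#' @param upstream_target Sequence whose prefix the upstream arm anneals to
#'   (typically the target exon's 5' end; the footprint starts at its first
#'   base so that it abuts the upstream ligation junction).
#' @param downstream_target Sequence whose suffix the downstream arm anneals
#'   to. For a single looped-out exon pass the same sequence twice.
#' @param barcode Barcode placed in the spacer (may be `""`).
#' @param config A [design_config()].
#' @param region_id,variant_id,ligamer_id Identifiers recorded on the
#'   ligamer.
#' @param footprint_budget Maximum combined footprint length of the two
#'   arms; when both arms sit on the same exon this is the exon length, so
#'   the footprints cannot overlap.
#' @return A one-row ligamer tibble.
#' @export
design_internal_ligamer <- function(upstream_target, downstream_target,
                                    barcode = "",
                                    config = design_config(),
                                    region_id = "region",
                                    variant_id = NA_character_,
                                    ligamer_id = NULL,
                                    footprint_budget = Inf) {
  check_dna(upstream_target, "upstream_target", min_len = 2)
  check_dna(downstream_target, "downstream_target", min_len = 2)
  if (nzchar(barcode)) check_dna(barcode, "barcode", min_len = 1)
  lo <- config$arm_tm_target - config$arm_tm_tolerance
  hi <- config$arm_tm_target + config$arm_tm_tolerance
  budget <- min(config$max_len - nchar(barcode), footprint_budget)
  Lu <- nchar(upstream_target); Ld <- nchar(downstream_target)
  min_len <- max(2L, min(config$min_arm_len, Lu, Ld))
  lens_u <- seq.int(min(min_len, Lu), Lu)
  lens_d <- seq.int(min(min_len, Ld), Ld)
  tm_u <- scan_tms(upstream_target, lens_u, "prefix", config$params)
  tm_d <- scan_tms(downstream_target, lens_d, "suffix", config$params)
  feas_u <- lens_u[tm_u >= lo & tm_u <= hi]
  feas_d <- lens_d[tm_d >= lo & tm_d <= hi]
  if (length(feas_u) == 0 || length(feas_d) == 0)
    abort(paste0("no arm length reaches the Tm window [", lo, ", ", hi,
                 "] for ", if (length(feas_u) == 0) "upstream" else "downstream",
                 " target (constraint: arm_tm)"),
          class = "ligzip_error_infeasible")
  if (min(feas_u) + min(feas_d) > budget)
    abort(paste0("arms satisfying the Tm window cannot fit in max_len = ",
                 config$max_len, " with a ", nchar(barcode),
                 " nt barcode (constraint: max_len)"),
          class = "ligzip_error_infeasible")
  len_up <- max(feas_u[feas_u + min(feas_d) <= budget])
  len_dn <- max(feas_d[feas_d <= budget - len_up])
  arm_up <- substr(upstream_target, 1, len_up)
  arm_dn <- substring(downstream_target, Ld - len_dn + 1, Ld)
  if (is.null(ligamer_id))
    ligamer_id <- paste0("I_", if (is.na(variant_id)) region_id else variant_id)
  ligamer_row(
    ligamer_id, "internal", region_id, variant_id, arm_up, arm_dn,
    spacer = barcode, barcode = if (nzchar(barcode)) barcode else NA_character_,
    has_5p_phosphate = TRUE,
    targets = tibble(arm = c("up", "down"),
                     region_id = region_id,
                     variant_id = variant_id,
                     start = c(0L, Ld - len_dn),
                     end = c(len_up, Ld))
  )
}

#' Generate a barcode set
#'
#' Random search for `n` distinct codes of the given length with pairwise
#' Hamming distance at least `min_hamming` and no homopolymer run longer
#' than 3. Reproducible under `seed`.
#'
#' @param n Number of codes.
#' @param length Code length in nt.
#' @param min_hamming Minimum pairwise Hamming distance.
#' @param seed Integer seed.
#' @param max_attempts Search budget (candidate draws) before giving up.
#' @return Character vector of class `barcode_set` with attributes `length`,
#'   `min_hamming`, `seed`.
#' @export
#' @examples
#' generate_barcodes(4, length = 7, min_hamming = 3, seed = 1)
generate_barcodes <- function(n, length = 7, min_hamming = 3, seed = 1L,
                              max_attempts = 10000L * n) {
  if (n > 4^length)
    abort(paste0("cannot draw ", n, " distinct codes of length ", length,
                 " (capacity ", 4^length, ")"), class = "ligzip_error_capacity")
  codes <- character(0)
  code_mat <- matrix(character(0), nrow = length, ncol = 0)
  with_seed(seed, {
    attempts <- 0L
    while (base::length(codes) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        abort(paste0("barcode search exhausted after ", max_attempts,
                     " attempts"), class = "ligzip_error_search")
      cand <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      cs <- paste(cand, collapse = "")
      if (grepl("AAAA|CCCC|GGGG|TTTT", cs)) next
      if (ncol(code_mat) > 0 &&
          any(colSums(code_mat != cand) < min_hamming)) next
      codes <- c(codes, cs)
      code_mat <- cbind(code_mat, cand)
    }
  })
  structure(codes, length = length, min_hamming = min_hamming,
            seed = as.integer(seed), class = "barcode_set")
}

#' Plan a ligamer pool for a gene model
#'
#' Emits exactly: one terminal ligamer at each end of the profiled span, one
#' internal ligamer per variant exon in each variant region (a skip outcome,
#' encoded as an empty variant sequence, adds none -- its flanking ligamers
#' simply become adjacent), and one internal ligamer per interior
#' constitutive block separating variant regions. Every internal ligamer
#' carries a unique barcode so that ligation products are distinguishable
#' and template switches across pools are detectable.
#'
#' @param gm A [gene_model()]. The first and last regions must be
#'   constitutive (the terminal anchors).
#' @param config A [design_config()].
#' @param pool_label Pool label recorded on every ligamer.
#' @param barcodes Optional character vector of barcodes to use (in region
#'   order); by default generated with [generate_barcodes()] from
#'   `config$barcode_seed`.
#' @return A ligamer pool tibble of class `ligamer_pool`.
#' @export
plan_pool <- function(gm, config = design_config(), pool_label = "pool1",
                      barcodes = NULL) {
  stopifnot(inherits(gm, "gene_model"))
  n <- nrow(gm)
  if (gm$type[1] != "constitutive" || gm$type[n] != "constitutive")
    abort("the profiled span must start and end on a constitutive block (no terminal anchor for a variant region)",
          class = "ligzip_error_design")
  interior <- gm[seq_len(n)[-c(1, n)], , drop = FALSE]
  n_internal <- sum(vapply(seq_len(nrow(interior)), function(i) {
    if (interior$type[i] == "constitutive") 1L
    else sum(nzchar(interior$variants[[i]]))
  }, integer(1)))
  if (is.null(barcodes)) {
    barcodes <- generate_barcodes(n_internal, length = config$barcode_length,
                                  min_hamming = config$min_hamming,
                                  seed = config$barcode_seed)
  } else if (length(barcodes) < n_internal) {
    abort(paste0("need ", n_internal, " barcodes, got ", length(barcodes)),
          class = "ligzip_error_design")
  }
  rows <- list(
    design_terminal_ligamer(gm$variants[[1]][[1]], "five_prime",
                            config$primer_tail_5p, config,
                            region_id = gm$region_id[1])
  )
  b <- 0L
  for (i in seq_len(nrow(interior))) {
    rid <- interior$region_id[i]
    if (interior$type[i] == "constitutive") {
      b <- b + 1L
      rows[[length(rows) + 1L]] <- design_internal_ligamer(
        interior$variants[[i]][[1]], interior$variants[[i]][[1]],
        barcode = barcodes[[b]], config = config, region_id = rid,
        ligamer_id = paste0("I_", rid),
        footprint_budget = nchar(interior$variants[[i]][[1]]))
    } else {
      vs <- interior$variants[[i]]
      for (vid in names(vs)) {
        if (!nzchar(vs[[vid]])) next # skip outcome: no ligamer
        b <- b + 1L
        rows[[length(rows) + 1L]] <- design_internal_ligamer(
          vs[[vid]], vs[[vid]], barcode = barcodes[[b]], config = config,
          region_id = rid, variant_id = vid,
          ligamer_id = paste0("I_", vid),
          footprint_budget = nchar(vs[[vid]]))
      }
    }
  }
  rows[[length(rows) + 1L]] <- design_terminal_ligamer(
    gm$variants[[n]][[1]], "three_prime", config$primer_tail_3p, config,
    region_id = gm$region_id[n])
  pool <- dplyr::bind_rows(rows)
  pool$pool_label <- pool_label
  structure(pool, gene_id = gene_id(gm),
            class = c("ligamer_pool", class(pool)))
}

#' Plan two differentially coded pools
#'
#' Both pools share arms and structure but every internal ligamer carries a
#' different barcode in pool 1 than in pool 2 (and all barcodes are unique
#' across both pools), so any product mixing the two codings is a
#' template-switch signature.
#'
#' @inheritParams plan_pool
#' @param labels Length-2 character vector of pool labels.
#' @return A list of two `ligamer_pool` tibbles.
#' @export
plan_dual_pools <- function(gm, config = design_config(),
                            labels = c("pool1", "pool2")) {
  stopifnot(length(labels) == 2, labels[1] != labels[2])
  probe <- plan_pool(gm, config, pool_label = labels[1])
  n_internal <- sum(probe$kind == "internal")
  codes <- generate_barcodes(2L * n_internal, length = config$barcode_length,
                             min_hamming = config$min_hamming,
                             seed = config$barcode_seed)
  p1 <- plan_pool(gm, config, pool_label = labels[1],
                  barcodes = codes[seq_len(n_internal)])
  p2 <- plan_pool(gm, config, pool_label = labels[2],
                  barcodes = codes[n_internal + seq_len(n_internal)])
  list(p1, p2)
}

#' Validate ligamer pool invariants
#'
#' Checks that every internal ligamer respects the length bound and both
#' arm-Tm windows, terminal arms respect `tm_max`, barcodes are unique
#' pool-wide, and exactly one ligamer is 5'-phosphate-free (the 5' terminal).
#'
#' @param pool A `ligamer_pool`.
#' @param config The [design_config()] the pool was built under.
#' @return `TRUE` invisibly; aborts with a message on violation.
#' @export
validate_pool <- function(pool, config = design_config()) {
  internal <- dplyr::filter(pool, .data$kind == "internal")
  if (nrow(internal) > 0) {
    if (any(nchar(internal$sequence) > config$max_len))
      abort("internal ligamer exceeds max_len", class = "ligzip_error_pool")
    lo <- config$arm_tm_target - config$arm_tm_tolerance
    hi <- config$arm_tm_target + config$arm_tm_tolerance
    tms <- melting_temp(c(internal$arm_up, internal$arm_down), config$params)
    if (any(tms < lo - 1e-9 | tms > hi + 1e-9))
      abort("internal arm Tm outside window", class = "ligzip_error_pool")
    bc <- internal$barcode[!is.na(internal$barcode)]
    if (anyDuplicated(bc))
      abort("barcodes are not unique within the pool", class = "ligzip_error_pool")
  }
  term <- dplyr::filter(pool, .data$kind != "internal")
  tms <- melting_temp(term$arm_up, config$params)
  bad <- tms > config$tm_max + 1e-9 & !grepl("infeasible_tm", term$flags)
  if (any(bad))
    abort("terminal arm Tm above tm_max", class = "ligzip_error_pool")
  if (sum(!pool$has_5p_phosphate) != 1 ||
      pool$kind[!pool$has_5p_phosphate] != "terminal_5p")
    abort("exactly the 5' terminal ligamer must lack the 5' phosphate",
          class = "ligzip_error_pool")
  invisible(TRUE)
}

#' Screen a pool for specificity and cognate / near-cognate energy gaps
#'
#' Each arm is searched against the transcript set as an exact and
#' one-mismatch substring (the design-time stand-in for a genome alignment
#' check). For each variant-targeting ligamer the hybridization free energy
#' against its cognate variant and against every other variant in its
#' cluster is computed; the gap (nearest near-cognate delta-G minus cognate
#' delta-G) is reported and flagged when below `config$dg_gap_min`.
#'
#' @param pool A `ligamer_pool`.
#' @param transcripts Named character vector (or `DNAStringSet`) of
#'   transcript sequences to screen against.
#' @param gm The [gene_model()] the pool was designed on.
#' @param config A [design_config()].
#' @return A tibble with one row per variant ligamer: exact and 1-mismatch
#'   hit counts, `dg_cognate`, `dg_nearest_near_cognate`,
#'   `nearest_near_cognate` variant id, `gap`, `flagged`; plus attribute
#'   `arm_hits`, the per-arm hit table over all ligamers.
#' @export
screen_pool_specificity <- function(pool, transcripts, gm,
                                    config = design_config()) {
  if (length(transcripts) == 0)
    abort("transcript set is empty", class = "ligzip_error_design")
  if (!methods::is(transcripts, "DNAStringSet"))
    transcripts <- Biostrings::DNAStringSet(unlist(transcripts))
  arms <- dplyr::bind_rows(
    tibble(ligamer_id = pool$ligamer_id, arm = "up", seq = pool$arm_up),
    tibble(ligamer_id = pool$ligamer_id, arm = "down", seq = pool$arm_down)
  ) %>% dplyr::filter(nzchar(.data$seq))
  arms$n_hits_exact <- vapply(arms$seq, function(a)
    sum(Biostrings::vcountPattern(a, transcripts, max.mismatch = 0)),
    numeric(1), USE.NAMES = FALSE)
  arms$n_hits_1mm <- vapply(arms$seq, function(a)
    sum(Biostrings::vcountPattern(a, transcripts, max.mismatch = 1)),
    numeric(1), USE.NAMES = FALSE)
  arms$off_target_hits <- arms$n_hits_1mm - arms$n_hits_exact

  vl <- dplyr::filter(pool, !is.na(.data$variant_id))
  rows <- purrr::map(seq_len(nrow(vl)), function(i) {
    lg <- vl[i, ]
    vs <- gm$variants[[match(lg$region_id, gm$region_id)]]
    vs <- vs[nzchar(vs)]
    # the physical probe strand is the reverse complement of the stored
    # sense-orientation arm; delta-G is computed against each variant's
    # corresponding terminal region
    dg <- vapply(names(vs), function(vid) {
      s <- vs[[vid]]
      lu <- nchar(lg$arm_up); ld <- nchar(lg$arm_down)
      if (nchar(s) < max(lu, ld)) return(NA_real_)
      duplex_free_energy(reverse_complement(lg$arm_up),
                         substr(s, 1, lu), config$params) +
        duplex_free_energy(reverse_complement(lg$arm_down),
                           substring(s, nchar(s) - ld + 1, nchar(s)),
                           config$params)
    }, numeric(1))
    cognate <- dg[[lg$variant_id]]
    others <- dg[setdiff(names(dg), lg$variant_id)]
    others <- others[!is.na(others)]
    nn_dg <- if (length(others)) min(others) else NA_real_
    nn_id <- if (length(others)) names(others)[which.min(others)] else NA_character_
    tibble(ligamer_id = lg$ligamer_id, region_id = lg$region_id,
           variant_id = lg$variant_id, dg_cognate = cognate,
           dg_nearest_near_cognate = nn_dg, nearest_near_cognate = nn_id,
           gap = nn_dg - cognate,
           flagged = !is.na(nn_dg) && (nn_dg - cognate) < config$dg_gap_min)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "arm_hits") <- dplyr::select(arms, -"seq")
  out
}

#' Export a pool as a TSV order sheet or FASTA
#'
#' The TSV has columns `ligamer_id`, `sequence` (5'->3' in the package's
#' sense convention), `has_5p_phosphate`.
#'
#' @param pool A `ligamer_pool`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool_tsv <- function(pool, path) {
  utils::write.table(
    pool[, c("ligamer_id", "sequence", "has_5p_phosphate")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_tsv
#' @export
write_pool_fasta <- function(pool, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(pool$sequence, pool$ligamer_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
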