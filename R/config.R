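# Pool-design configuration: every threshold the designer uses, in one
# list that round-trips through YAML.

#' Ligamer design configuration
#'
#' Thresholds governing arm trimming, pool assembly and specificity
#' screening. Temperatures are degrees Celsius, lengths nucleotides,
#' energies kcal/mol.
#'
#' @param tm_max Maximum arm melting temperature; terminal arms are trimmed
#'   until Tm is at or below this (default 65).
#' @param arm_tm_target,arm_tm_tolerance Internal arms must fall in
#'   `arm_tm_target` +/- `arm_tm_tolerance` (default 60 +/- 5).
#' @param max_len Maximum total internal ligamer length, arms plus barcode
#'   (default 60).
#' @param barcode_length Barcode length in nt (default 7).
#' @param min_hamming Minimum pairwise Hamming distance between barcodes
#'   (default 3).
#' @param dg_gap_min Minimum acceptable free-energy gap (kcal/mol) between a
#'   ligamer's cognate and nearest near-cognate duplex before the screen
#'   flags it (default 5).
#' @param tm_floor Terminal arms whose best achievable Tm is below this are
#'   flagged `low_tm` (default 40).
#' @param min_arm_len Shortest arm the trimming scan will consider
#'   (default 8).
#' @param primer_tail_5p,primer_tail_3p Amplification primer sequences
#'   carried verbatim on the terminal ligamers.
#' @param barcode_seed Seed for reproducible barcode generation during pool
#'   planning.
#' @param params A [duplex_params()] object used for all Tm/delta-G
#'   calculations.
#' @return A list of class `design_config`.
#' @export
design_config <- function(tm_max = 65,
                          arm_tm_target = 60,
                          arm_tm_tolerance = 5,
                          max_len = 60,
                          barcode_length = 7,
                          min_hamming = 3,
                          dg_gap_min = 5,
                          tm_floor = 40,
                          min_arm_len = 8,
                          primer_tail_5p = "ACACGACGCTCTTCCGATCT",
                          primer_tail_3p = "AGATCGGAAGAGCACACGTC",
                          barcode_seed = 1L,
                          params = duplex_params()) {
  structure(
    list(tm_max = tm_max, arm_tm_target = arm_tm_target,
         arm_tm_tolerance = arm_tm_tolerance, max_len = max_len,
         barcode_length = barcode_length, min_hamming = min_hamming,
         dg_gap_min = dg_gap_min, tm_floor = tm_floor,
         min_arm_len = min_arm_len,
         primer_tail_5p = primer_tail_5p, primer_tail_3p = primer_tail_3p,
         barcode_seed = as.integer(barcode_seed), params = params),
    class = "design_config"
  )
}

#' Read / write a design configuration as YAML
#'
#' @param path File path.
#' @return `read_design_config()` returns a `design_config`;
#'   `write_design_config()` returns `path` invisibly.
#' @export
read_design_config <- function(path) {
  y <- yaml::read_yaml(path)
  p <- y$params
  y$params <- NULL
  cfg <- do.call(design_config, y)
  if (!is.null(p)) cfg$params <- do.call(duplex_params, p)
  cfg
}

#' @rdname read_design_config
#' @param config A `design_config` object.
#' @export
write_design_config <- function(config, path) {
  out <- unclass(config)
  out$params <- unclass(out$params)
  yaml::write_yaml(out, path)
  invisible(path)
}

# run code with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
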