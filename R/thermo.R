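# Nearest-neighbor duplex thermodynamics: melting temperature and
# hybridization free energy, used by ligamer arm trimming and by
# cognate / near-cognate screening.

# cache for parameter tables keyed by parameter_table_id
.nn_cache <- new.env(parent = emptyenv())

#' Duplex thermodynamic parameters
#'
#' Conditions and parameter set under which melting temperatures and
#' hybridization free energies are computed. Defaults follow the unified
#' DNA nearest-neighbor parameter set of SantaLucia (1998) at 50 mM
#' monovalent salt and 500 nM total oligonucleotide. DNA:RNA hybrids are
#' approximated with DNA:DNA parameters; `parameter_table_id` is a hook for
#' substituting a hybrid table shipped in the same plain-text format.
#'
#' @param monovalent_salt Monovalent cation concentration in mol/L.
#' @param oligo_conc Total oligonucleotide concentration in mol/L.
#' @param temperature_for_dg Temperature (degrees Celsius) at which
#'   [duplex_free_energy()] reports delta-G.
#' @param parameter_table_id Basename (without extension) of a tab-separated
#'   parameter table under `extdata/` providing delta-H (kcal/mol) and
#'   delta-S (cal/mol/K) for all 16 dinucleotide stacks plus the four
#'   terminal initiation terms.
#' @param mismatch_dg_penalty Free-energy penalty (kcal/mol) added per
#'   mismatched stack in [duplex_free_energy()]; a single uniform
#'   destabilization term, configurable because no position-specific
#'   mismatch model is assumed.
#' @return A list of class `duplex_params`.
#' @export
#' @examples
#' melting_temp("ACGTACGTACGTACGT", duplex_params())
duplex_params <- function(monovalent_salt = 0.05,
                          oligo_conc = 5e-7,
                          temperature_for_dg = 37,
                          parameter_table_id = "santalucia1998_dna",
                          mismatch_dg_penalty = 1.0) {
  if (!is.numeric(monovalent_salt) || monovalent_salt <= 0)
    abort("`monovalent_salt` must be > 0", class = "ligzip_error_params")
  if (!is.numeric(oligo_conc) || oligo_conc <= 0)
    abort("`oligo_conc` must be > 0", class = "ligzip_error_params")
  structure(
    list(monovalent_salt = monovalent_salt,
         oligo_conc = oligo_conc,
         temperature_for_dg = temperature_for_dg,
         parameter_table_id = parameter_table_id,
         mismatch_dg_penalty = mismatch_dg_penalty),
    class = "duplex_params"
  )
}

# load (and cache) a nearest-neighbor table; validates coverage of all 16
# stacks and 4 initiation terms
nn_table <- function(id = "santalucia1998_dna") {
  if (!is.null(.nn_cache[[id]])) return(.nn_cache[[id]])
  path <- system.file("extdata", paste0("nn_", id, ".tsv"), package = "ligzip")
  if (!nzchar(path))
    abort(paste0("unknown parameter_table_id: ", id), class = "ligzip_error_params")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stacks <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  need <- c(stacks, paste0("init_", c("A", "C", "G", "T")))
  if (!all(need %in% tab$key))
    abort("parameter table must cover all 16 stacks and 4 initiation terms",
          class = "ligzip_error_params")
  dh <- stats::setNames(tab$dh_kcal_mol, tab$key)
  ds <- stats::setNames(tab$ds_cal_mol_k, tab$key)
  .nn_cache[[id]] <- list(dh = dh, ds = ds)
  .nn_cache[[id]]
}

.gas_const <- 1.987 # cal / (mol K)

check_dna <- function(x, what = "sequence", min_len = 2) {
  if (!is.character(x) || any(is.na(x)))
    abort(paste0(what, " must be a character vector"), class = "ligzip_error_sequence")
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    abort(paste0(what, " contains non-ACGT characters: ",
                 paste(utils::head(x[bad], 3), collapse = ", ")),
          class = "ligzip_error_sequence")
  if (any(nchar(x) < min_len))
    abort(paste0(what, " shorter than ", min_len, " nt"),
          class = "ligzip_error_sequence")
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of ACGT strings.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# sum dH (kcal/mol) and dS (cal/mol/K) over stacks of a perfect duplex,
# including terminal initiation terms
nn_sums <- function(sequence, tab) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  stacks <- paste0(ch[-n], ch[-1])
  dh <- sum(tab$dh[stacks]) + tab$dh[paste0("init_", ch[1])] +
    tab$dh[paste0("init_", ch[n])]
  ds <- sum(tab$ds[stacks]) + tab$ds[paste0("init_", ch[1])] +
    tab$ds[paste0("init_", ch[n])]
  c(dh = unname(dh), ds = unname(ds))
}

#' Nearest-neighbor duplex melting temperature
#'
#' Tm of each sequence against its perfect complement, from summed
#' nearest-neighbor delta-H/delta-S with entropic salt correction
#' (0.368 x n_stacks x ln\[Na+\] cal/mol/K) and the two-state formula
#' Tm = 1000 dH / (dS' + R ln(Ct/4)) - 273.15. Deterministic; invariant
#' under reverse complement.
#'
#' @param sequence Character vector of ACGT strings, each length >= 2.
#' @param params A [duplex_params()] object.
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @export
#' @examples
#' melting_temp(c("GCGCGCGCGCGC", "ATATATATATAT"))
melting_temp <- function(sequence, params = duplex_params()) {
  check_dna(sequence, "sequence", min_len = 2)
  tab <- nn_table(params$parameter_table_id)
  vapply(sequence, function(s) {
    hs <- nn_sums(s, tab)
    ds_salt <- hs["ds"] + 0.368 * (nchar(s) - 1) * log(params$monovalent_salt)
    unname(1000 * hs["dh"] /
             (ds_salt + .gas_const * log(params$oligo_conc / 4)) - 273.15)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Hybridization free energy of an aligned probe/target duplex
#'
#' Delta-G (kcal/mol) at `params$temperature_for_dg` for a probe annealed
#' antiparallel to an equal-length target region. Positions where the target
#' base is not the Watson-Crick partner of the probe base are mismatches:
#' stacks touching a mismatch contribute no nearest-neighbor term and incur
#' `params$mismatch_dg_penalty` each, so every additional perfectly paired
#' stack makes delta-G more negative and mismatches destabilize uniformly.
#' With `target = NULL` the perfect complement is assumed.
#'
#' @param probe Character vector of ACGT strings (length >= 2 each).
#' @param target Character vector of target regions, written 5'->3', each the
#'   same length as the corresponding probe, or `NULL` for perfect duplexes.
#' @param params A [duplex_params()] object.
#' @return Numeric vector of free energies in kcal/mol.
#' @export
#' @examples
#' duplex_free_energy("ACGTACGTACGTACGT")
duplex_free_energy <- function(probe, target = NULL, params = duplex_params()) {
  check_dna(probe, "probe", min_len = 2)
  if (is.null(target)) target <- reverse_complement(probe)
  check_dna(target, "target", min_len = 2)
  if (length(target) != length(probe))
    abort("`probe` and `target` must have the same length", class = "ligzip_error_alignment")
  if (any(nchar(target) != nchar(probe)))
    abort("probe/target length mismatch: alignment must be gap-free and equal length",
          class = "ligzip_error_alignment")
  tab <- nn_table(params$parameter_table_id)
  tK <- params$temperature_for_dg + 273.15
  mapply(function(p, t) {
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    n <- length(ch)
    # probe position i pairs with target position n + 1 - i
    partner <- rev(strsplit(t, "", fixed = TRUE)[[1]])
    matched <- chartr("ACGT", "TGCA", ch) ==
      vapply(seq_len(n), function(i) partner[i], character(1))
    stacks <- paste0(ch[-n], ch[-1])
    ok <- matched[-n] & matched[-1]
    dh <- sum(tab$dh[stacks[ok]])
    ds <- sum(tab$ds[stacks[ok]])
    if (matched[1]) {
      dh <- dh + tab$dh[paste0("init_", ch[1])]
      ds <- ds + tab$ds[paste0("init_", ch[1])]
    }
    if (matched[n]) {
      dh <- dh + tab$dh[paste0("init_", ch[n])]
      ds <- ds + tab$ds[paste0("init_", ch[n])]
    }
    ds_salt <- ds + 0.368 * sum(ok) * log(params$monovalent_salt)
    unname(dh - tK * ds_salt / 1000) +
      params$mismatch_dg_penalty * sum(!ok)
  }, probe, target, USE.NAMES = FALSE)
}
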