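# Independent nearest-neighbor summation oracle for Tm and delta-G, kept
# deliberately separate from the package implementation: parameters are
# inlined literally and the sums are accumulated in a plain loop.

.oracle_dh <- c(
  AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
  CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
  GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
  TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9,
  init_A = 2.3, init_C = 0.1, init_G = 0.1, init_T = 2.3)
.oracle_ds <- c(
  AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
  CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
  GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
  TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2,
  init_A = 4.1, init_C = -2.8, init_G = -2.8, init_T = 4.1)

oracle_hs <- function(s) {
  ch <- strsplit(s, "")[[1]]
  dh <- .oracle_dh[[paste0("init_", ch[1])]] +
    .oracle_dh[[paste0("init_", ch[length(ch)])]]
  ds <- .oracle_ds[[paste0("init_", ch[1])]] +
    .oracle_ds[[paste0("init_", ch[length(ch)])]]
  for (i in seq_len(length(ch) - 1)) {
    st <- paste0(ch[i], ch[i + 1])
    dh <- dh + .oracle_dh[[st]]
    ds <- ds + .oracle_ds[[st]]
  }
  c(dh, ds)
}

oracle_tm <- function(s, na = 0.05, ct = 5e-7) {
  hs <- oracle_hs(s)
  ds_salt <- hs[2] + 0.368 * (nchar(s) - 1) * log(na)
  1000 * hs[1] / (ds_salt + 1.987 * log(ct / 4)) - 273.15
}

oracle_dg <- function(s, na = 0.05, t_c = 37) {
  hs <- oracle_hs(s)
  ds_salt <- hs[2] + 0.368 * (nchar(s) - 1) * log(na)
  hs[1] - (273.15 + t_c) * ds_salt / 1000
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

all_kmers <- function(k) {
  apply(do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k)),
        1, paste, collapse = "")
}
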