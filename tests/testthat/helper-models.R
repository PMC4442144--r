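# Fixture gene models and pools, built in code.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Fibronectin-like model: terminal blocks, one cassette exon (included or
# skipped), one separating constitutive block, and an alternative-3'SS
# region with long/short/skip outcomes.
gm_fn1_like <- function(seed = 11) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(gene_model("fn1_like", list(
    list(id = "up", type = "constitutive", sequence = rand_seq(150)),
    list(id = "EDA", type = "cassette",
         variants = c(EDA.in = rand_seq(150), EDA.skip = "")),
    list(id = "mid", type = "constitutive", sequence = rand_seq(200)),
    list(id = "V", type = "alt3ss",
         variants = c(V.120 = rand_seq(360), V.95 = rand_seq(285),
                      V.0 = "")),
    list(id = "dn", type = "constitutive", sequence = rand_seq(150)))))
}

# Dscam1-like model: three mutually exclusive clusters of 12, 48 and 33
# variants separated by constitutive blocks, flanked by terminal anchors.
gm_dscam1_like <- function(seed = 12, exon_length = 120, flank_length = 120) {
  synth_gene(3, c(12, 48, 33), exon_length = exon_length, similarity = 0.7,
             seed = seed, flank_length = flank_length, gene_id = "dscam1_like",
             cluster_ids = c("4", "6", "9"))
}

# Four-cluster variant space (adds the 2-variant terminal cluster)
gm_dscam1_four_clusters <- function(seed = 12) {
  synth_gene(4, c(12, 48, 33, 2), exon_length = 60, similarity = 0.6,
             seed = seed, flank_length = 60, gene_id = "dscam1_space",
             cluster_ids = c("4", "6", "9", "17"))
}

# The four-ligamer loop-out toy: 26-nt ligamers (10-nt arms, 6-nt spacer)
# on a 307-nt template; footprints span 244 nt in total.
toy_loop_pool <- function(seed = 5) {
  set.seed(seed)
  template <- rand_seq(307)
  gm <- gene_model("toy", list(
    list(id = "R", type = "constitutive", sequence = template)))
  coords <- list( # up-arm start, down-arm start (10-nt arms)
    c(10, 40), c(50, 100), c(110, 170), c(180, 244))
  rows <- lapply(seq_along(coords), function(i) {
    us <- coords[[i]][1]; ds <- coords[[i]][2]
    ligzip:::ligamer_row(
      ligamer_id = paste0("L", i), kind = "internal", region_id = "R",
      variant_id = NA_character_,
      arm_up = substr(template, us + 1, us + 10),
      arm_down = substr(template, ds + 1, ds + 10),
      spacer = rand_seq(6), barcode = NA_character_,
      has_5p_phosphate = i > 1,
      targets = tibble::tibble(
        arm = c("up", "down"), region_id = "R", variant_id = NA_character_,
        start = c(us, ds), end = c(us + 10L, ds + 10L)))
  })
  list(gm = gm, pool = dplyr::bind_rows(rows))
}

# random small model for property tests: 1-4 clusters of 1-5 variants
random_model <- function(seed, max_clusters = 4, max_variants = 5,
                         exon_length = 100) {
  set.seed(seed)
  k <- sample.int(max_clusters, 1)
  sizes <- sample.int(max_variants, k, replace = TRUE)
  synth_gene(k, sizes, exon_length = exon_length, similarity = 0.5,
             seed = seed + 1000, flank_length = 100,
             gene_id = paste0("rand", seed))
}
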