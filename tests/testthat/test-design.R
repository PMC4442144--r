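cfg <- design_config()

test_that("terminal arm trimming matches an exhaustive prefix/suffix scan", {
  set.seed(10)
  for (i in 1:40) {
    region <- random_dna(1, sample(40:80, 1))
    for (end in c("five_prime", "three_prime")) {
      lg <- design_terminal_ligamer(region, end, config = cfg)
      arm <- lg$arm_up
      L <- nchar(region)
      # oracle: Tm of every candidate length, longest at or below tm_max
      lens <- 2:L
      cands <- if (end == "five_prime")
        substring(rep(region, length(lens)), L - lens + 1, L)
      else substr(rep(region, length(lens)), 1, lens)
      tms <- vapply(cands, oracle_tm, numeric(1), USE.NAMES = FALSE)
      ok <- which(tms <= cfg$tm_max)
      expect_equal(arm, cands[max(ok)])
      if (max(ok) < length(lens)) expect_gt(tms[max(ok) + 1], cfg$tm_max)
    }
  }
})

test_that("terminal design boundary cases behave as specified", {
  # a 30-nt all-AT region never reaches 65C: full arm, flagged exhausted
  lg <- design_terminal_ligamer(strrep("AT", 15), "five_prime", config = cfg)
  expect_equal(nchar(lg$arm_up), 30)
  expect_match(lg$flags, "exhausted")
  # GC-rich regions reach the threshold sooner than AT-rich ones
  gc <- "CCCACAGGATCTATGCAGAAGAATTCAGCGCCGGGTCCGC"
  at <- "TAGTAAAGTGGTTATAATTGTATGCTTAGAAGGTGCGTAT"
  expect_lt(nchar(design_terminal_ligamer(gc, "three_prime", config = cfg)$arm_up),
            nchar(design_terminal_ligamer(at, "three_prime", config = cfg)$arm_up))
  expect_error(design_terminal_ligamer("", "five_prime", config = cfg),
               class = "ligzip_error_design")
})

test_that("internal arms match the exhaustive feasibility oracle", {
  set.seed(11)
  lo <- cfg$arm_tm_target - cfg$arm_tm_tolerance
  hi <- cfg$arm_tm_target + cfg$arm_tm_tolerance
  n_checked <- 0
  for (i in 1:40) {
    up <- random_dna(1, sample(30:60, 1))
    dn <- random_dna(1, sample(30:60, 1))
    bc <- random_dna(1, 7)
    res <- tryCatch(design_internal_ligamer(up, dn, bc, cfg),
                    error = function(e) NULL)
    # oracle: enumerate every arm-length pair meeting both constraints
    budget <- cfg$max_len - nchar(bc)
    feas <- expand.grid(lu = 2:nchar(up), ld = 2:nchar(dn))
    tm_of <- function(s) oracle_tm(s)
    feas$ok <- vapply(seq_len(nrow(feas)), function(r) {
      tu <- tm_of(substr(up, 1, feas$lu[r]))
      td <- tm_of(substring(dn, nchar(dn) - feas$ld[r] + 1))
      tu >= lo && tu <= hi && td >= lo && td <= hi &&
        feas$lu[r] + feas$ld[r] <= budget &&
        feas$lu[r] >= cfg$min_arm_len && feas$ld[r] >= cfg$min_arm_len
    }, logical(1))
    feas <- feas[feas$ok, ]
    if (nrow(feas) == 0) {
      expect_null(res)
    } else {
      n_checked <- n_checked + 1
      # same tie-break: longest upstream arm, then longest downstream
      lu_best <- max(feas$lu)
      ld_best <- max(feas$ld[feas$lu == lu_best])
      expect_equal(nchar(res$arm_up), lu_best)
      expect_equal(nchar(res$arm_down), ld_best)
      expect_lte(nchar(res$sequence), cfg$max_len)
    }
  }
  expect_gt(n_checked, 10) # the battery must actually exercise feasible cases
})

test_that("internal design boundary cases behave as specified", {
  # identical AT-rich 25-nt targets with a 7-nt barcode: symmetric arms
  s <- "TGCGACATATTCCATAGTACGGTTA"
  lg <- design_internal_ligamer(s, s, "ACGTACG", cfg)
  expect_equal(nchar(lg$arm_up), nchar(lg$arm_down))
  # all-GC targets with an enormous barcode cannot satisfy the length bound
  expect_error(
    design_internal_ligamer(strrep("GC", 15), strrep("GC", 15),
                            random_dna(1, 48), cfg),
    class = "ligzip_error_infeasible")
})

test_that("barcode sets satisfy their invariants and are reproducible", {
  bs <- generate_barcodes(20, length = 7, min_hamming = 3, seed = 7)
  expect_length(bs, 20)
  expect_false(anyDuplicated(bs) > 0)
  expect_false(any(grepl("AAAA|CCCC|GGGG|TTTT", bs)))
  mat <- do.call(rbind, strsplit(unclass(bs), ""))
  for (i in 1:19) for (j in (i + 1):20)
    expect_gte(sum(mat[i, ] != mat[j, ]), 3)
  expect_identical(unclass(bs),
                   unclass(generate_barcodes(20, 7, 3, seed = 7)))
  expect_error(generate_barcodes(20, length = 1),
               class = "ligzip_error_capacity")
})

test_that("pool planning emits the expected ligamer counts", {
  # Fibronectin-like: 2 terminals + EDA + separating block + V120 + V95
  fn1 <- gm_fn1_like()
  pool_fn1 <- plan_pool(fn1, cfg)
  expect_equal(nrow(pool_fn1), 6)
  expect_equal(sum(pool_fn1$kind == "terminal_5p"), 1)
  expect_equal(sum(pool_fn1$kind == "terminal_3p"), 1)
  # degenerate: constitutive-only transcript needs only the terminals
  set.seed(20)
  gm0 <- gene_model("plain", list(
    list(id = "a", type = "constitutive", sequence = rand_seq(120)),
    list(id = "b", type = "constitutive", sequence = rand_seq(120))))
  expect_equal(nrow(plan_pool(gm0, cfg)), 2)
  # a variant region at the end of the span has no terminal anchor
  set.seed(21)
  bad <- gene_model("bad", list(
    list(id = "a", type = "constitutive", sequence = rand_seq(120)),
    list(id = "c", type = "cassette",
         variants = c(c.1 = rand_seq(100), c.2 = rand_seq(100)))))
  expect_error(plan_pool(bad, cfg), class = "ligzip_error_design")
})

test_that("ligamer count follows 2 + variants + separating blocks on random models", {
  for (seed in 1:8) {
    gm <- random_model(seed)
    pool <- plan_pool(gm, cfg)
    n_var <- sum(vapply(seq_len(nrow(gm)), function(i)
      if (gm$type[i] == "constitutive") 0L
      else sum(nzchar(gm$variants[[i]])), integer(1)))
    n_sep <- sum(gm$type[-c(1, nrow(gm))] == "constitutive")
    expect_equal(nrow(pool), 2 + n_var + n_sep)
    validate_pool(pool, cfg)
    expect_true(all(nchar(dplyr::filter(pool, kind == "internal")$sequence) <= 60))
  }
})

test_that("pool design is deterministic", {
  gm <- random_model(3)
  p1 <- plan_pool(gm, cfg)
  p2 <- plan_pool(gm, cfg)
  expect_identical(p1$sequence, p2$sequence)
  expect_identical(p1$barcode, p2$barcode)
})

test_that("dual pools differ in every internal barcode", {
  gm <- random_model(4)
  pools <- plan_dual_pools(gm, cfg)
  i1 <- dplyr::filter(pools[[1]], kind == "internal")
  i2 <- dplyr::filter(pools[[2]], kind == "internal")
  expect_identical(i1$ligamer_id, i2$ligamer_id)
  expect_true(all(i1$barcode != i2$barcode))
  expect_false(anyDuplicated(c(i1$barcode, i2$barcode)) > 0)
  # arms identical across pools; only the coding differs
  expect_identical(i1$arm_up, i2$arm_up)
})

test_that("specificity screen reports clean pools and flags degenerate clusters", {
  gm <- synth_gene(2, 3, exon_length = 120, similarity = 0, seed = 31,
                   flank_length = 120)
  pool <- plan_pool(gm, cfg)
  tx <- vapply(enumerate_isoforms(gm), function(k) isoform_sequence(gm, k),
               character(1))
  rep_clean <- screen_pool_specificity(pool, tx, gm, cfg)
  expect_true(all(rep_clean$gap > 0))
  expect_true(all(attr(rep_clean, "arm_hits")$off_target_hits == 0))
  # gap equals a brute-force all-pairs free-energy computation
  for (i in seq_len(nrow(rep_clean))) {
    lg <- pool[pool$ligamer_id == rep_clean$ligamer_id[i], ]
    vs <- gm$variants[[match(lg$region_id, gm$region_id)]]
    dg <- vapply(vs, function(s) {
      duplex_free_energy(reverse_complement(lg$arm_up),
                         substr(s, 1, nchar(lg$arm_up))) +
        duplex_free_energy(reverse_complement(lg$arm_down),
                           substring(s, nchar(s) - nchar(lg$arm_down) + 1))
    }, numeric(1))
    expect_equal(rep_clean$dg_cognate[i], unname(dg[lg$variant_id]))
    expect_equal(rep_clean$gap[i],
                 min(dg[names(dg) != lg$variant_id]) - dg[[lg$variant_id]])
  }
  # identical variants in a cluster collapse the gap to zero and get flagged
  gm_deg <- synth_gene(1, 2, exon_length = 120, similarity = 1, seed = 32,
                       flank_length = 120)
  pool_deg <- plan_pool(gm_deg, cfg)
  rep_deg <- screen_pool_specificity(
    pool_deg, vapply(enumerate_isoforms(gm_deg),
                     function(k) isoform_sequence(gm_deg, k), character(1)),
    gm_deg, cfg)
  expect_true(all(abs(rep_deg$gap) < 1e-9))
  expect_true(all(rep_deg$flagged))
})

test_that("pool export round-trips through TSV and FASTA", {
  gm <- random_model(5)
  pool <- plan_pool(gm, cfg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_pool_tsv(pool, tsv)
  write_pool_fasta(pool, fa)
  back <- utils::read.delim(tsv)
  expect_equal(back$sequence, pool$sequence)
  fa_seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(fa_seqs), stats::setNames(pool$sequence,
                                                      pool$ligamer_id))
})
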