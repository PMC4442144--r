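# end-to-end fixture shared across decode tests
decode_fixture <- function(seed = 30, n = 500, switch_rate = 0,
                           near_cognate_rate = 0, per_base_error = 0,
                           dual = TRUE, n_clusters = 3, variants = 3) {
  gm <- synth_gene(n_clusters, variants, exon_length = 110, similarity = 0.6,
                   seed = seed, flank_length = 110)
  pools <- if (dual) plan_dual_pools(gm) else plan_pool(gm)
  keys <- enumerate_isoforms(gm)
  mix <- simulate_isoform_mix(gm, stats::setNames(rep(1, length(keys)), keys),
                              n, seed = seed + 1)
  led <- simulate_ligation(mix, pools, gm, switch_rate, near_cognate_rate,
                           seed = seed + 2)
  reads <- simulate_reads(led, 250, per_base_error, seed = seed + 3)
  ps <- if (dual) pools else list(pools)
  ix <- lapply(ps, function(p) build_product_index(gm, p))
  list(gm = gm, pools = ps, ledger = led, reads = reads, index = ix)
}

test_that("mate merging reconstructs products and fails without overlap", {
  fx <- decode_fixture(seed = 31, n = 100)
  mg <- merge_pairs(fx$reads)
  expect_true(all(mg$merged))
  expect_identical(mg$sequence, fx$ledger$sequence)
  expect_equal(nchar(mg$sequence),
               nchar(fx$reads$r1) + nchar(fx$reads$r2) - mg$overlap_len)
  # disjoint halves have no qualifying overlap
  set.seed(32)
  a <- rand_seq(120); b <- rand_seq(120)
  bad <- tibble::tibble(read_id = "x", r1 = a, r2 = reverse_complement(b))
  expect_false(merge_pairs(bad)$merged)
})

test_that("error-free reads decode to their true isoforms exactly", {
  fx <- decode_fixture(seed = 33, n = 800)
  asg <- assign_reads(merge_pairs(fx$reads), fx$index, fx$pools)
  expect_true(all(asg$status == "assigned"))
  expect_identical(asg$isoform_key, fx$ledger$true_isoform_key)
})

test_that("decoder is exact at zero error across random models and seeds", {
  for (seed in c(41, 47, 53, 61, 71, 83)) {
    fx <- decode_fixture(seed = seed, n = 150,
                         n_clusters = 1 + seed %% 3,
                         variants = 2 + seed %% 3)
    asg <- assign_reads(merge_pairs(fx$reads), fx$index, fx$pools)
    expect_true(all(asg$status == "assigned"))
    expect_identical(asg$isoform_key, fx$ledger$true_isoform_key)
  }
})

test_that("decoder tolerates low per-base error with bounded arm mismatches", {
  hits <- 0; total <- 0
  for (seed in c(101, 103, 107)) {
    fx <- decode_fixture(seed = seed, n = 400, per_base_error = 0.005)
    asg <- assign_reads(merge_pairs(fx$reads), fx$index, fx$pools,
                        max_mismatch_per_segment = 2)
    ok <- asg$status == "assigned" &
      asg$isoform_key == fx$ledger$true_isoform_key
    hits <- hits + sum(ok, na.rm = TRUE); total <- total + nrow(asg)
  }
  expect_gte(hits / total, 0.99)
})

test_that("cross-pool barcodes mark a read as switched", {
  fx <- decode_fixture(seed = 35, n = 200, switch_rate = 0.1)
  asg <- assign_reads(merge_pairs(fx$reads), fx$index, fx$pools)
  truth_sw <- fx$ledger$artifact == "switched"
  expect_identical(asg$status == "switched", truth_sw)
  # hand-built chimera: pool-1 product with one segment recoded from pool 2
  ix1 <- fx$index[[1]]
  chain <- ix1$ligamer_chain[[1]]
  seqs1 <- stats::setNames(fx$pools[[1]]$sequence, fx$pools[[1]]$ligamer_id)
  seqs2 <- stats::setNames(fx$pools[[2]]$sequence, fx$pools[[2]]$ligamer_id)
  segs <- seqs1[chain]
  internal <- which(!is.na(fx$pools[[1]]$barcode[
    match(chain, fx$pools[[1]]$ligamer_id)]))
  segs[internal[2]] <- seqs2[chain[internal[2]]]
  chim <- tibble::tibble(read_id = "chimera", sequence = paste(segs, collapse = ""),
                         overlap_len = 10L, n_overlap_mismatches = 0L,
                         merged = TRUE)
  asg2 <- assign_reads(chim, fx$index, fx$pools)
  expect_equal(asg2$status, "switched")
})

test_that("a barcode contradicting its flanking arms is called near-cognate", {
  fx <- decode_fixture(seed = 37, n = 10, dual = FALSE)
  pool <- fx$pools[[1]]
  ix <- fx$index[[1]]
  # take a genuine product of variant A, then replace only the barcode of
  # one variant ligamer with a sibling variant's barcode: arms stay A's
  vl <- dplyr::filter(pool, !is.na(variant_id))
  cl <- vl$region_id[1]
  sibs <- dplyr::filter(vl, region_id == cl)
  lig_a <- sibs[1, ]; lig_b <- sibs[2, ]
  prod <- ix[grepl(lig_a$variant_id, ix$isoform_key, fixed = TRUE), ][1, ]
  read <- sub(lig_a$barcode, lig_b$barcode, prod$product_sequence, fixed = TRUE)
  mg <- tibble::tibble(read_id = "nc", sequence = read, overlap_len = 10L,
                       n_overlap_mismatches = 0L, merged = TRUE)
  asg <- assign_reads(mg, fx$index, fx$pools)
  expect_equal(asg$status, "near_cognate")
})

test_that("status tallies conserve the number of read pairs", {
  fx <- decode_fixture(seed = 39, n = 300, switch_rate = 0.05,
                       per_base_error = 0.02)
  asg <- assign_reads(merge_pairs(fx$reads), fx$index, fx$pools)
  ct <- count_isoforms(asg, "s1")
  tot <- attr(ct, "status_totals")
  expect_equal(sum(tot$n), nrow(fx$reads))
  expect_equal(sum(ct$count), tot$n[tot$status == "assigned"])
  # failed merges are explicit unassigned losses
  broken <- merge_pairs(fx$reads)
  broken$merged[1:5] <- FALSE
  asg2 <- assign_reads(broken, fx$index, fx$pools)
  expect_true(all(asg2$status[1:5] == "unassigned"))
})

test_that("count tables tally statuses separately from assignments", {
  asg <- structure(
    tibble::tibble(
      read_id = paste0("r", 1:4),
      status = c("assigned", "assigned", "assigned", "ambiguous"),
      isoform_key = c("a", "a", "b", NA),
      pool_labels = "pool1",
      seg_mismatches = list(integer(0))),
    class = c("assignment_table", class(tibble::tibble())))
  ct <- count_isoforms(asg, "toy")
  expect_equal(sum(ct$count), 3)
  expect_equal(sum(attr(ct, "status_totals")$n), 4)
  # empty input gives an empty table with zero totals
  ct0 <- count_isoforms(asg[0, ], "toy")
  expect_equal(nrow(ct0), 0)
  expect_equal(sum(attr(ct0, "status_totals")$n), 0)
})

test_that("switch reports quantify dual-pool chimeras and degrade gracefully", {
  fx0 <- decode_fixture(seed = 43, n = 400, switch_rate = 0)
  asg0 <- assign_reads(merge_pairs(fx0$reads), fx0$index, fx0$pools)
  rep0 <- switch_report(asg0)
  expect_equal(attr(rep0, "n_switched"), 0)
  fx <- decode_fixture(seed = 45, n = 2000, switch_rate = 0.02)
  asg <- assign_reads(merge_pairs(fx$reads), fx$index, fx$pools)
  repd <- switch_report(asg)
  expect_true(attr(repd, "applicable"))
  expect_equal(attr(repd, "n_switched"), sum(fx$ledger$artifact == "switched"))
  expect_true(all(grepl("pool1", repd$pattern) & grepl("pool2", repd$pattern)))
  # single-pool data: report marked not applicable
  fx1 <- decode_fixture(seed = 49, n = 100, dual = FALSE)
  asg1 <- assign_reads(merge_pairs(fx1$reads), fx1$index, fx1$pools)
  expect_false(attr(switch_report(asg1), "applicable"))
})
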