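mk_counts <- function(keys, counts, sample = "s1") {
  structure(tibble::tibble(isoform_key = keys, sample = sample,
                           count = as.integer(counts)),
            class = c("count_table", class(tibble::tibble())))
}

gm22 <- local({
  set.seed(60)
  gene_model("g22", list(
    list(id = "up", type = "constitutive", sequence = rand_seq(60)),
    list(id = "A", type = "cassette",
         variants = c(A.1 = rand_seq(60), A.2 = rand_seq(60))),
    list(id = "m", type = "constitutive", sequence = rand_seq(60)),
    list(id = "B", type = "cassette",
         variants = c(B.1 = rand_seq(60), B.2 = rand_seq(60),
                      B.3 = rand_seq(60))),
    list(id = "dn", type = "constitutive", sequence = rand_seq(60))))
})

test_that("marginal frequencies normalize and match direct tallies", {
  # a single observed isoform gives unit marginals
  m1 <- marginal_exon_freq(mk_counts("A.1|B.2", 7), gm22)
  expect_equal(m1$freq[m1$variant_id == "A.1"], 1)
  expect_equal(m1$freq[m1$variant_id == "B.2"], 1)
  # uniform 2x2 counts give 0.5 everywhere
  keys4 <- c("A.1|B.1", "A.1|B.2", "A.2|B.1", "A.2|B.2")
  mu <- marginal_exon_freq(mk_counts(keys4, rep(5, 4)), gm22)
  expect_true(all(abs(mu$freq[mu$cluster_id == "A"] - 0.5) < 1e-12))
  # random tables: marginals equal per-variant sums over total
  set.seed(61)
  keys <- enumerate_isoforms(gm22)
  for (rep in 1:5) {
    cnt <- rpois(length(keys), 20)
    m <- marginal_exon_freq(mk_counts(keys, cnt), gm22)
    for (i in seq_len(nrow(m))) {
      direct <- sum(cnt[grepl(m$variant_id[i], keys, fixed = TRUE)])
      expect_equal(m$count[i], direct)
    }
    sums <- tapply(m$freq, m$cluster_id, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("expected combination frequencies are products of marginals", {
  keys <- enumerate_isoforms(gm22)
  set.seed(62)
  m <- marginal_exon_freq(mk_counts(keys, rpois(6, 30) + 1), gm22)
  ex <- expected_combinations(m, c("A", "B"))
  expect_equal(sum(ex$expected_freq), 1, tolerance = 1e-9)
  fa <- stats::setNames(m$freq[m$cluster_id == "A"],
                        m$variant_id[m$cluster_id == "A"])
  fb <- stats::setNames(m$freq[m$cluster_id == "B"],
                        m$variant_id[m$cluster_id == "B"])
  for (i in seq_len(nrow(ex))) {
    p <- strsplit(ex$combination_key[i], "|", fixed = TRUE)[[1]]
    expect_equal(ex$expected_freq[i], unname(fa[p[1]] * fb[p[2]]))
  }
  # uniform marginals (1/2, 1/2) x (1/3, 1/3, 1/3): every pair is 1/6
  mu <- marginal_exon_freq(mk_counts(keys, rep(10, 6)), gm22)
  exu <- expected_combinations(mu, c("A", "B"))
  expect_true(all(abs(exu$expected_freq - 1 / 6) < 1e-12))
})

test_that("marginalizing three-way expectations reproduces pairwise ones", {
  set.seed(63)
  gm3 <- synth_gene(3, c(2, 3, 2), exon_length = 60, similarity = 0.5,
                    seed = 64, flank_length = 60)
  keys <- enumerate_isoforms(gm3)
  m <- marginal_exon_freq(mk_counts(keys, rpois(length(keys), 15) + 1), gm3)
  ex3 <- expected_combinations(m, c("c1", "c2", "c3"))
  ex2 <- expected_combinations(m, c("c1", "c3"))
  proj <- vapply(strsplit(ex3$combination_key, "|", fixed = TRUE),
                 function(p) paste(p[c(1, 3)], collapse = "|"), character(1))
  marg <- tapply(ex3$expected_freq, proj, sum)
  expect_equal(as.vector(marg[ex2$combination_key]), ex2$expected_freq,
               tolerance = 1e-12)
})

test_that("coordination tests flag strong deviations and not exact fits", {
  keys <- enumerate_isoforms(gm22)
  # observed exactly proportional to expected: p = 1 everywhere
  cnt <- mk_counts(keys, c(10, 10, 10, 20, 20, 20) * 6)
  m <- marginal_exon_freq(cnt, gm22)
  ex <- expected_combinations(m, c("A", "B"))
  obs <- observed_combinations(cnt, gm22, c("A", "B"))
  ct <- coordination_test(obs, ex)
  expect_true(all(ct$p > 0.999))
  expect_false(any(ct$flagged))
  # one combination forced to ten times its expectation is flagged
  n <- 100000
  ex_forced <- tibble::tibble(
    combination_key = c("x", "y", "z", "w"),
    expected_freq = c(0.005, 0.195, 0.4, 0.4))
  obs_forced <- tibble::tibble(
    combination_key = c("x", "y", "z", "w"),
    count = as.integer(round(c(0.05, 0.15, 0.4, 0.4) * n)))
  ctf <- coordination_test(obs_forced, ex_forced, total = n)
  expect_true(ctf$flagged[ctf$combination_key == "x"])
  expect_true(all(ctf$q >= ctf$p))
  expect_error(coordination_test(obs_forced[0, ], ex_forced, total = 0),
               class = "ligzip_error_stats")
})

test_that("flag rate under the independence null is controlled", {
  set.seed(65)
  keys <- enumerate_isoforms(gm22)
  pA <- c(0.6, 0.4); pB <- c(0.5, 0.3, 0.2)
  p_joint <- as.vector(outer(pB, pA)) # column-major matches sorted keys
  any_flag <- logical(500)
  for (r in 1:500) {
    cnt <- as.integer(stats::rmultinom(1, 2000, p_joint))
    tab <- mk_counts(keys, cnt)
    m <- marginal_exon_freq(tab, gm22)
    ex <- expected_combinations(m, c("A", "B"))
    obs <- observed_combinations(tab, gm22, c("A", "B"))
    ct <- coordination_test(obs, ex)
    any_flag[r] <- any(ct$flagged)
  }
  expect_lte(mean(any_flag), 0.07)
})

test_that("replicate correlation matches closed form and detects noise", {
  keys <- paste0("k", 1:5)
  a <- mk_counts(keys, c(2, 5, 9, 14, 30))
  b <- mk_counts(keys, c(3, 4, 11, 13, 28))
  rc <- replicate_correlation(a, b, pseudo_count = 1)
  # textbook Pearson on the log-transformed toy table, computed by hand
  x <- log(c(2, 5, 9, 14, 30) + 1); y <- log(c(3, 4, 11, 13, 28) + 1)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rc$r, r_hand, tolerance = 1e-12)
  expect_equal(rc$p, 2 * stats::pnorm(-abs(atanh(r_hand)) * sqrt(5 - 3)),
               tolerance = 1e-12)
  # identical tables correlate perfectly
  expect_equal(replicate_correlation(a, a)$r, 1)
  # independent tables do not
  set.seed(66)
  big <- paste0("k", 1:1000)
  ra <- mk_counts(big, rpois(1000, 20))
  rb <- mk_counts(big, rpois(1000, 20))
  expect_lt(abs(replicate_correlation(ra, rb)$r), 0.1)
  expect_error(replicate_correlation(a[1:3, ], b[1:3, ]),
               class = "ligzip_error_stats")
})

test_that("tidiers and plots expose results in standard shapes", {
  keys <- enumerate_isoforms(gm22)
  tab <- mk_counts(keys, c(12, 30, 18, 25, 40, 9))
  m <- marginal_exon_freq(tab, gm22)
  ex <- expected_combinations(m, c("A", "B"))
  obs <- observed_combinations(tab, gm22, c("A", "B"))
  ct <- coordination_test(obs, ex)
  expect_s3_class(tidy(ct), "tbl_df")
  g <- glance(ct)
  expect_equal(g$n_combinations, 6)
  expect_s3_class(autoplot(ct), "ggplot")
  expect_s3_class(plot_exon_usage(m), "ggplot")
  rc <- replicate_correlation(tab, tab)
  expect_s3_class(tidy(rc), "tbl_df")
})
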