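test_that("uncorrected heterozygosities match hand-derivable values", {
  # identical 0.5/0.5 frequencies
  h <- heterozygosities(rbind(c(10, 10), c(10, 10)))
  expect_equal(h$hs, 0.5)
  expect_equal(h$ht, 0.5)
  # fixed difference
  h <- heterozygosities(rbind(c(20, 0), c(0, 20)))
  expect_equal(h$hs, 0)
  expect_equal(h$ht, 0.5)
  # worked example: p1 = 0.25, p2 = 0.75
  h <- heterozygosities(rbind(c(30, 10), c(10, 30)))
  expect_equal(h$hs, 0.375)
  expect_equal(h$ht, 0.5)
  # a population with zero called copies is undefined
  expect_null(heterozygosities(rbind(c(0, 0), c(10, 10))))
})

test_that("G_ST, G'_ST and Jost's D reproduce the worked triple", {
  expect_equal(gst(0.375, 0.5), 0.25)
  expect_equal(gst_hedrick(0.25, 0.375, k = 2), 0.25 * 1.375 / 0.625)
  expect_equal(gst_hedrick(0.25, 0.375, k = 2), 0.55)
  expect_equal(jost_d(0.375, 0.5, k = 2), 2 * 0.125 / 0.625)
  expect_equal(jost_d(0.375, 0.5, k = 2), 0.4)
  # fixed difference: all three maximal
  expect_equal(gst(0, 0.5), 1)
  expect_equal(gst_hedrick(1, 0, k = 2), 1)
  expect_equal(jost_d(0, 0.5, k = 2), 1)
  # no differentiation: all three zero
  expect_equal(gst(0.4, 0.4), 0)
  expect_equal(gst_hedrick(0, 0.4, k = 2), 0)
  expect_equal(jost_d(0.4, 0.4, k = 2), 0)
  # monomorphic: undefined
  expect_true(is.na(gst(0, 0)))
})

test_that("uncorrected invariants: ht >= hs, gst in [0,1], ordering", {
  set.seed(31)
  for (i in 1:200) {
    counts <- matrix(sample(0:30, 4, replace = TRUE), 2, 2)
    if (any(rowSums(counts) == 0)) next
    h <- heterozygosities(counts)
    expect_gte(h$ht, h$hs - 1e-12)
    if (h$ht > 0) {
      g <- gst(h$hs, h$ht)
      expect_gte(g, -1e-12)
      expect_lte(g, 1 + 1e-12)
      if (h$hs > 0 && h$hs < 1 && g > 0) {
        expect_gte(gst_hedrick(g, h$hs), g - 1e-12)
        expect_gte(jost_d(h$hs, h$ht), g * 1e-9)  # positive whenever g > 0
      }
    }
  }
})

test_that("phi_st: fixed difference gives 1, equal frequencies give <= 0", {
  expect_equal(phi_st(rbind(c(20, 0), c(0, 20))), 1)
  # identical allele frequencies and counts: no among-population variance
  expect_lte(phi_st(rbind(c(10, 10), c(10, 10))), 0)
  # degenerate: all alleles identical
  expect_true(is.na(phi_st(rbind(c(20, 0), c(20, 0)))))
})

test_that("phi_st equals brute-force AMOVA on small instances", {
  # spec worked example: A = {1,1,1,0}, B = {0,0,0,1}
  a <- c(1, 1, 1, 0); b <- c(0, 0, 0, 1)
  counts <- rbind(c(sum(a == 0), sum(a == 1)), c(sum(b == 0), sum(b == 1)))
  expect_equal(phi_st(counts), oracle_phi_st(list(a, b)), tolerance = 1e-10)
  # random <= 20-allele instances
  set.seed(77)
  tried <- 0
  while (tried < 60) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    a <- sample(0:1, n1, replace = TRUE)
    b <- sample(0:1, n2, replace = TRUE)
    if (sum(c(a, b)) == 0 || sum(c(a, b)) == n1 + n2) next
    tried <- tried + 1
    counts <- rbind(c(sum(a == 0), sum(a == 1)),
                    c(sum(b == 0), sum(b == 1)))
    expect_equal(phi_st(counts), oracle_phi_st(list(a, b)),
                 tolerance = 1e-10)
  }
})

test_that("fisher_exact_p matches the worked example and full enumeration", {
  # [[2,0],[0,2]]: extreme mass 2/6
  expect_equal(fisher_exact_p(rbind(c(2, 0), c(0, 2))), 1 / 3,
               tolerance = 1e-12)
  # most probable table: p = 1
  expect_equal(fisher_exact_p(rbind(c(5, 5), c(5, 5))), 1)
  # empty margin convention
  expect_equal(suppressMessages(fisher_exact_p(rbind(c(0, 0), c(3, 2)))), 1)
  # random tables with margins <= 30 vs enumeration oracle and fisher.test
  set.seed(13)
  for (i in 1:100) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2, 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 ||
        sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) next
    p <- fisher_exact_p(tab)
    expect_equal(p, oracle_fisher(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("bonferroni_flag uses a strict alpha/m threshold", {
  expect_equal(bonferroni_flag(0.04, m = 1), TRUE)
  expect_equal(bonferroni_flag(c(0.0004, 0.0005), m = 100), c(TRUE, FALSE))
  expect_equal(bonferroni_flag(numeric(0)), logical(0))
  set.seed(3)
  p <- stats::runif(50, 0, 0.1)
  expect_equal(bonferroni_flag(p), p < 0.05 / 50)
})

test_that("corrected estimators are unbiased where the naive ones are not", {
  # fixed truth: two populations at p = 0.3 and 0.5, 24 diploids each,
  # HWE sampling; true hs = (0.42 + 0.5)/2 = 0.46, true ht = 1 - 2*0.4^2
  set.seed(41)
  reps <- 400
  hs_corr <- ht_corr <- hs_unc <- numeric(reps)
  for (r in seq_len(reps)) {
    g1 <- stats::rbinom(24, 2, 0.3)
    g2 <- stats::rbinom(24, 2, 0.5)
    counts <- rbind(c(48 - sum(g1), sum(g1)), c(48 - sum(g2), sum(g2)))
    n_het <- c(sum(g1 == 1), sum(g2 == 1))
    h <- heterozygosities(counts, corrected = TRUE, n_het = n_het)
    hu <- heterozygosities(counts)
    hs_corr[r] <- h$hs; ht_corr[r] <- h$ht; hs_unc[r] <- hu$hs
  }
  true_hs <- mean(c(2 * 0.3 * 0.7, 2 * 0.5 * 0.5))
  true_ht <- 1 - (0.4^2 + 0.6^2)
  expect_equal(mean(hs_corr), true_hs, tolerance = 0.01)
  expect_equal(mean(ht_corr), true_ht, tolerance = 0.01)
  # the naive estimator is visibly biased low at this sample size
  expect_lt(mean(hs_unc), true_hs - 0.003)
})

test_that("snp_divergence excludes monomorphic sites from the family", {
  geno <- rbind(c(rep(1L, 8)),          # polymorphic
                c(rep(0L, 8)),          # monomorphic -> excluded
                c(rep(2L, 4), rep(0L, 4)))  # fixed difference
  ss <- make_snp_set("g1", c(10L, 50L, 90L), geno,
                     populations = rep(c("MN", "ND"), each = 4))
  div <- suppressMessages(snp_divergence(ss, corrected = FALSE))
  expect_equal(nrow(div), 2)
  expect_equal(div$pos, c(10L, 90L))
  expect_equal(div$gst[2], 1)
  # m = 2, not 3: flags computed against alpha/2
  expect_equal(div$significant, div$fisher_p < 0.05 / 2)
  expect_error(snp_divergence(make_snp_set("g", 1L, matrix(1L, 1, 4),
                                           populations = rep("MN", 4))),
               "exactly 2 populations")
})

test_that("summarize_divergence reports both aggregation conventions", {
  div <- data.frame(unigene_id = c("a", "a", "b"), pos = 1:3,
                    hs = c(0.3, 0.2, 0.4), ht = c(0.4, 0.25, 0.45),
                    gst = c(0.1, 0.3, 0.2), significant = c(TRUE, TRUE, FALSE))
  s <- summarize_divergence(div)
  expect_equal(s$mean_gst, 0.2)
  expect_equal(s$global_gst, (mean(div$ht) - mean(div$hs)) / mean(div$ht))
  expect_equal(s$n_significant_snps, 2)
  expect_equal(s$n_significant_genes, 1)
  expect_equal(s$gst_range_significant, c(0.1, 0.3))
  s0 <- summarize_divergence(div[div$gst > 1, ])
  expect_equal(s0$n_significant_snps, 0)
  expect_true(all(is.na(s0$gst_range_significant)))
})
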