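test_that("GQ masking respects the inclusive 'at least 20' boundary", {
  # 5 calls at GQ 10, 19, 20, 21, 99 on one site
  ss <- make_snp_set("g1", 1L, matrix(1L, 1, 5), gq = 99,
                     populations = c("MN", "MN", "MN", "ND", "ND"))
  ss$gq[1, ] <- c(10, 19, 20, 21, 99)
  out <- mask_low_quality_genotypes(ss, 20)
  expect_equal(attr(out, "n_masked"), 2)
  expect_equal(is.na(out$geno[1, ]),
               c(s01 = TRUE, s02 = TRUE, s03 = FALSE, s04 = FALSE,
                 s05 = FALSE))
})

test_that("cluster rule matches the all-window brute force", {
  # worked example: span of {1,10,20,34} is 34 <= 35 and count 4 > 3
  expect_equal(flag_snp_clusters(rep("g", 4), c(1L, 10L, 20L, 34L)),
               rep(TRUE, 4))
  expect_equal(flag_snp_clusters(rep("g", 3), c(1L, 10L, 20L)),
               rep(FALSE, 3))
  expect_equal(flag_snp_clusters(rep("g", 4), c(1L, 40L, 80L, 120L)),
               rep(FALSE, 4))
  # property: random position sets across several unigenes
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    unigene <- sample(c("a", "b"), n, replace = TRUE)
    pos <- integer(n)
    for (g in unique(unigene)) {
      k <- sum(unigene == g)
      pos[unigene == g] <- sample.int(200, k)
    }
    expect_equal(flag_snp_clusters(unigene, pos),
                 oracle_cluster_flags(unigene, pos),
                 info = paste("rep", rep))
  }
})

test_that("site filters: boundaries and worked MAF example", {
  # fs == 30 exactly is kept ("greater than 30" is strict)
  ss <- make_snp_set("g1", c(10L, 200L), rbind(rep(1L, 32), rep(1L, 32)),
                     fs = c(30, 30.01), qd = 20, depth = 100)
  out <- apply_site_filters(ss, filter_thresholds(min_called_per_pop = 16))
  expect_equal(unname(out$removed_by_rule["fs"]), 1L)
  expect_equal(out$kept$sites$pos, 10L)

  # 96 individuals all called, 1 alt copy of 192: MAF 0.0052 < 0.01
  g <- matrix(0L, 1, 96); g[1, 1] <- 1L
  ss <- make_snp_set("g1", 1L, g)
  out <- apply_site_filters(ss, filter_thresholds())
  expect_equal(unname(out$removed_by_rule["maf"]), 1L)

  # 15 called in population A (one of 16 missing), 48 in B: presence rule
  g <- matrix(1L, 1, 64)
  g[1, 16] <- NA
  ss <- make_snp_set("g1", 1L, g,
                     populations = rep(c("MN", "ND"), each = 32))
  g2 <- ss$geno; g2[1, 17:32] <- NA   # MN down to 15 called
  ss$geno <- g2
  out <- apply_site_filters(ss, filter_thresholds())
  expect_equal(unname(out$removed_by_rule["presence"]), 1L)
})

test_that("strict_info removes records with missing INFO, lax keeps them", {
  ss <- make_snp_set("g1", c(5L, 400L), rbind(rep(1L, 40), rep(1L, 40)),
                     fs = c(NA, 2), qd = 20, depth = 100,
                     populations = rep(c("MN", "ND"), each = 20))
  strict <- apply_site_filters(ss, filter_thresholds())
  expect_equal(unname(strict$removed_by_rule["fs"]), 1L)
  lax <- apply_site_filters(ss, filter_thresholds(strict_info = FALSE))
  expect_equal(sum(lax$removed_by_rule), 0L)
})

test_that("filter cascade equals the naive oracle on random fixtures", {
  set.seed(202)
  th <- filter_thresholds()
  for (rep in 1:8) {
    n <- sample(20:50, 1)
    nsamp <- 40
    geno <- matrix(sample(c(0:2, NA), n * nsamp, replace = TRUE,
                          prob = c(.4, .3, .2, .1)), n, nsamp)
    ss <- make_snp_set(
      unigene = sample(c("a", "b", "c"), n, replace = TRUE),
      pos = as.integer(sample.int(500, n)),
      geno = geno,
      fs = round(stats::rexp(n, 1 / 15), 1),
      qd = round(stats::runif(n, 0, 10), 1),
      depth = sample(10:120, n, replace = TRUE),
      populations = rep(c("MN", "ND"), each = 20)
    )
    # avoid duplicated positions within a unigene
    key <- paste(ss$sites$unigene_id, ss$sites$pos)
    ss <- subset_sites(ss, !duplicated(key))
    got <- apply_site_filters(ss, th)
    want <- oracle_filter(ss, th)
    expect_equal(site_key(got$kept), site_key(ss)[want$keep])
    expect_equal(unname(got$removed_by_rule[c("fs", "qd", "cluster", "depth",
                                              "presence", "maf")]),
                 unname(c(sum(want$rule == "fs", na.rm = TRUE),
                          sum(want$rule == "qd", na.rm = TRUE),
                          sum(want$rule == "cluster", na.rm = TRUE),
                          sum(want$rule == "depth", na.rm = TRUE),
                          sum(want$rule == "presence", na.rm = TRUE),
                          sum(want$rule == "maf", na.rm = TRUE))))
  }
})

test_that("conservation, idempotence and monotonicity properties hold", {
  sim <- simulate_dataset(simulation_config(n_genes = 60, seed = 5))
  ss <- mask_low_quality_genotypes(sim$snps)
  th <- filter_thresholds()
  out <- apply_site_filters(ss, th)
  # conservation
  expect_equal(n_sites(out$kept) + sum(out$removed_by_rule), n_sites(ss))
  # idempotence
  again <- apply_site_filters(out$kept, th)
  expect_equal(sum(again$removed_by_rule), 0L)
  expect_equal(site_key(again$kept), site_key(out$kept))
  # monotonicity: tightening any threshold never increases |kept|
  tighter <- list(
    filter_thresholds(fs_max = 20), filter_thresholds(qd_min = 5),
    filter_thresholds(cluster_max_snps = 2), filter_thresholds(depth_min = 60),
    filter_thresholds(gq_min = 40, min_called_per_pop = 20),
    filter_thresholds(maf_min = 0.05)
  )
  for (t2 in tighter) {
    ss2 <- mask_low_quality_genotypes(sim$snps, t2$gq_min)
    expect_lte(n_sites(apply_site_filters(ss2, t2)$kept), n_sites(out$kept))
  }
})

test_that("planted FS violations are removed exactly, by rule 1", {
  cfg <- simulation_config(n_genes = 80, fs_rate = 0.05, qd_rate = 0,
                           cluster_rate = 0, missing_rate = 0,
                           gq_low_prob = 0, depth_mean = 200, seed = 9)
  sim <- simulate_dataset(cfg)
  planted <- sim$truth == "fs"
  out <- apply_site_filters(mask_low_quality_genotypes(sim$snps),
                            filter_thresholds(depth_min = 0, maf_min = 0))
  expect_equal(unname(out$removed_by_rule["fs"]), sum(planted))
  expect_equal(setdiff(site_key(sim$snps), site_key(out$kept)),
               site_key(sim$snps)[planted])
})

test_that("invalid thresholds raise configuration errors", {
  expect_error(filter_thresholds(fs_max = -1), "configuration error")
  expect_error(filter_thresholds(cluster_window = 0), "cluster_window")
})
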