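# Independent oracle implementations, deliberately naive: loops and
# enumeration only, no code shared with the package internals.

# --- Fisher exact: full enumeration over all tables with fixed margins ----
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  total <- r1 + r2
  prob_of <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(0)
    exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(total, c1))
  }
  p_obs <- prob_of(tab[1, 1])
  p <- 0
  for (a in 0:min(r1, c1)) {
    pa <- prob_of(a)
    if (pa <= p_obs * (1 + 1e-7)) p <- p + pa
  }
  min(1, p)
}

# --- AMOVA phi_ST: brute force over all allele pairs ----------------------
# alleles: list of 0/1 vectors, one per population
oracle_phi_st <- function(alleles) {
  x <- unlist(alleles)
  N <- length(x)
  k <- length(alleles)
  n_i <- lengths(alleles)
  d2 <- outer(x, x, function(a, b) as.numeric(a != b))
  ssd_total <- sum(d2[upper.tri(d2)]) / N
  ssd_within <- 0
  for (g in alleles) {
    dg <- outer(g, g, function(a, b) as.numeric(a != b))
    ssd_within <- ssd_within + sum(dg[upper.tri(dg)]) / length(g)
  }
  ssd_among <- ssd_total - ssd_within
  ms_among <- ssd_among / (k - 1)
  ms_within <- ssd_within / (N - k)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  sigma_a <- (ms_among - ms_within) / n0
  sigma_a / (sigma_a + ms_within)
}

# --- site pi: enumerate unordered pairs of allele copies ------------------
oracle_site_pi <- function(counts) {
  copies <- rep(seq_along(counts), counts)
  n <- length(copies)
  if (n < 2) return(NA_real_)
  diff <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (copies[i] != copies[j]) diff <- diff + 1
  }
  diff / tot
}

# --- Tajima's D: explicit 1989 pipeline with integer harmonic sums --------
oracle_tajima <- function(S, k_hat, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- SNP cluster rule: brute-force scan over every possible window --------
oracle_cluster_flags <- function(unigene, pos, window = 35, max_snps = 3) {
  removed <- logical(length(pos))
  for (g in unique(unigene)) {
    idx <- which(unigene == g)
    p <- pos[idx]
    for (w in 1:max(p)) {
      inside <- which(p >= w & p <= w + window - 1)
      if (length(inside) > max_snps) removed[idx[inside]] <- TRUE
    }
  }
  removed
}

# --- naive reimplementation of the full site-filter cascade ---------------
oracle_filter <- function(ss, th) {
  keep <- logical(transpopgen:::n_sites(ss))
  rule <- rep(NA_character_, length(keep))
  cl <- oracle_cluster_flags(ss$sites$unigene_id, ss$sites$pos,
                             th$cluster_window, th$cluster_max_snps)
  pops <- split(seq_len(nrow(ss$samples)), ss$samples$population)
  for (i in seq_along(keep)) {
    s <- ss$sites[i, ]
    g <- ss$geno[i, ]
    fail <- function(x, cmp) (!is.na(x) && cmp(x)) || (is.na(x) && th$strict_info)
    r <- NULL
    if (fail(s$fs, function(x) x > th$fs_max)) r <- "fs"
    else if (fail(s$qd, function(x) x < th$qd_min)) r <- "qd"
    else if (cl[i]) r <- "cluster"
    else if (fail(s$depth, function(x) x < th$depth_min)) r <- "depth"
    else {
      called <- sapply(pops, function(j) sum(!is.na(g[j])))
      if (any(called < th$min_called_per_pop)) r <- "presence"
      else {
        alt <- sum(g, na.rm = TRUE)
        tot <- 2 * sum(!is.na(g))
        f <- if (tot > 0) alt / tot else 0
        if (tot == 0 || min(f, 1 - f) < th$maf_min) r <- "maf"
      }
    }
    if (is.null(r)) keep[i] <- TRUE else rule[i] <- r
  }
  list(keep = keep, rule = rule)
}

# --- percentile with linear interpolation (type 7), from first principles -
oracle_percentile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# --- tiny snp_set builder for fixtures ------------------------------------
make_snp_set <- function(unigene, pos, geno, ref = NULL, alt = NULL,
                         fs = 1, qd = 20, depth = 100, gq = 99,
                         populations = NULL) {
  geno <- as.matrix(geno)
  n <- length(pos)
  nsamp <- ncol(geno)
  if (is.null(populations)) {
    populations <- rep(c("MN", "ND"), each = nsamp / 2)
  }
  sites <- data.frame(
    unigene_id = rep_len(unigene, n), pos = pos,
    ref = rep_len(ref %||% "A", n), alt = rep_len(alt %||% "G", n),
    fs = rep_len(fs, n), qd = rep_len(qd, n), depth = rep_len(depth, n),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(nsamp)),
                        population = populations, stringsAsFactors = FALSE)
  gqm <- matrix(rep_len(gq, n * nsamp), n, nsamp)
  snp_set(sites, geno, gqm, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype matrix (sites x samples) with given per-population alt dosages
geno_from_counts <- function(alt_per_pop, n_per_pop) {
  # alt_per_pop: list of dosage vectors, one per population
  do.call(cbind, lapply(alt_per_pop, function(v) matrix(v, nrow = 1)))
}
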