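#' Within- and total expected heterozygosity at one site
#'
#' Uncorrected ("textbook") form: Hs is the across-population mean of
#' 1 - sum(p_a^2), Ht uses the unweighted across-population mean allele
#' frequencies. The corrected form applies the Nei-Chesser small-sample
#' estimators: with n-tilde the harmonic mean number of individuals sampled
#' per population, Ho the mean observed heterozygote frequency, and k
#' populations,
#' \deqn{\hat H_S = \frac{\tilde n}{\tilde n - 1}\Big(H_S - \frac{H_o}{2\tilde n}\Big)}
#' \deqn{\hat H_T = H_T + \frac{\hat H_S}{k\tilde n} - \frac{H_o}{2 k \tilde n}}
#' The corrected estimators are (nearly) unbiased and may produce hs > ht or
#' small negative differentiation downstream; values are reported unclamped.
#'
#' @param counts matrix, populations x 2 (ref count, alt count) of called
#'   allele copies
#' @param corrected use the Nei-Chesser estimators (needs `n_het`)
#' @param n_het heterozygous-individual count per population (for corrected)
#' @return list `(hs, ht)`; `NULL` if any population has zero called copies
#' @export
heterozygosities <- function(counts, corrected = FALSE, n_het = NULL) {
  counts <- as.matrix(counts)
  n <- rowSums(counts)
  if (any(n == 0)) return(NULL)
  p <- counts / n
  hs_obs <- mean(1 - rowSums(p^2))
  pbar <- colMeans(p)
  ht_obs <- 1 - sum(pbar^2)
  if (!corrected) return(list(hs = hs_obs, ht = ht_obs))
  if (is.null(n_het)) stop("corrected estimator needs heterozygote counts")
  n_ind <- n / 2
  if (any(n_ind < 1)) return(NULL)
  k <- nrow(counts)
  n_harm <- 1 / mean(1 / n_ind)
  ho <- mean(n_het / n_ind)
  hs <- n_harm / (n_harm - 1) * (hs_obs - ho / (2 * n_harm))
  ht <- ht_obs + hs / (k * n_harm) - ho / (2 * k * n_harm)
  list(hs = hs, ht = ht)
}

#' Nei's G_ST
#' @param hs within-population expected heterozygosity
#' @param ht total expected heterozygosity (> 0)
#' @return (ht - hs) / ht; `NA` when ht <= 0 (monomorphic site)
#' @export
gst <- function(hs, ht) ifelse(ht > 0, (ht - hs) / ht, NA_real_)

#' Hedrick's G'_ST
#'
#' G_ST rescaled by its maximum given Hs, comparable across loci of
#' different diversity: G'_ST = G_ST (k - 1 + Hs) / ((k - 1)(1 - Hs)).
#'
#' @param gst_value Nei's G_ST
#' @param hs within-population expected heterozygosity (< 1)
#' @param k number of populations
#' @return G'_ST; `NA` when hs >= 1
#' @export
gst_hedrick <- function(gst_value, hs, k = 2) {
  ifelse(hs < 1, gst_value * (k - 1 + hs) / ((k - 1) * (1 - hs)), NA_real_)
}

#' Jost's D
#' @param hs within-population expected heterozygosity (< 1)
#' @param ht total expected heterozygosity
#' @param k number of populations
#' @return (k/(k-1)) (ht - hs) / (1 - hs); `NA` when hs >= 1
#' @export
jost_d <- function(hs, ht, k = 2) {
  ifelse(hs < 1, (k / (k - 1)) * (ht - hs) / (1 - hs), NA_real_)
}

#' AMOVA-based phi_ST at one biallelic site
#'
#' Single-locus AMOVA on allele copies under the 0/1 match/mismatch
#' distance. With per-population ref/alt copy counts the sums of squared
#' deviations collapse to products: the within-population SSD is
#' sum_i ref_i*alt_i/n_i and the total SSD is R*A/N over the pooled counts.
#' Variance components use n0 = (N - sum n_i^2/N)/(k - 1); phi_ST =
#' sigma2_a/(sigma2_a + sigma2_w), reported unclamped (can be negative).
#'
#' @param counts matrix, populations x 2 (ref count, alt count)
#' @return phi_ST, or `NA` when degenerate (all alleles identical, or fewer
#'   than 2 copies in a population)
#' @export
phi_st <- function(counts) {
  counts <- as.matrix(counts)
  n_i <- rowSums(counts)
  if (any(n_i < 2)) return(NA_real_)
  N <- sum(n_i)
  k <- nrow(counts)
  R <- sum(counts[, 1]); A <- sum(counts[, 2])
  if (R == 0 || A == 0) return(NA_real_)
  ssd_total <- R * A / N
  ssd_within <- sum(counts[, 1] * counts[, 2] / n_i)
  ssd_among <- ssd_total - ssd_within
  ms_among <- ssd_among / (k - 1)
  ms_within <- ssd_within / (N - k)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  sigma_w <- ms_within
  sigma_a <- (ms_among - ms_within) / n0
  sigma_a / (sigma_a + sigma_w)
}

#' Two-sided Fisher exact test on a 2x2 allele-count table
#'
#' p is the sum of hypergeometric probabilities (margins fixed) of all
#' tables whose probability does not exceed the observed one times
#' (1 + 1e-7); the tolerance factor resolves floating-point ties the way the
#' conventional implementations do, so results are reproducible across
#' languages.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows: alleles,
#'   columns: populations, or vice versa)
#' @return p-value in (0, 1]; an empty margin gives 1 by convention
#' @export
fisher_exact_p <- function(table) {
  x <- as.matrix(table)
  stopifnot(all(dim(x) == c(2, 2)), all(x >= 0), all(x == round(x)))
  m <- sum(x[1, ])          # margin of row 1
  n <- sum(x[2, ])          # margin of row 2
  kk <- sum(x[, 1])         # margin of column 1
  if (m == 0 || n == 0 || kk == 0 || sum(x[, 2]) == 0) {
    message("fisher_exact_p: empty margin, p = 1 by convention")
    return(1)
  }
  support <- max(0, kk - n):min(kk, m)
  probs <- stats::dhyper(support, m, n, kk)
  obs <- stats::dhyper(x[1, 1], m, n, kk)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Bonferroni significance flags
#' @param pvalues vector of per-SNP exact-test p-values
#' @param alpha family-wise error rate
#' @param m family size; defaults to `length(pvalues)` (the post-filter,
#'   polymorphic test family)
#' @return logical vector: `p < alpha / m` (strict)
#' @export
bonferroni_flag <- function(pvalues, alpha = 0.05, m = length(pvalues)) {
  if (m == 0) return(logical(0))
  pvalues < alpha / m
}

#' Per-SNP divergence table
#'
#' Computes Hs, Ht (Nei-Chesser corrected by default, or uncorrected),
#' G_ST, G'_ST, Jost's D, phi_ST and the Fisher exact-test p with Bonferroni
#' flags, for every polymorphic site of a filtered two-population snp_set.
#' Sites that are monomorphic over the pooled called copies, or where one
#' population has no called genotype, carry no test and are excluded from
#' the output (and hence from the Bonferroni family), with a message.
#'
#' @param ss a filtered [snp_set()] with exactly two populations
#' @param corrected use Nei-Chesser small-sample estimators (default)
#' @param alpha family-wise error rate for the Bonferroni flag
#' @return data.frame: unigene_id, pos, hs, ht, gst, gst_hedrick, jost_d,
#'   phi_st, fisher_p, significant
#' @export
snp_divergence <- function(ss, corrected = TRUE, alpha = 0.05) {
  pops <- population_index(ss)
  if (length(pops) != 2) {
    stop("divergence statistics require exactly 2 populations, got ",
         length(pops))
  }
  cnt <- allele_count_matrices(ss)
  k <- 2
  ns <- n_sites(ss)
  hs <- ht <- phi <- fp <- rep(NA_real_, ns)
  usable <- rep(TRUE, ns)
  for (i in seq_len(ns)) {
    tab <- cbind(ref = cnt$ref[i, ], alt = cnt$alt[i, ])
    tot_alt <- sum(tab[, "alt"]); tot <- sum(tab)
    if (any(rowSums(tab) == 0) || tot_alt == 0 || tot_alt == tot) {
      usable[i] <- FALSE
      next
    }
    h <- heterozygosities(tab, corrected = corrected, n_het = cnt$n_het[i, ])
    if (is.null(h)) { usable[i] <- FALSE; next }
    hs[i] <- h$hs; ht[i] <- h$ht
    phi[i] <- phi_st(tab)
    fp[i] <- fisher_exact_p(t(tab))
  }
  if (any(!usable)) {
    message(sum(!usable),
            " monomorphic/uncallable site(s) excluded from divergence tests")
  }
  idx <- which(usable)
  out <- data.frame(
    unigene_id = ss$sites$unigene_id[idx],
    pos = ss$sites$pos[idx],
    hs = hs[idx], ht = ht[idx],
    gst = gst(hs[idx], ht[idx]),
    gst_hedrick = gst_hedrick(gst(hs[idx], ht[idx]), hs[idx], k),
    jost_d = jost_d(hs[idx], ht[idx], k),
    phi_st = phi[idx],
    fisher_p = fp[idx],
    stringsAsFactors = FALSE
  )
  out$significant <- bonferroni_flag(out$fisher_p, alpha = alpha)
  out
}

#' Transcriptome-wide divergence summary
#'
#' Reports both aggregation conventions for the headline differentiation:
#' `mean_gst`, the arithmetic mean of per-SNP G_ST, and `global_gst`, the
#' ratio of means (mean Ht - mean Hs)/mean Ht, which is the convention that
#' converges to the Balding-Nichols closed form F/(2-F) and is the default
#' headline value.
#'
#' @param div data.frame from [snp_divergence()]
#' @return list: mean_gst, global_gst, n_significant_snps,
#'   n_significant_genes, gst_range_significant (c(min, max) or c(NA, NA))
#' @export
summarize_divergence <- function(div) {
  sig <- div[which(div$significant), , drop = FALSE]
  list(
    mean_gst = mean(div$gst, na.rm = TRUE),
    global_gst = (mean(div$ht, na.rm = TRUE) - mean(div$hs, na.rm = TRUE)) /
      mean(div$ht, na.rm = TRUE),
    n_significant_snps = nrow(sig),
    n_significant_genes = length(unique(sig$unigene_id)),
    gst_range_significant = if (nrow(sig)) range(sig$gst) else c(NA_real_, NA_real_)
  )
}
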