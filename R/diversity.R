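#' Per-site nucleotide diversity
#'
#' The fraction of unordered pairs of called allele copies that differ:
#' \deqn{\pi_{nt} = 1 - \sum_i \binom{n_i}{2} / \binom{n}{2}}
#' where n_i is the count of allele i in the population and n their sum.
#'
#' @param counts integer vector of allele copy counts (length 2 for a
#'   biallelic site; the formula is general)
#' @return pi in \[0, 1\]; `NA` when fewer than 2 copies are called
#' @export
site_pi <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  1 - sum(choose(counts, 2)) / choose(n, 2)
}

#' Per-gene nucleotide diversity
#'
#' Mode `"per-length"` (default) averages site pi over every position of
#' the transcript (non-SNP positions contribute 0): sum(site_pi)/length.
#' Mode `"per-snp"` averages over SNP positions only. Both are emitted by
#' the report because "average over each position across the gene" admits
#' either reading.
#'
#' @param site_pis numeric vector of per-SNP pi values for the gene
#' @param gene_length transcript length in bp (>= 1)
#' @param mode `"per-length"` or `"per-snp"`
#' @return average nucleotide diversity; 0 (per-length) or `NA` (per-snp)
#'   when the gene has no SNPs
#' @export
gene_pi <- function(site_pis, gene_length, mode = c("per-length", "per-snp")) {
  mode <- match.arg(mode)
  site_pis <- site_pis[!is.na(site_pis)]
  if (mode == "per-length") {
    stopifnot(gene_length >= 1)
    sum(site_pis) / gene_length
  } else {
    if (!length(site_pis)) NA_real_ else mean(site_pis)
  }
}

#' Constants of Tajima's D
#'
#' The 1989 constants a1, a2, b1, b2, c1, c2, e1, e2 as functions of the
#' sample size n. Because the sample size here is the average number of
#' alleles genotyped per SNP, n is generically non-integer; the harmonic
#' sums are generalized through the digamma/trigamma identities
#' a1 = digamma(n) - digamma(1), a2 = trigamma(1) - trigamma(n), which
#' reproduce the integer sums exactly at integer n. `integer_n = TRUE`
#' rounds n first (for comparison against integer-only implementations).
#'
#' @param n_bar (possibly fractional) number of sampled allele copies, >= 2
#' @param integer_n round n to the nearest integer before computing
#' @return list of constants a1, a2, b1, b2, c1, c2, e1, e2 (and n used)
#' @export
tajima_constants <- function(n_bar, integer_n = FALSE) {
  n <- if (integer_n) round(n_bar) else n_bar
  if (n < 2) stop("Tajima constants need n >= 2, got ", n)
  a1 <- digamma(n) - digamma(1)
  a2 <- trigamma(1) - trigamma(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' Standardized difference between the pairwise-diversity estimator of
#' theta (k_hat, the sum of per-site pi over the gene's segregating sites,
#' i.e. the mean number of pairwise differences) and the Watterson
#' estimator S/a1:
#' \deqn{D = \frac{\hat k - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}}}
#'
#' @param S number of segregating sites in the sample (>= 1)
#' @param k_hat mean pairwise differences (sum of site pi across sites)
#' @param n_bar sample size: average called allele copies per SNP
#' @param integer_n passed to [tajima_constants()]
#' @return D, or `NA` when the variance term is not positive
#' @export
tajimas_d <- function(S, k_hat, n_bar, integer_n = FALSE) {
  if (S < 1) return(NA_real_)
  cc <- tajima_constants(n_bar, integer_n = integer_n)
  v <- cc$e1 * S + cc$e2 * S * (S - 1)
  if (!is.finite(v) || v <= 0) {
    warning("non-positive variance in Tajima's D; returning NA")
    return(NA_real_)
  }
  (k_hat - S / cc$a1) / sqrt(v)
}

#' Flag Tajima's D outliers by percentile
#'
#' A gene is flagged when its D falls at or beyond the pct-th or
#' (100-pct)-th percentile of its population's distribution (linear
#' interpolation between order statistics, inclusive tails). Fewer than
#' `min_n` finite values give no flags and a warning, since the tails are
#' then meaningless.
#'
#' @param d_values numeric vector of per-gene D for one population
#' @param pct tail percentile (default 2.5)
#' @param min_n minimum finite values required (default 40)
#' @return logical vector aligned with `d_values` (`FALSE` for `NA` inputs)
#' @export
classify_outliers <- function(d_values, pct = 2.5, min_n = 40) {
  ok <- is.finite(d_values)
  flags <- rep(FALSE, length(d_values))
  if (sum(ok) < min_n) {
    warning("fewer than ", min_n, " finite D values; no outliers flagged")
    return(flags)
  }
  if (max(d_values[ok]) == min(d_values[ok])) {
    # zero-spread distribution has no tails; nothing is an outlier
    return(flags)
  }
  lo <- stats::quantile(d_values[ok], pct / 100, type = 7, names = FALSE)
  hi <- stats::quantile(d_values[ok], 1 - pct / 100, type = 7, names = FALSE)
  flags[ok] <- d_values[ok] <= lo | d_values[ok] >= hi
  flags
}

#' Per-gene, per-population diversity and Tajima's D
#'
#' For each unigene and each population separately: per-site pi at every SNP
#' (within-population allele counts), gene-level pi under both averaging
#' modes, the number of segregating sites S (sites polymorphic within that
#' population; a SNP fixed in the population is not segregating there),
#' n_bar (mean called allele copies across the gene's SNPs), Tajima's D,
#' and the percentile outlier flags. A gene is an overall outlier if
#' flagged in at least one population.
#'
#' @param ss a filtered [snp_set()]
#' @param annotations data.frame from [read_annotations()] (for gene length)
#' @param pct outlier tail percentile
#' @param min_n minimum finite D values per population for outlier calling
#' @return data.frame: unigene_id, population, pi_per_length, pi_per_snp,
#'   S, n_bar, tajima_d, outlier, outlier_any
#' @export
gene_diversity <- function(ss, annotations, pct = 2.5, min_n = 40) {
  pops <- population_index(ss)
  cnt <- allele_count_matrices(ss)
  len <- stats::setNames(annotations$length, annotations$unigene_id)
  missing_len <- setdiff(unique(ss$sites$unigene_id), names(len))
  if (length(missing_len)) {
    stop("no annotation for unigene(s): ",
         paste(utils::head(missing_len, 5), collapse = ", "))
  }
  rows <- list()
  gene_idx <- split(seq_len(n_sites(ss)), ss$sites$unigene_id)
  for (pop in names(pops)) {
    j <- match(pop, colnames(cnt$ref))
    for (g in names(gene_idx)) {
      idx <- gene_idx[[g]]
      refs <- cnt$ref[idx, j]; alts <- cnt$alt[idx, j]
      n_called <- refs + alts
      pis <- vapply(seq_along(idx),
                    function(i) site_pi(c(refs[i], alts[i])), numeric(1))
      seg <- refs > 0 & alts > 0
      S <- sum(seg)
      nb_sites <- n_called[n_called > 0]
      n_bar <- if (length(nb_sites)) mean(nb_sites) else NA_real_
      k_hat <- sum(pis, na.rm = TRUE)
      d <- if (S >= 1 && is.finite(n_bar) && n_bar >= 2) {
        tajimas_d(S, k_hat, n_bar)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        unigene_id = g, population = pop,
        pi_per_length = gene_pi(pis, len[[g]], "per-length"),
        pi_per_snp = gene_pi(pis, len[[g]], "per-snp"),
        S = S, n_bar = n_bar, tajima_d = d,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$outlier <- FALSE
  for (pop in names(pops)) {
    sel <- out$population == pop
    out$outlier[sel] <- classify_outliers(out$tajima_d[sel], pct = pct,
                                          min_n = min_n)
  }
  any_by_gene <- tapply(out$outlier, out$unigene_id, any)
  out$outlier_any <- as.logical(any_by_gene[out$unigene_id])
  rownames(out) <- NULL
  out
}
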