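#' Hard-filter thresholds
#'
#' Defaults reproduce the GATK-style cascade used for RNA-seq SNP calls:
#' strand bias FS > 30 removed, quality-by-depth QD < 2 removed, more than 3
#' SNPs in any 35-bp window removed, site depth below 25 reads removed,
#' sites called in fewer than 16 individuals in either population removed,
#' pooled minor allele frequency below 1% removed. Genotypes with GQ < 20
#' are masked to missing before the site-level rules run.
#'
#' @param fs_max maximum FisherStrand phred score (strictly greater removed)
#' @param qd_min minimum quality-by-depth (strictly less removed)
#' @param cluster_window window size in bp for the SNP-cluster rule
#' @param cluster_max_snps maximum SNPs tolerated in any window
#' @param depth_min minimum site-level read depth
#' @param gq_min minimum genotype quality (calls below are masked)
#' @param min_called_per_pop minimum called individuals per population
#' @param maf_min minimum pooled minor allele frequency
#' @param strict_info if `TRUE` (default) a site missing FS, QD or DP fails
#'   the corresponding rule; if `FALSE` it passes it
#' @return a `filter_thresholds` list
#' @export
filter_thresholds <- function(fs_max = 30, qd_min = 2, cluster_window = 35,
                              cluster_max_snps = 3, depth_min = 25,
                              gq_min = 20, min_called_per_pop = 16,
                              maf_min = 0.01, strict_info = TRUE) {
  th <- list(fs_max = fs_max, qd_min = qd_min,
             cluster_window = as.integer(cluster_window),
             cluster_max_snps = as.integer(cluster_max_snps),
             depth_min = depth_min, gq_min = gq_min,
             min_called_per_pop = min_called_per_pop, maf_min = maf_min,
             strict_info = isTRUE(strict_info))
  nums <- unlist(th[setdiff(names(th), "strict_info")])
  if (any(!is.finite(nums)) || any(nums < 0)) {
    stop("configuration error: thresholds must be finite and non-negative")
  }
  if (th$cluster_window < 1) {
    stop("configuration error: cluster_window must be >= 1")
  }
  class(th) <- "filter_thresholds"
  th
}

#' Mask low-quality genotype calls
#'
#' Calls with GQ below `gq_min` become missing ("no call"); site-level
#' fields are untouched. The inclusive boundary follows "quality score of at
#' least 20": GQ 20 is retained, GQ 19 is masked.
#'
#' @param ss a [snp_set()]
#' @param gq_min phred threshold
#' @return the masked `snp_set`; attribute `n_masked` counts newly missing
#'   calls
#' @export
mask_low_quality_genotypes <- function(ss, gq_min = 20) {
  low <- ss$gq < gq_min & !is.na(ss$geno)
  ss$geno[low] <- NA_integer_
  attr(ss, "n_masked") <- sum(low)
  ss
}

#' Flag SNPs in dense clusters
#'
#' A SNP is flagged if it lies in any window of `window` consecutive bases
#' (on the same unigene) that contains more than `max_snps` SNPs — GATK
#' cluster-filter semantics: every SNP of an offending window is removed,
#' not just the excess. Scanning windows anchored at each SNP position is
#' sufficient: sliding a window left until it starts on a SNP never lowers
#' its count.
#'
#' @param unigene_id character vector of site unigenes
#' @param pos integer vector of site positions
#' @param window window width in bp (positions p .. p+window-1)
#' @param max_snps tolerated SNP count per window
#' @return logical vector, `TRUE` where the site is removed
#' @export
flag_snp_clusters <- function(unigene_id, pos, window = 35, max_snps = 3) {
  removed <- logical(length(pos))
  for (idx in split(seq_along(pos), unigene_id)) {
    p <- pos[idx]
    o <- order(p)
    ps <- p[o]
    # for window starting at ps[i], last contained SNP index:
    hi <- findInterval(ps + window - 1L, ps)
    flag <- logical(length(ps))
    for (i in seq_along(ps)) {
      if (hi[i] - i + 1L > max_snps) flag[i:hi[i]] <- TRUE
    }
    removed[idx[o]] <- flag
  }
  removed
}

#' Apply the site-level hard-filter cascade
#'
#' Genotype masking must already have been applied. Each rule is evaluated
#' on the full input and every removed record is attributed to the first
#' rule (in the fixed order below) that it violates, so per-rule counts are
#' deterministic:
#' 1. `fs`: FS > fs_max; 2. `qd`: QD < qd_min; 3. `cluster`: >max_snps SNPs
#' in a window; 4. `depth`: DP < depth_min; 5. `presence`: called
#' individuals < min_called_per_pop in either population; 6. `maf`: pooled
#' minor allele frequency < maf_min (monomorphic sites fall here too).
#'
#' With `strict_info = TRUE` a missing FS/QD/DP value fails its rule.
#'
#' @param ss a masked [snp_set()]
#' @param thresholds a [filter_thresholds()]
#' @return list with `kept` (a `snp_set`), `removed_by_rule` (named integer
#'   vector over the six rule labels), and `genotypes_masked` (copied from
#'   the `n_masked` attribute of `ss`, 0 if absent)
#' @export
apply_site_filters <- function(ss, thresholds = filter_thresholds()) {
  th <- thresholds
  if (!inherits(th, "filter_thresholds")) {
    stop("configuration error: thresholds must come from filter_thresholds()")
  }
  miss_fails <- function(x) if (th$strict_info) is.na(x) else rep(FALSE, length(x))

  viol <- list(
    fs = (ss$sites$fs > th$fs_max & !is.na(ss$sites$fs)) |
      miss_fails(ss$sites$fs),
    qd = (ss$sites$qd < th$qd_min & !is.na(ss$sites$qd)) |
      miss_fails(ss$sites$qd),
    cluster = flag_snp_clusters(ss$sites$unigene_id, ss$sites$pos,
                                th$cluster_window, th$cluster_max_snps),
    depth = (ss$sites$depth < th$depth_min & !is.na(ss$sites$depth)) |
      miss_fails(ss$sites$depth)
  )
  cnt <- allele_count_matrices(ss)
  if (ncol(cnt$n_called) < 1) stop("no populations in sample sheet")
  viol$presence <- rowSums(cnt$n_called < th$min_called_per_pop) > 0
  total <- rowSums(cnt$ref) + rowSums(cnt$alt)
  altf <- ifelse(total > 0, rowSums(cnt$alt) / total, 0)
  maf <- pmin(altf, 1 - altf)
  viol$maf <- maf < th$maf_min | total == 0

  first <- rep(NA_character_, n_sites(ss))
  for (rule in names(viol)) {
    hit <- is.na(first) & viol[[rule]]
    first[hit] <- rule
  }
  removed_by_rule <- vapply(names(viol), function(r) sum(first == r, na.rm = TRUE),
                            integer(1))
  kept <- subset_sites(ss, is.na(first))
  list(kept = kept,
       removed_by_rule = removed_by_rule,
       genotypes_masked = attr(ss, "n_masked") %||% 0L)
}
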