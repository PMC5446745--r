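#' SNP set container
#'
#' A `snp_set` bundles everything the pipeline knows about a collection of
#' biallelic SNPs on transcripts: site-level metadata (unigene, position,
#' alleles, the INFO annotations used by the hard filters) and the per-sample
#' genotype dosage and genotype-quality matrices, together with the
#' population assignment of every sample.
#'
#' Genotypes are coded as alt-allele dosage (0, 1, 2) with `NA` for missing
#' ("no call"). Positions are 1-based transcript coordinates, as in VCF;
#' unigenes are treated as single-exon plus-strand sequences, so there is no
#' strand handling anywhere in the package.
#'
#' @param sites data.frame with columns `unigene_id` (character), `pos`
#'   (integer, >= 1), `ref`, `alt` (single nucleotides, ref != alt), `fs`,
#'   `qd`, `depth` (site-level FS / QD / DP; `NA` when absent from the VCF).
#' @param geno integer matrix, sites x samples, entries in \{0, 1, 2, NA\}.
#' @param gq numeric matrix, sites x samples, phred genotype qualities >= 0.
#' @param samples data.frame with columns `sample_id` and `population`;
#'   row order defines the column order of `geno` and `gq`.
#' @return An object of class `snp_set`.
#' @export
snp_set <- function(sites, geno, gq, samples) {
  stopifnot(is.data.frame(sites), is.data.frame(samples))
  req <- c("unigene_id", "pos", "ref", "alt", "fs", "qd", "depth")
  if (!all(req %in% names(sites))) {
    stop("sites must have columns: ", paste(req, collapse = ", "))
  }
  geno <- as.matrix(geno)
  gq <- as.matrix(gq)
  if (nrow(geno) != nrow(sites) || nrow(gq) != nrow(sites)) {
    stop("geno/gq must have one row per site")
  }
  if (ncol(geno) != nrow(samples) || ncol(gq) != nrow(samples)) {
    stop("geno/gq must have one column per sample")
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  bad <- sites$ref == sites$alt
  if (any(bad)) stop("ref == alt at site ", which(bad)[1])
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  colnames(geno) <- colnames(gq) <- samples$sample_id
  structure(
    list(sites = sites, geno = geno, gq = gq, samples = samples),
    class = "snp_set"
  )
}

#' @export
print.snp_set <- function(x, ...) {
  cat(sprintf(
    "snp_set: %d biallelic SNPs on %d unigenes, %d samples (%s)\n",
    nrow(x$sites), length(unique(x$sites$unigene_id)), nrow(x$samples),
    paste(sprintf("%s=%d", names(table(x$samples$population)),
                  as.integer(table(x$samples$population))), collapse = ", ")
  ))
  invisible(x)
}

#' Number of sites in a snp_set
#' @param ss a `snp_set`
#' @return integer site count
#' @export
n_sites <- function(ss) nrow(ss$sites)

#' Site keys ("unigene:pos") of a snp_set
#' @param ss a `snp_set`
#' @return character vector
#' @export
site_key <- function(ss) paste(ss$sites$unigene_id, ss$sites$pos, sep = ":")

#' Subset a snp_set by site index
#' @param ss a `snp_set`
#' @param idx logical or integer site index
#' @return a `snp_set` with the selected sites
#' @export
subset_sites <- function(ss, idx) {
  snp_set(ss$sites[idx, , drop = FALSE],
          ss$geno[idx, , drop = FALSE],
          ss$gq[idx, , drop = FALSE],
          ss$samples)
}

#' Population labels and sample index
#' @param ss a `snp_set`
#' @return named list of integer column indices, one per population label
#' @export
population_index <- function(ss) {
  split(seq_len(nrow(ss$samples)), ss$samples$population)
}

#' Per-population called allele counts at every site
#'
#' For each site and population, the number of called ref and alt allele
#' copies (2 per called diploid genotype), plus the heterozygote count used
#' by the Nei-Chesser estimators.
#'
#' @param ss a `snp_set`
#' @return list with per-population matrices `ref`, `alt` (sites x pops),
#'   `n_called` (called individuals), `n_het` (heterozygous individuals)
#' @export
allele_count_matrices <- function(ss) {
  pops <- population_index(ss)
  npop <- length(pops)
  ns <- n_sites(ss)
  ref <- alt <- n_called <- n_het <- matrix(
    0L, ns, npop, dimnames = list(NULL, names(pops))
  )
  for (j in seq_along(pops)) {
    g <- ss$geno[, pops[[j]], drop = FALSE]
    called <- !is.na(g)
    n_called[, j] <- rowSums(called)
    altc <- rowSums(g, na.rm = TRUE)
    alt[, j] <- as.integer(altc)
    ref[, j] <- as.integer(2L * n_called[, j] - altc)
    n_het[, j] <- rowSums(g == 1L, na.rm = TRUE)
  }
  list(ref = ref, alt = alt, n_called = n_called, n_het = n_het)
}
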