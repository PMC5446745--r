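#' Complete-case genotype matrix
#'
#' Individuals x SNPs dosage matrix restricted to SNPs genotyped in every
#' individual (the structure analyses use no imputation). Constant columns
#' carry no information for PCA and are dropped with a message.
#'
#' @param ss a filtered [snp_set()]
#' @return matrix with rownames = sample ids, colnames = "unigene:pos",
#'   attributes `population` (per row) and `n_constant_dropped`
#' @export
complete_case_matrix <- function(ss) {
  complete <- rowSums(is.na(ss$geno)) == 0
  m <- t(ss$geno[complete, , drop = FALSE])
  colnames(m) <- site_key(ss)[complete]
  rownames(m) <- ss$samples$sample_id
  constant <- apply(m, 2, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    message(sum(constant), " constant column(s) dropped")
  }
  m <- m[, !constant, drop = FALSE]
  if (ncol(m) == 0) {
    stop("no complete-case polymorphic SNPs survive; consider laxer filters")
  }
  attr(m, "population") <- ss$samples$population
  attr(m, "n_constant_dropped") <- sum(constant)
  m
}

#' PCA of a genotype dosage matrix
#'
#' Columns are mean-centered (optionally scaled by sqrt(p(1-p)) of the
#' column allele frequency); scores come from the SVD of the centered
#' matrix, equivalent to an eigendecomposition of the individual-by-
#' individual covariance. Deterministic sign convention: within each
#' component the largest-magnitude SNP loading is made positive, so scores
#' are comparable across runs and languages.
#'
#' @param m matrix from [complete_case_matrix()]
#' @param n_components number of components to return
#' @param scaling `"none"` (default) or `"freq"` for 1/sqrt(p(1-p)) scaling
#' @return list of class `pca_result`: `scores` (individuals x components),
#'   `loadings`, `variance_explained` (fraction of total variance per
#'   returned component), `population`
#' @export
pca_genotypes <- function(m, n_components = 10, scaling = c("none", "freq")) {
  scaling <- match.arg(scaling)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 individuals and >= 2 SNPs")
  x <- scale(m, center = TRUE, scale = FALSE)
  if (scaling == "freq") {
    p <- colMeans(m) / 2
    x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  }
  sv <- svd(x)
  tol <- max(dim(x)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (n_components > rank) {
    warning("n_components > rank (", rank, "); truncating")
    n_components <- rank
  }
  keep <- seq_len(n_components)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  for (j in keep) {
    peak <- which.max(abs(loadings[, j]))
    if (loadings[peak, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", keep)
  structure(
    list(scores = scores, loadings = loadings,
         variance_explained = sv$d[keep]^2 / sum(sv$d^2),
         population = attr(m, "population")),
    class = "pca_result"
  )
}

#' k-means cluster summary of PCA scores
#'
#' A lightweight stand-in for model-based structure inference: k-means on
#' the leading components with a fixed seed and multiple restarts, plus the
#' per-cluster population composition and the mean silhouette width (0 by
#' convention for k = 1). Randomness is confined to a local RNG state, so
#' the caller's stream is untouched and the same seed always reproduces the
#' same assignments.
#'
#' @param scores score matrix (individuals x components), e.g.
#'   `pca$scores[, 1:2]`
#' @param k number of clusters (<= number of individuals)
#' @param population optional per-individual labels for the composition
#'   table
#' @param seed RNG seed for k-means restarts
#' @param nstart number of k-means restarts
#' @return list: `assignments` (integer per individual), `composition`
#'   (cluster x population table or `NULL`), `silhouette` (mean width)
#' @export
cluster_summary <- function(scores, k, population = NULL, seed = 1,
                            nstart = 25) {
  scores <- as.matrix(scores)
  if (k > nrow(scores)) stop("k exceeds the number of individuals")
  assignments <- local_seed(seed, {
    if (k == 1) rep(1L, nrow(scores)) else
      stats::kmeans(scores, centers = k, nstart = nstart)$cluster
  })
  sil <- if (k == 1) 0 else mean_silhouette(scores, assignments)
  comp <- if (!is.null(population)) {
    table(cluster = assignments, population = population)
  }
  list(assignments = assignments, composition = comp, silhouette = sil)
}

# Run code under a temporary RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Mean silhouette width over all points (Euclidean distance). Singleton
# clusters get width 0, the usual convention.
mean_silhouette <- function(x, cluster) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  widths <- vapply(seq_len(n), function(i) {
    own <- cluster == cluster[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(cluster), cluster[i]),
                    function(cl) mean(d[i, cluster == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(widths)
}
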