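#' Pipeline configuration
#'
#' Paths plus every analysis knob: filter thresholds, estimator choice,
#' Bonferroni alpha, gene-pi averaging mode, outlier percentile, PCA options
#' and the seed used by any stochastic step (k-means restarts).
#'
#' @param vcf,fasta,annotations,samples input file paths
#' @param out_dir output directory for the report bundle
#' @param thresholds a [filter_thresholds()]
#' @param corrected use Nei-Chesser bias-corrected Hs/Ht (default)
#' @param alpha family-wise error rate for Bonferroni
#' @param percentile Tajima's D outlier tail percentile
#' @param pca_components number of PCs to report
#' @param pca_scaling `"none"` or `"freq"`
#' @param kmeans_k clusters for the structure summary
#' @param seed seed for stochastic steps
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(vcf, fasta, annotations, samples, out_dir,
                            thresholds = filter_thresholds(),
                            corrected = TRUE, alpha = 0.05,
                            percentile = 2.5, pca_components = 10,
                            pca_scaling = "none", kmeans_k = 3, seed = 1) {
  for (p in c(vcf, fasta, annotations, samples)) {
    if (!file.exists(p)) stop("configuration error: missing input: ", p)
  }
  cfg <- as.list(environment())
  cfg$p <- NULL
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' read -> mask -> filter -> divergence -> diversity -> effects ->
#' structure -> reports. Writes, under `out_dir`: `divergence.tsv` (per-SNP
#' Table-5-shaped report with effect classes), `diversity.tsv` (per-gene,
#' per-population), `effect_summary.tsv`, `filter_summary.tsv`,
#' `pca_scores.tsv`, `pca_variance.tsv`, `clusters.tsv`, and
#' `manifest.json` (config hash, package version, per-stage row counts).
#' Identical config and inputs give identical outputs.
#'
#' @param config a [pipeline_config()]
#' @return list of the in-memory results (invisible), with the manifest as
#'   `$manifest`
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  sheet <- stage("read_samples", read_sample_sheet(config$samples))
  ss <- stage("read_vcf", read_vcf(config$vcf, sheet))
  ann <- stage("read_annotations", read_annotations(config$annotations))
  tx <- stage("read_transcripts", read_transcripts(config$fasta))

  masked <- stage("mask", mask_low_quality_genotypes(
    ss, config$thresholds$gq_min))
  fo <- stage("filter", apply_site_filters(masked, config$thresholds))
  kept <- fo$kept

  empty <- n_sites(kept) == 0
  if (empty) warning("no SNPs survive filtering; reports will be header-only")

  div <- if (!empty) {
    stage("divergence", snp_divergence(kept, corrected = config$corrected,
                                       alpha = config$alpha))
  } else empty_divergence()
  eff <- if (!empty) {
    stage("effects", classify_effects(kept, ann, tx))
  } else NULL
  if (!empty && nrow(div)) {
    key <- paste(eff$unigene_id, eff$pos)
    div$effect_class <- eff$effect_class[match(paste(div$unigene_id, div$pos),
                                               key)]
  }
  dvr <- if (!empty) {
    stage("diversity", gene_diversity(kept, ann, pct = config$percentile))
  } else NULL

  pca <- clus <- NULL
  if (!empty) {
    pca <- stage("structure", {
      m <- complete_case_matrix(kept)
      pca_genotypes(m, n_components = config$pca_components,
                    scaling = config$pca_scaling)
    })
    clus <- cluster_summary(pca$scores[, seq_len(min(2, ncol(pca$scores))),
                                       drop = FALSE],
                            k = config$kmeans_k, population = pca$population,
                            seed = config$seed)
  }

  # ---- reports -------------------------------------------------------
  write_divergence_report(div, file.path(config$out_dir, "divergence.tsv"))
  write_diversity_report(
    dvr %||% data.frame(), file.path(config$out_dir, "diversity.tsv"))
  es <- effect_summary(eff %||% data.frame(effect_class = character(0),
                                           transition = logical(0)))
  utils::write.table(
    data.frame(metric = names(es), value = unlist(lapply(es, report_num))),
    file.path(config$out_dir, "effect_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(rule = c(names(fo$removed_by_rule), "kept",
                        "genotypes_masked"),
               count = c(unname(fo$removed_by_rule), n_sites(kept),
                         fo$genotypes_masked)),
    file.path(config$out_dir, "filter_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pca)) {
    utils::write.table(
      data.frame(sample_id = rownames(pca$scores),
                 population = pca$population,
                 round(pca$scores, 6)),
      file.path(config$out_dir, "pca_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(component = colnames(pca$scores),
                 variance_explained = report_num(pca$variance_explained)),
      file.path(config$out_dir, "pca_variance.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = rownames(pca$scores),
                 population = pca$population,
                 cluster = clus$assignments),
      file.path(config$out_dir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    for (f in c("pca_scores.tsv", "pca_variance.tsv", "clusters.tsv")) {
      writeLines("sample_id\tpopulation\tvalue", file.path(config$out_dir, f))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("transpopgen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = config_hash(config),
    inputs = list(vcf = config$vcf, fasta = config$fasta,
                  annotations = config$annotations,
                  samples = config$samples),
    counts = list(
      snps_parsed = n_sites(ss),
      lines_skipped = attr(ss, "n_skipped"),
      genotypes_masked = fo$genotypes_masked,
      removed_by_rule = as.list(fo$removed_by_rule),
      snps_kept = n_sites(kept),
      snps_tested = nrow(div),
      significant_snps = sum(div$significant),
      significant_genes = length(unique(div$unigene_id[div$significant])),
      pca_snps = if (!is.null(pca)) nrow(pca$loadings) else 0L
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(snps = ss, filtered = fo, divergence = div, diversity = dvr,
                 effects = eff, pca = pca, clusters = clus,
                 manifest = manifest))
}

empty_divergence <- function() {
  data.frame(unigene_id = character(0), pos = integer(0), hs = numeric(0),
             ht = numeric(0), gst = numeric(0), gst_hedrick = numeric(0),
             jost_d = numeric(0), phi_st = numeric(0), fisher_p = numeric(0),
             significant = logical(0), stringsAsFactors = FALSE)
}

# Stable hash of the configuration: md5 of its deparsed, path-normalized
# representation (base tools only; no digest dependency).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- config
  flat$thresholds <- unclass(flat$thresholds)
  writeLines(deparse(flat[order(names(flat))]), tmp)
  unname(tools::md5sum(tmp))
}
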