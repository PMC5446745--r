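#' Simulation configuration
#'
#' Describes the synthetic world the generator emulates: two populations of
#' diploid individuals genotyped at biallelic transcript SNPs, with
#' per-population allele frequencies drawn around an ancestral frequency
#' under the Balding-Nichols model, Beta(p(1-F)/F, (1-p)(1-F)/F). Under the
#' `"standing_variation"` scenario two ancestral subclusters C1 and C2 are
#' drawn; the "MN"-like ancestral population mixes them (an individual comes
#' from C2 with probability `mix_weight`) while the derived "ND"-like
#' population samples C1 only — the "derived population is a subsample of
#' ancestral standing variation" pattern.
#'
#' Defaults state the study-like world: 48 diploids per population, an
#' overall divergence F = 0.0354 (the Balding-Nichols closed form
#' G = F/(2-F) then equals 0.018), ~5 SNPs per gene on ~1 kb transcripts
#' (about the observed 5.5 SNPs/kb), mix_weight 0.75 (about a quarter of
#' the ancestral population clusters with the derived one), small artifact
#' rates to exercise every hard-filter rule, and a combined per-call no-call
#' rate (raw missingness + sub-threshold GQ) of ~3.4%, which reproduces the
#' study-like ~3.6% fraction of SNPs genotyped in all 96 individuals.
#'
#' @param n_genes number of unigenes
#' @param gene_length_mean mean transcript length in bp
#' @param snps_per_gene expected SNPs per gene (Poisson, >= 1 enforced)
#' @param n_per_pop diploid individuals per population
#' @param F Balding-Nichols divergence parameter, in (0, 1)
#' @param scenario `"two_pop"` or `"standing_variation"`
#' @param mix_weight fraction of the ancestral ("MN") population drawn from
#'   subcluster C2 (standing_variation only)
#' @param missing_rate per-call missingness probability
#' @param depth_mean,depth_size negative-binomial site depth model
#' @param gq_low_prob,gq_low_max genotype-quality model: GQ is 99 except
#'   with probability `gq_low_prob`, when it is uniform on
#'   \[0, gq_low_max\] (a low tail that exercises masking)
#' @param fs_rate,qd_rate,cluster_rate fractions of sites planted with
#'   FS > 30, QD < 2, or an extra dense SNP cluster
#' @param orf_fraction fraction of genes given a planted ORF
#' @param pop_labels the two population labels
#' @param seed integer seed; all randomness flows from it
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_genes = 500, gene_length_mean = 999,
                              snps_per_gene = 5, n_per_pop = 48,
                              F = 0.0354,
                              scenario = c("two_pop", "standing_variation"),
                              mix_weight = 0.75, missing_rate = 0.017,
                              depth_mean = 100, depth_size = 5,
                              gq_low_prob = 0.034, gq_low_max = 40,
                              fs_rate = 0.01, qd_rate = 0.01,
                              cluster_rate = 0.01, orf_fraction = 0.8,
                              pop_labels = c("MN", "ND"), seed = 1) {
  scenario <- match.arg(scenario)
  if (!(F > 0 && F < 1)) stop("F must lie in (0, 1)")
  if (mix_weight < 0 || mix_weight > 1) stop("mix_weight must be in [0, 1]")
  rates <- c(missing_rate, gq_low_prob, fs_rate, qd_rate, cluster_rate,
             orf_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate ancestral and per-cluster allele frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each cluster draws its
#' frequency from Beta(p(1-F)/F, (1-p)(1-F)/F) independently. For
#' `"two_pop"` the clusters are the two populations; for
#' `"standing_variation"` they are the ancestral subclusters C1 and C2 (the
#' derived population uses C1).
#'
#' @param n_loci number of loci
#' @param config a [simulation_config()] (its `seed` is NOT applied here;
#'   call within [simulate_dataset()] or set the seed yourself)
#' @return data.frame: ancestral `p`, cluster frequencies `f1`, `f2`
#' @export
simulate_frequencies <- function(n_loci, config) {
  F <- config$F
  p <- stats::runif(n_loci, 0.05, 0.95)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  data.frame(p = p,
             f1 = stats::rbeta(n_loci, a, b),
             f2 = stats::rbeta(n_loci, a, b))
}

#' Simulate genotypes, qualities and site annotations
#'
#' Hardy-Weinberg dosage draws per individual from the relevant cluster
#' frequency; Bernoulli missingness; negative-binomial site depth; GQ with
#' a planted low tail; FS/QD artifacts planted at the configured rates and
#' recorded as ground truth.
#'
#' @param freqs data.frame from [simulate_frequencies()]
#' @param sites data.frame with `unigene_id`, `pos`, `ref`, `alt` (one row
#'   per row of `freqs`), e.g. from [simulate_transcripts()]
#' @param config a [simulation_config()]
#' @return list: `snps` (a [snp_set()]), `truth` (per-site planted artifact
#'   label, "" when clean), `membership` (per-sample cluster origin)
#' @export
simulate_genotypes <- function(freqs, sites, config) {
  n_loci <- nrow(freqs)
  stopifnot(nrow(sites) == n_loci)
  n <- config$n_per_pop
  pops <- rep(config$pop_labels, each = n)
  samples <- data.frame(
    sample_id = sprintf("%s_%02d", pops, c(seq_len(n), seq_len(n))),
    population = pops, stringsAsFactors = FALSE
  )
  # cluster of origin per individual
  membership <- if (config$scenario == "standing_variation") {
    c(ifelse(stats::runif(n) < config$mix_weight, 2L, 1L), rep(1L, n))
  } else {
    c(rep(1L, n), rep(2L, n))
  }
  nm <- nrow(samples)
  fmat <- cbind(freqs$f1, freqs$f2)   # loci x clusters
  geno <- matrix(0L, n_loci, nm)
  for (j in seq_len(nm)) {
    geno[, j] <- stats::rbinom(n_loci, 2L, fmat[, membership[j]])
  }
  if (config$missing_rate > 0) {
    geno[matrix(stats::runif(n_loci * nm) < config$missing_rate,
                n_loci, nm)] <- NA_integer_
  }
  gq <- matrix(99, n_loci, nm)
  low <- matrix(stats::runif(n_loci * nm) < config$gq_low_prob, n_loci, nm)
  gq[low] <- round(stats::runif(sum(low), 0, config$gq_low_max))

  depth <- stats::rnbinom(n_loci, size = config$depth_size,
                          mu = config$depth_mean)
  fs <- round(stats::rexp(n_loci, rate = 1 / 3), 2)
  fs <- pmin(fs, 29.99)
  qd <- round(stats::runif(n_loci, 2, 35), 2)
  truth <- character(n_loci)
  plant <- function(rate) stats::runif(n_loci) < rate
  fs_bad <- plant(config$fs_rate)
  fs[fs_bad] <- round(stats::runif(sum(fs_bad), 31, 60), 2)
  truth[fs_bad] <- "fs"
  qd_bad <- plant(config$qd_rate) & !fs_bad
  qd[qd_bad] <- round(stats::runif(sum(qd_bad), 0, 1.99), 2)
  truth[qd_bad] <- "qd"

  st <- sites
  st$fs <- fs; st$qd <- qd; st$depth <- as.numeric(depth)
  ss <- snp_set(st, geno, gq, samples)
  list(snps = ss, truth = truth, membership = membership)
}

#' Simulate transcripts, ORFs and SNP placement
#'
#' Random nucleotide transcripts; a planted ORF (ATG ... stop, internal
#' codons free of stops, length divisible by 3) in `orf_fraction` of genes;
#' SNP positions uniform over the transcript without replacement; ref = the
#' transcript base, alt uniform over the other three bases (so transitions
#' occur at rate 1/3). A `cluster_rate` fraction of genes additionally gets
#' 4 SNPs planted inside one 35-bp window to exercise the cluster filter;
#' those sites are labelled in `cluster_truth`.
#'
#' @param config a [simulation_config()]
#' @return list: `transcripts` (named character vector of sequences),
#'   `annotations` (data.frame as from [read_annotations()]), `sites`
#'   (unigene_id, pos, ref, alt), `cluster_truth` (logical per site)
#' @export
simulate_transcripts <- function(config) {
  bases <- c("A", "C", "G", "T")
  n_genes <- config$n_genes
  ids <- sprintf("g%04d", seq_len(n_genes))
  lens <- pmax(120L, as.integer(round(stats::rnorm(
    n_genes, config$gene_length_mean, config$gene_length_mean / 10))))
  seqs <- vapply(lens, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- ids

  has_orf <- stats::runif(n_genes) < config$orf_fraction
  orf_start <- orf_end <- rep(NA_integer_, n_genes)
  for (i in which(has_orf)) {
    L <- lens[i]
    n_codons <- max(10L, as.integer(L * 0.6) %/% 3L)  # incl. start + stop
    start_max <- L - 3L * n_codons + 1L
    s <- sample.int(max(1L, start_max), 1L)
    internal <- replicate(n_codons - 2L, make_codon_nostop())
    orf_seq <- paste0("ATG", paste(internal, collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L))
    substr(seqs[i], s, s + nchar(orf_seq) - 1L) <- orf_seq
    orf_start[i] <- s
    orf_end[i] <- s + nchar(orf_seq) - 1L
  }
  annotations <- data.frame(unigene_id = ids, length = lens,
                            orf_start = orf_start, orf_end = orf_end,
                            stringsAsFactors = FALSE)

  site_list <- list()
  for (i in seq_len(n_genes)) {
    k <- max(1L, stats::rpois(1, config$snps_per_gene))
    pos <- sort(sample.int(lens[i], min(k, lens[i])))
    clustered <- logical(length(pos))
    if (stats::runif(1) < config$cluster_rate && lens[i] > 60) {
      w0 <- sample.int(lens[i] - 34L, 1L)
      cpos <- sort(sample(w0:(w0 + 34L), 4L))
      keep <- !(pos %in% cpos)
      pos <- c(pos[keep], cpos)
      clustered <- c(clustered[keep], rep(TRUE, 4L))
      o <- order(pos)
      pos <- pos[o]; clustered <- clustered[o]
      dup <- duplicated(pos)
      pos <- pos[!dup]; clustered <- clustered[!dup]
    }
    refs <- substring(seqs[i], pos, pos)
    alts <- vapply(refs, function(r) sample(setdiff(bases, r), 1L),
                   character(1), USE.NAMES = FALSE)
    site_list[[i]] <- data.frame(unigene_id = ids[i], pos = pos, ref = refs,
                                 alt = alts, clustered = clustered,
                                 stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_list)
  rownames(sites) <- NULL
  list(transcripts = seqs, annotations = annotations,
       sites = sites[, c("unigene_id", "pos", "ref", "alt")],
       cluster_truth = sites$clustered)
}

make_codon_nostop <- function() {
  repeat {
    codon <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                   collapse = "")
    if (!codon %in% c("TAA", "TAG", "TGA")) return(codon)
  }
}

#' Simulate a complete dataset
#'
#' Seeds the RNG from `config$seed`, simulates transcripts, frequencies and
#' genotypes, and returns everything including the planted ground truth
#' (per-site artifact labels and per-individual cluster memberships).
#'
#' @param config a [simulation_config()]
#' @return list: `snps` ([snp_set()]), `transcripts`, `annotations`,
#'   `frequencies`, `truth` (per-site label in \{"", "fs", "qd",
#'   "cluster"\}), `membership`, `config`
#' @export
simulate_dataset <- function(config = simulation_config()) {
  set.seed(config$seed)
  tx <- simulate_transcripts(config)
  n_loci <- nrow(tx$sites)
  freqs <- simulate_frequencies(n_loci, config)
  sim <- simulate_genotypes(freqs, tx$sites, config)
  truth <- sim$truth
  truth[tx$cluster_truth & truth == ""] <- "cluster"
  list(snps = sim$snps, transcripts = tx$transcripts,
       annotations = tx$annotations, frequencies = freqs, truth = truth,
       membership = sim$membership, config = config)
}

#' Write a simulated dataset as standard files
#'
#' Emits a VCF 4.2 (GT:GQ, INFO FS/QD/DP), a transcript FASTA, the ORF
#' annotation TSV, the sample sheet TSV, and a ground-truth manifest TSV.
#' Output is byte-identical for identical inputs.
#'
#' @param sim list from [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return named character vector of the file paths, invisibly
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "snps.vcf"),
             fasta = file.path(dir, "transcripts.fa"),
             annotations = file.path(dir, "annotations.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_snp_vcf(sim$snps, paths["vcf"])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$transcripts), paths["fasta"])
  ann <- sim$annotations
  utils::write.table(ann, paths["annotations"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(sim$snps$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(unigene_id = sim$snps$sites$unigene_id,
               pos = sim$snps$sites$pos, planted = sim$truth),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a snp_set as VCF 4.2
#'
#' @param ss a [snp_set()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_snp_vcf <- function(ss, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=transpopgen",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand bias (FisherStrand)\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ss$samples$sample_id), collapse = "\t")
  )
  gt <- matrix("./.", n_sites(ss), nrow(ss$samples))
  gt[which(ss$geno == 0L)] <- "0/0"
  gt[which(ss$geno == 1L)] <- "0/1"
  gt[which(ss$geno == 2L)] <- "1/1"
  cells <- matrix(paste0(gt, ":", as.integer(round(ss$gq))),
                  n_sites(ss), nrow(ss$samples))
  fmt_num <- function(x) ifelse(is.na(x), NA, formatC(x, format = "fg",
                                                      digits = 6))
  info <- vapply(seq_len(n_sites(ss)), function(i) {
    parts <- c(
      if (!is.na(ss$sites$fs[i])) paste0("FS=", fmt_num(ss$sites$fs[i])),
      if (!is.na(ss$sites$qd[i])) paste0("QD=", fmt_num(ss$sites$qd[i])),
      if (!is.na(ss$sites$depth[i]))
        paste0("DP=", as.integer(ss$sites$depth[i]))
    )
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))
  body <- paste(ss$sites$unigene_id, ss$sites$pos, ".", ss$sites$ref,
                ss$sites$alt, "50", "PASS", info, "GT:GQ",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  if (n_sites(ss) == 0) body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
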