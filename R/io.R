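#' Read a population assignment table
#'
#' Tab-separated, header `sample_id<TAB>population`. Sample ids must be
#' unique. The divergence statistics require exactly two population labels;
#' that is checked where k matters, not here, so the reader can also serve
#' single-population diversity runs.
#'
#' @param path TSV file path
#' @return data.frame with columns `sample_id`, `population`
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(df))) {
    stop("sample sheet must have columns sample_id, population: ", path)
  }
  df$sample_id <- as.character(df$sample_id)
  df$population <- as.character(df$population)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  df[, c("sample_id", "population")]
}

#' Read biallelic SNPs from a VCF into a snp_set
#'
#' Wraps `VariantAnnotation::readVcf`. CHROM is interpreted as the unigene id
#' and POS as the 1-based transcript coordinate. Only biallelic SNV lines are
#' kept; indel and multiallelic lines are skipped and the skip count is
#' reported with a message. Genotypes become alt-allele dosages; `./.` is
#' missing. If FORMAT carries no GQ, every call gets GQ 99 (logged once) so
#' that minimal fixtures pass the genotype-quality mask. INFO FS/QD/DP absent
#' from a record are stored as `NA`; the filter stage decides their fate via
#' its `strict_info` flag.
#'
#' @param path VCF 4.x file (plain text or bgzipped)
#' @param sample_sheet data.frame from [read_sample_sheet()]; every sample in
#'   the VCF must appear in it
#' @return a [snp_set()]; attribute `n_skipped` holds the count of
#'   non-biallelic-SNP data lines
#' @export
read_vcf <- function(path, sample_sheet) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  check_vcf_lines(path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  vcf_samples <- colnames(vcf)
  unknown <- setdiff(vcf_samples, sample_sheet$sample_id)
  if (length(unknown)) {
    stop("configuration error: VCF samples absent from sample sheet: ",
         paste(unknown, collapse = ", "))
  }
  sheet <- sample_sheet[match(vcf_samples, sample_sheet$sample_id), ,
                        drop = FALSE]

  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  alt1 <- rep(NA_character_, length(vcf))
  single <- lengths(alts) == 1L
  alt1[single] <- as.character(unlist(alts[single]))
  keep <- single & nchar(refs) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    refs %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T") &
    refs != alt1
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped,
            " non-biallelic-SNP line(s) skipped (indel/multiallelic)")
  }
  vcf <- vcf[keep]
  rr <- rr[keep]

  info <- VariantAnnotation::info(vcf)
  pull_info <- function(field) {
    if (field %in% colnames(info)) {
      v <- info[[field]]
      if (is.list(v)) v <- vapply(v, function(x)
        if (length(x)) as.numeric(x[1]) else NA_real_, numeric(1))
      as.numeric(v)
    } else {
      rep(NA_real_, length(vcf))
    }
  }
  sites <- data.frame(
    unigene_id = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = refs[keep],
    alt = alt1[keep],
    fs = pull_info("FS"),
    qd = pull_info("QD"),
    depth = pull_info("DP"),
    stringsAsFactors = FALSE
  )

  gt <- VariantAnnotation::geno(vcf)$GT
  geno <- gt_to_dosage(gt)
  if ("GQ" %in% names(VariantAnnotation::geno(vcf))) {
    gq <- VariantAnnotation::geno(vcf)$GQ
    mode(gq) <- "numeric"
    gq[is.na(gq)] <- 99
  } else {
    message("FORMAT has no GQ; treating all calls as GQ 99")
    gq <- matrix(99, nrow(geno), ncol(geno))
  }
  out <- snp_set(sites, geno, gq, sheet)
  attr(out, "n_skipped") <- n_skipped
  out
}

# Cheap structural pre-scan so malformed lines are reported with their
# 1-based line number (readVcf's own errors do not carry one).
check_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) stop("malformed VCF (no #CHROM header line): ", path)
  ncols <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(data_idx)) {
    nf <- lengths(strsplit(lines[data_idx], "\t", fixed = TRUE))
    bad <- data_idx[nf != ncols]
    if (length(bad)) {
      stop("malformed VCF line ", bad[1], " in ", path, ": expected ", ncols,
           " tab-separated fields, found ", nf[which(nf != ncols)[1]])
    }
  }
  invisible(length(data_idx))
}

gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- (a1 == "1") + (a2 == "1")
  d[a1 == "." | a2 == "." | gt == "." | is.na(gt)] <- NA
  out <- matrix(as.integer(d), nrow(gt), ncol(gt))
  colnames(out) <- colnames(gt)
  out
}

#' Read transcript ORF annotations
#'
#' TSV with header `unigene_id`, `length`, `orf_start`, `orf_end`; empty
#' ORF fields mean the transcript has no predicted ORF. Invariants enforced:
#' 1 <= orf_start < orf_end <= length and ORF length divisible by 3.
#'
#' @param path TSV file path
#' @return data.frame, one row per unigene, ORF columns `NA` when absent
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(unigene_id = "character"))
  req <- c("unigene_id", "length", "orf_start", "orf_end")
  if (!all(req %in% names(df))) {
    stop("annotation table must have columns: ", paste(req, collapse = ", "))
  }
  df$length <- as.integer(df$length)
  df$orf_start <- suppressWarnings(as.integer(df$orf_start))
  df$orf_end <- suppressWarnings(as.integer(df$orf_end))
  if (anyDuplicated(df$unigene_id)) {
    stop("duplicate unigene ids in annotation table")
  }
  has_orf <- !is.na(df$orf_start) | !is.na(df$orf_end)
  half <- has_orf & (is.na(df$orf_start) | is.na(df$orf_end))
  if (any(half)) {
    stop("validation error: ORF with only one endpoint for: ",
         paste(df$unigene_id[half], collapse = ", "))
  }
  with_orf <- which(has_orf)
  bad <- with_orf[
    df$orf_start[with_orf] < 1 |
      df$orf_start[with_orf] >= df$orf_end[with_orf] |
      df$orf_end[with_orf] > df$length[with_orf] |
      (df$orf_end[with_orf] - df$orf_start[with_orf] + 1L) %% 3L != 0L
  ]
  if (length(bad)) {
    stop("validation error: invalid ORF (bounds or length not divisible",
         " by 3) for: ", paste(df$unigene_id[bad], collapse = ", "))
  }
  df[, req]
}

#' Read transcript sequences
#' @param path FASTA file of unigene consensus sequences
#' @return a `Biostrings::DNAStringSet` named by unigene id
#' @export
read_transcripts <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; the id is the first token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

report_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Write the per-SNP divergence report
#'
#' Deterministic column order: unigene, position, Hs, Ht, G_ST, G'_ST,
#' Jost's D, phi_ST, Fisher p, significance flag, effect class. Numbers are
#' written with 6 significant digits.
#'
#' @param records data.frame from [snp_divergence()] (optionally carrying an
#'   `effect_class` column from [classify_effects()])
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_divergence_report <- function(records, path) {
  cols <- c("unigene", "position", "Hs", "Ht", "G_ST", "G_ST_Hedrick",
            "Jost_D", "phi_ST", "fisher_p", "significant", "effect_class")
  out <- data.frame(
    unigene = records$unigene_id %||% character(0),
    position = records$pos %||% integer(0),
    Hs = report_num(records$hs %||% numeric(0)),
    Ht = report_num(records$ht %||% numeric(0)),
    G_ST = report_num(records$gst %||% numeric(0)),
    G_ST_Hedrick = report_num(records$gst_hedrick %||% numeric(0)),
    Jost_D = report_num(records$jost_d %||% numeric(0)),
    phi_ST = report_num(records$phi_st %||% numeric(0)),
    fisher_p = report_num(records$fisher_p %||% numeric(0)),
    significant = records$significant %||% logical(0),
    effect_class = if (is.null(records$effect_class) && nrow(records) > 0)
      rep(NA_character_, nrow(records)) else
        (records$effect_class %||% character(0)),
    stringsAsFactors = FALSE
  )
  names(out) <- cols
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-gene, per-population diversity report
#'
#' Columns: unigene, population, pi_per_length, pi_per_snp, S, n_bar,
#' tajima_D, outlier.
#'
#' @param records data.frame from [gene_diversity()]
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_diversity_report <- function(records, path) {
  out <- data.frame(
    unigene = records$unigene_id %||% character(0),
    population = records$population %||% character(0),
    pi_per_length = report_num(records$pi_per_length %||% numeric(0)),
    pi_per_snp = report_num(records$pi_per_snp %||% numeric(0)),
    S = records$S %||% integer(0),
    n_bar = report_num(records$n_bar %||% numeric(0)),
    tajima_D = report_num(records$tajima_d %||% numeric(0)),
    outlier = records$outlier %||% logical(0),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
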