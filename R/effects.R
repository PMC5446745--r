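#' Transition test
#'
#' A substitution is a transition when it stays within the purines
#' \{A, G\} or within the pyrimidines \{C, T\}; of the 12 ordered base
#' pairs, 4 are transitions, so a uniform substitution model yields a 1/3
#' transition fraction.
#'
#' @param ref,alt single nucleotides in \{A, C, G, T\}, ref != alt
#'   (vectorized)
#' @return logical vector
#' @export
is_transition <- function(ref, alt) {
  valid <- c("A", "C", "G", "T")
  if (!all(ref %in% valid) || !all(alt %in% valid)) {
    stop("invalid base; alleles must be one of A, C, G, T")
  }
  if (any(ref == alt)) stop("ref == alt is not a substitution")
  purine <- c("A", "G")
  (ref %in% purine) == (alt %in% purine)
}

#' Classify a SNP against its transcript ORF
#'
#' No predicted ORF on the transcript: `noncoding`. Position outside the
#' ORF: `utr` (the side, 5' or 3', is recorded as the `utr_side` attribute
#' in [classify_effects()], not as a separate class). Inside the ORF the
#' containing codon is translated with the reference and with the alternate
#' base under the standard genetic code: same amino acid is `synonymous`,
#' anything else — including stop gain or loss — is `nonsynonymous`.
#'
#' @param pos 1-based position on the transcript
#' @param ref,alt SNP alleles
#' @param orf_start,orf_end 1-based inclusive ORF bounds, or `NA` for none
#' @param seq transcript sequence (character or `DNAString`)
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"utr"`, `"noncoding"`
#' @export
classify_snp <- function(pos, ref, alt, orf_start, orf_end, seq) {
  seq <- toupper(as.character(seq))
  if (pos > nchar(seq)) stop("position ", pos, " beyond transcript end")
  base <- substr(seq, pos, pos)
  if (base != ref) {
    stop("validation error: ref allele ", ref, " does not match transcript",
         " base ", base, " at position ", pos)
  }
  if (is.na(orf_start) || is.na(orf_end)) return("noncoding")
  if (pos < orf_start || pos > orf_end) return("utr")
  offset <- pos - orf_start               # 0-based within ORF
  codon_start <- orf_start + 3L * (offset %/% 3L)
  codon <- substr(seq, codon_start, codon_start + 2L)
  within <- offset %% 3L + 1L
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon])
  aa_alt <- unname(code[alt_codon])
  if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
}

#' Classify every SNP of a snp_set
#'
#' @param ss a [snp_set()]
#' @param annotations data.frame from [read_annotations()]
#' @param transcripts `DNAStringSet` from [read_transcripts()]
#' @return data.frame: unigene_id, pos, ref, alt, effect_class, utr_side
#'   (`"5prime"`/`"3prime"`/`NA`), transition (logical)
#' @export
classify_effects <- function(ss, annotations, transcripts) {
  ann <- annotations[match(ss$sites$unigene_id, annotations$unigene_id), ]
  if (any(is.na(ann$unigene_id))) {
    stop("no annotation for unigene(s): ",
         paste(unique(ss$sites$unigene_id[is.na(ann$unigene_id)]),
               collapse = ", "))
  }
  miss <- setdiff(unique(ss$sites$unigene_id), names(transcripts))
  if (length(miss)) {
    stop("no transcript sequence for unigene(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  seqs <- as.character(transcripts)
  n <- n_sites(ss)
  cls <- character(n)
  side <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cls[i] <- classify_snp(ss$sites$pos[i], ss$sites$ref[i], ss$sites$alt[i],
                           ann$orf_start[i], ann$orf_end[i],
                           seqs[[ss$sites$unigene_id[i]]])
    if (cls[i] == "utr") {
      side[i] <- if (ss$sites$pos[i] < ann$orf_start[i]) "5prime" else "3prime"
    }
  }
  data.frame(
    unigene_id = ss$sites$unigene_id, pos = ss$sites$pos,
    ref = ss$sites$ref, alt = ss$sites$alt,
    effect_class = cls, utr_side = side,
    transition = if (n) is_transition(ss$sites$ref, ss$sites$alt) else logical(0),
    stringsAsFactors = FALSE
  )
}

#' Effect-class summary percentages
#'
#' All percentages use the full set of classified (kept) SNPs as the
#' denominator: transitions, SNPs on ORF-bearing transcripts, SNPs inside
#' ORFs (= synonymous + nonsynonymous, exactly), synonymous, nonsynonymous,
#' UTR, and noncoding.
#'
#' @param effects data.frame from [classify_effects()]
#' @return list of counts (`n`) and percentages; empty list fields are
#'   `NA` when there are no SNPs
#' @export
effect_summary <- function(effects) {
  n <- nrow(effects)
  if (n == 0) {
    return(list(n = 0L, pct_transitions = NA_real_, pct_in_coding = NA_real_,
                pct_in_orf = NA_real_, pct_synonymous = NA_real_,
                pct_nonsynonymous = NA_real_, pct_utr = NA_real_,
                pct_noncoding = NA_real_))
  }
  pc <- function(x) 100 * sum(x) / n
  cls <- effects$effect_class
  list(
    n = n,
    pct_transitions = pc(effects$transition),
    pct_in_coding = pc(cls != "noncoding"),
    pct_in_orf = pc(cls %in% c("synonymous", "nonsynonymous")),
    pct_synonymous = pc(cls == "synonymous"),
    pct_nonsynonymous = pc(cls == "nonsynonymous"),
    pct_utr = pc(cls == "utr"),
    pct_noncoding = pc(cls == "noncoding")
  )
}
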