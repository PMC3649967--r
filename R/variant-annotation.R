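# Variant annotation module: effect-class partition, damaging consensus,
# allele frequencies, rarity, VCF parsing.

.broadMissenseTokens <- c("SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_DONOR",
                          "STOP_GAINED", "NON_SYNONYMOUS_CODING",
                          "STOP_LOST", "START_LOST", "START_GAINED")
.lofTokens <- c("SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_DONOR", "STOP_GAINED",
                "STOP_LOST")

.unknownTokenCache <- new.env(parent = emptyenv())

#' Classify a raw effect token into an effect class
#'
#' The broad "exonic missense" class comprises the seven tokens
#' `SPLICE_SITE_ACCEPTOR`, `SPLICE_SITE_DONOR`, `STOP_GAINED`,
#' `NON_SYNONYMOUS_CODING`, `STOP_LOST`, `START_LOST`, `START_GAINED`.
#' Within it, variants introducing or disrupting a stop codon or a splice
#' site (`SPLICE_SITE_*`, `STOP_GAINED`, `STOP_LOST`) are loss-of-function
#' (`LOF`); start-codon changes are broad missense but not LoF.
#' `SYNONYMOUS_CODING` maps to `SYNONYMOUS`; anything else to `OTHER`
#' (logged once per unknown token).
#'
#' @param raw_effect character vector of annotation tokens.
#' @return character vector of `"SYNONYMOUS"`, `"MISSENSE_BROAD"`, `"LOF"`,
#'   `"OTHER"`. Use [isBroadMissense()] for tallies where LoF is a subset of
#'   the broad class.
#' @examples
#' classifyEffect(c("STOP_GAINED", "NON_SYNONYMOUS_CODING",
#'                  "SYNONYMOUS_CODING"))
#' @export
classifyEffect <- function(raw_effect) {
  stopifnot(is.character(raw_effect), all(nzchar(raw_effect)))
  out <- rep("OTHER", length(raw_effect))
  out[raw_effect %in% .broadMissenseTokens] <- "MISSENSE_BROAD"
  out[raw_effect %in% .lofTokens] <- "LOF"
  out[raw_effect == "SYNONYMOUS_CODING"] <- "SYNONYMOUS"
  unknown <- setdiff(unique(raw_effect[out == "OTHER"]),
                     ls(.unknownTokenCache))
  for (tok in unknown) {
    essLog("classifyEffect: unknown token '%s' -> OTHER", tok)
    assign(tok, TRUE, envir = .unknownTokenCache)
  }
  out
}

#' Is an effect class part of the broad exonic-missense tally?
#'
#' LoF variants are a subset of the broad missense class in all "exonic
#' missense" tallies.
#'
#' @param effect_class character vector of effect classes.
#' @return logical vector.
#' @export
isBroadMissense <- function(effect_class) {
  effect_class %in% c("MISSENSE_BROAD", "LOF")
}

#' Damaging consensus of PolyPhen2 and SIFT
#'
#' A variant is putatively damaging only when both predictors call it
#' damaging; a missing call on either side yields `FALSE` (conservative).
#'
#' @param polyphen character, `"damaging"`, `"benign"` or `"missing"`/`NA`.
#' @param sift character, `"damaging"`, `"tolerated"` or `"missing"`/`NA`.
#' @return logical vector.
#' @examples
#' consensusDamaging("damaging", "damaging")  # TRUE
#' consensusDamaging("damaging", "missing")   # FALSE
#' @export
consensusDamaging <- function(polyphen, sift) {
  !is.na(polyphen) & !is.na(sift) & polyphen == "damaging" &
    sift == "damaging"
}

#' Allele frequency from one site's genotypes
#'
#' `af = alt-allele count / (2 x called diploid samples)`; missing genotypes
#' reduce the denominator.
#'
#' @param genotypes integer vector of alt-allele counts (0/1/2, `NA`
#'   missing).
#' @return allele frequency in `[0, 1]`.
#' @examples
#' computeAF(c(1, 0, 0, 0, 0))  # 0.1
#' @export
computeAF <- function(genotypes) {
  called <- sum(!is.na(genotypes))
  if (called == 0L) stop("all genotypes missing at site", call. = FALSE)
  sum(genotypes, na.rm = TRUE) / (2 * called)
}

#' Rare-variant flag (allele frequency strictly below 1%)
#'
#' @param af numeric allele frequencies.
#' @param threshold rarity threshold (default 0.01, strict `<`).
#' @return logical vector.
#' @examples
#' isRare(c(0.0099, 0.0100))  # TRUE FALSE
#' @export
isRare <- function(af, threshold = 0.01) {
  af < threshold
}

# Minimal VCFv4.1 writer for the synthetic-cohort dialect: one effect term
# per record in INFO key EFF ("TOKEN|GENE"), PolyPhen/SIFT calls in PP2/SIFT,
# AVGPOST genotype quality, unphased GT.
#' Write a VariantCohort as VCF v4.1
#'
#' @param cohort a [VariantCohort-class].
#' @param path output path (plain text).
#' @return the path, invisibly.
#' @export
writeCohortVCF <- function(cohort, path) {
  stopifnot(is(cohort, "VariantCohort"))
  v <- variantInfo(cohort)
  gt <- genotypeMatrix(cohort)
  hdr <- c(
    "##fileformat=VCFv4.1",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect token and gene: TOKEN|GENE\">",
    "##INFO=<ID=PP2,Number=1,Type=String,Description=\"PolyPhen2 call\">",
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"SIFT call\">",
    "##INFO=<ID=AVGPOST,Number=1,Type=Float,Description=\"Average posterior genotype probability\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t"))
  if (nrow(v)) {
    gtc <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nrow(gt))
    gtc[is.na(gt)] <- "./."
    info <- sprintf("EFF=%s|%s;PP2=%s;SIFT=%s;AVGPOST=%s", v$raw_effect,
                    v$gene_id, v$polyphen, v$sift,
                    format(v$avgpost, trim = TRUE, scientific = FALSE))
    body <- paste(v$chrom, v$pos, sprintf("var%05d", seq_len(nrow(v))),
                  v$ref, v$alt, ".", "PASS", info, "GT",
                  apply(gtc, 1L, paste, collapse = "\t"), sep = "\t")
  } else {
    body <- character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse an annotated VCF into a VariantCohort
#'
#' Reads a VCF v4.x with EFF-style annotation (`EFF=TOKEN|GENE`) and
#' PolyPhen2/SIFT call fields via `VariantAnnotation::readVcf`. Multi-allelic
#' rows are split; records without a gene assignment are dropped with a
#' logged count. Allele frequencies are recomputed from the genotypes.
#'
#' @param path VCF path (plain or bgzipped).
#' @return A [VariantCohort-class].
#' @export
parseCohortVCF <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  n <- nrow(vcf)
  samples <- colnames(vcf)
  if (n == 0L) {
    return(VariantCohort(
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), gene_id = character(0),
                 raw_effect = character(0), effect_class = character(0),
                 polyphen = character(0), sift = character(0),
                 damaging_consensus = logical(0), af = numeric(0),
                 rare = logical(0), avgpost = numeric(0)),
      matrix(integer(0), 0, length(samples),
             dimnames = list(NULL, samples))))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  eff <- as.character(info$EFF)
  parts <- strsplit(ifelse(is.na(eff), "|", eff), "|", fixed = TRUE)
  tok <- vapply(parts, function(p) if (length(p) >= 1) p[1] else "", "")
  gene <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")

  gtc <- VariantAnnotation::geno(vcf)$GT
  gt <- matrix(NA_integer_, nrow = n, ncol = length(samples),
               dimnames = list(NULL, samples))
  gt[gtc %in% c("0/0", "0|0")] <- 0L
  gt[gtc %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt[gtc %in% c("1/1", "1|1")] <- 2L

  # biallelic SNVs with a gene assignment only
  ref <- as.character(SummarizedExperiment::rowRanges(vcf)$REF)
  alt <- as.character(SummarizedExperiment::rowRanges(vcf)$ALT)
  snv <- nchar(ref) == 1L & nchar(alt) == 1L
  keep <- nzchar(gene) & snv
  if (any(!keep)) {
    essLog("parseCohortVCF: dropped %d records (no gene assignment or not SNV)",
           sum(!keep))
  }
  gt <- gt[keep, , drop = FALSE]
  called <- rowSums(!is.na(gt))
  af <- ifelse(called > 0, rowSums(gt, na.rm = TRUE) / (2 * called),
               NA_real_)
  pp <- as.character(info$PP2)[keep]
  sift <- as.character(info$SIFT)[keep]
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = ref[keep], alt = alt[keep], gene_id = gene[keep],
    raw_effect = tok[keep], effect_class = classifyEffect(tok[keep]),
    polyphen = pp, sift = sift,
    damaging_consensus = consensusDamaging(pp, sift),
    af = as.numeric(af), rare = isRare(af),
    avgpost = as.numeric(info$AVGPOST)[keep],
    stringsAsFactors = FALSE)
  VariantCohort(variants, gt)
}

#' Flag variants present in a curated high-confidence LoF list
#'
#' @param cohort a [VariantCohort-class].
#' @param hc_list data.frame `chrom`, `pos`, `ref`, `alt` (duplicate rows
#'   are deduplicated).
#' @return the cohort with a logical `hc_lof` rowData column.
#' @export
intersectHcLof <- function(cohort, hc_list) {
  stopifnot(is(cohort, "VariantCohort"),
            all(c("chrom", "pos", "ref", "alt") %in% names(hc_list)))
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  hc <- unique(key(hc_list))
  rowData(cohort)$hc_lof <- key(variantInfo(cohort)) %in% hc
  cohort
}
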