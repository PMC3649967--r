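# Constraint statistics module: length-corrected variant rates and Z-scores,
# Wilcoxon comparisons, Fisher 2x2 panels with Woolf CIs, SFS shift,
# promoter conservation means, generic gene-set metric comparisons.

#' Length-corrected per-gene variant rates and Z-scores
#'
#' For each gene, `rate = count of matching variants / exon_length_bp`.
#' Z-scores are computed relative to the full catalog ("genome average"):
#' `z = (rate - mean) / sd` over all genes in the catalog. The `zlog`
#' variant Z-normalizes `log(count + 1)` (a Box-Cox log transform with a
#' pseudo-count of 1) instead of the raw rate.
#'
#' @param cohort a [VariantCohort-class] (or a variant data.frame).
#' @param catalog a [GeneCatalog-class]; all its genes enter the rate table
#'   (genes without matching variants count 0).
#' @param effect_filter which variants to count: `"missense_broad"`
#'   (broad class including LoF), `"lof"`, `"synonymous"`, `"damaging"`
#'   (broad missense with damaging consensus) or `"all"`.
#' @param rare_only restrict to rare (<1%) variants.
#' @return data.frame `gene_id`, `ess_class`, `count`, `exon_length_bp`,
#'   `rate`, `log1p_count`, `z`, `zlog`.
#' @export
lengthCorrectedRate <- function(cohort, catalog,
                                effect_filter = c("missense_broad", "lof",
                                                  "synonymous", "damaging",
                                                  "all"),
                                rare_only = FALSE) {
  effect_filter <- match.arg(effect_filter)
  stopifnot(is(catalog, "GeneCatalog"))
  v <- if (is(cohort, "VariantCohort")) variantInfo(cohort) else cohort
  g <- geneTable(catalog)
  if (any(g$exon_length_bp <= 0)) {
    stop("zero-length gene in catalog", call. = FALSE)
  }
  sel <- switch(effect_filter,
    missense_broad = isBroadMissense(v$effect_class),
    lof = v$effect_class == "LOF",
    synonymous = v$effect_class == "SYNONYMOUS",
    damaging = isBroadMissense(v$effect_class) & v$damaging_consensus,
    all = rep(TRUE, nrow(v)))
  if (rare_only) sel <- sel & v$rare
  counts <- table(factor(v$gene_id[sel], levels = g$gene_id))
  out <- data.frame(gene_id = g$gene_id, ess_class = g$ess_class,
                    count = as.integer(counts),
                    exon_length_bp = g$exon_length_bp,
                    stringsAsFactors = FALSE)
  out$rate <- out$count / out$exon_length_bp
  out$log1p_count <- log1p(out$count)
  zOf <- function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mean(x)) / s
  }
  out$z <- zOf(out$rate)
  out$zlog <- zOf(out$log1p_count)
  out
}

#' Wilcoxon rank-sum / signed-rank comparison
#'
#' Wraps `stats::wilcox.test`: exact p for small samples without ties,
#' normal approximation with continuity correction otherwise. A paired test
#' whose differences are all zero carries no evidence and returns p = 1.
#'
#' @param a,b numeric value vectors (paired tests require equal lengths).
#' @param alternative `"less"` (a stochastically smaller), `"greater"` or
#'   `"two.sided"`.
#' @param paired logical.
#' @return A [TestResult-class].
#' @examples
#' pValue(wilcoxonCompare(1:3, 4:6, alternative = "less"))  # 0.05
#' @export
wilcoxonCompare <- function(a, b, alternative = c("two.sided", "less",
                                                  "greater"),
                            paired = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (paired) {
    if (length(a) != length(b)) {
      stop("paired comparison requires equal lengths", call. = FALSE)
    }
    keep <- !(is.na(a) | is.na(b))
    a <- a[keep]; b <- b[keep]
    if (all(a == b)) {
      return(TestResult(statistic = 0, pValue = 1,
                        sidedness = if (alternative == "two.sided") "two"
                                    else "one",
                        paired = TRUE, note = "all differences zero"))
    }
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(unique(c(a, b))) == 1L) {
      # every observation tied: carries no evidence
      return(TestResult(statistic = length(a) * length(b) / 2, pValue = 1,
                        sidedness = if (alternative == "two.sided") "two"
                                    else "one",
                        paired = FALSE, note = "all values tied"))
    }
  }
  ht <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                     paired = paired, correct = TRUE))
  TestResult(statistic = unname(ht$statistic), pValue = ht$p.value,
             sidedness = if (alternative == "two.sided") "two" else "one",
             paired = paired)
}

#' Two-sided Fisher's exact test with odds ratio and Woolf CI
#'
#' The exact p-value is computed by full enumeration of the hypergeometric
#' support conditional on the table margins (two-sided: sum of all outcome
#' probabilities not exceeding the observed one, with the customary 1e-7
#' relative tolerance). The default odds-ratio estimate is the conditional
#' maximum-likelihood value as computed by `stats::fisher.test` (the
#' field's standard point estimate for this test);
#' `or_method = "sample"` gives the cross-product `(a d) / (b c)`. The 95%
#' CI is Woolf's logit interval
#' `exp(log(OR_sample) +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Tables with
#' a zero cell get a 0.5 continuity correction on every cell and the
#' corrected cross-product estimate (flagged in the result's `note`); the
#' p-value is always exact.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major `a, b, c, d`) of
#'   non-negative integer counts.
#' @param or_method `"conditional"` (conditional MLE, default) or
#'   `"sample"` (cross-product).
#' @return A [TestResult-class] with `oddsRatio` and `ci95`.
#' @examples
#' res <- fisher2x2(rbind(c(399, 2073), c(588, 3223)))
#' round(oddsRatio(res), 2)  # 1.05
#' round(ci95(res), 2)       # 0.92 1.21
#' @export
fisher2x2 <- function(table, or_method = c("conditional", "sample")) {
  or_method <- match.arg(or_method)
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, 2,
                                         byrow = TRUE)
  stopifnot(dim(table) == c(2, 2), all(table >= 0),
            all(abs(table - round(table)) < 1e-9))
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  if (r1 + r2 == 0) stop("empty table", call. = FALSE)
  # enumeration of the conditional (hypergeometric) support for cell a
  kmin <- max(0, c1 - r2); kmax <- min(r1, c1)
  support <- kmin:kmax
  pr <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  note <- character(0)
  zero_cell <- any(table == 0)
  if (zero_cell) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
    note <- "0.5 continuity correction applied for OR/CI"
  }
  or_sample <- (a * d) / (b * c_)
  or <- if (or_method == "conditional" && !zero_cell) {
    unname(stats::fisher.test(table)$estimate)
  } else {
    or_sample
  }
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  TestResult(pValue = p, sidedness = "two", paired = FALSE, oddsRatio = or,
             ci95 = exp(log(or_sample) + c(-1.96, 1.96) * se), note = note)
}

.defaultSfsBins <- c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.5)

#' Site-frequency-spectrum relative excess of a variant set
#'
#' Per-bin excess = (share of the set's variants in the bin) minus (share of
#' the comparator's variants in the bin); a positive value in low-frequency
#' bins indicates a shift towards rare variants. An accompanying one-sided
#' Wilcoxon on the raw frequencies tests "the set is rarer".
#'
#' @param af_set allele frequencies of the focal set (non-empty).
#' @param af_all allele frequencies of the comparator.
#' @param bins bin break points (intervals are `(lo, hi]`, with the first
#'   interval closed below at 0).
#' @return list with `table` (data.frame `bin`, `share_set`, `share_all`,
#'   `excess`) and `test` (a [TestResult-class]).
#' @export
sfsRelativeExcess <- function(af_set, af_all, bins = .defaultSfsBins) {
  if (!length(af_set)) stop("empty focal set", call. = FALSE)
  if (!length(af_all)) stop("empty comparator set", call. = FALSE)
  cutShare <- function(x) {
    cnt <- table(cut(x, breaks = bins, include.lowest = TRUE, right = TRUE))
    as.numeric(cnt) / length(x)
  }
  share_set <- cutShare(af_set)
  share_all <- cutShare(af_all)
  lab <- levels(cut(numeric(0), breaks = bins, include.lowest = TRUE))
  list(table = data.frame(bin = lab, share_set = share_set,
                          share_all = share_all,
                          excess = share_set - share_all,
                          stringsAsFactors = FALSE),
       test = wilcoxonCompare(af_set, af_all, alternative = "less"))
}

#' Mean conservation score in promoter windows
#'
#' Per-gene arithmetic mean of per-base scores in
#' `[tss - window_bp, tss + window_bp]` (strand-symmetric); interval scores
#' are weighted by the number of covered bases in the window and missing
#' bases are omitted from the mean. Genes with no covered bases get `NA`
#' (logged).
#'
#' @param track a [GenomicRanges::GRanges] with a `score` column, or a
#'   bedGraph file path (imported via `rtracklayer`).
#' @param catalog a [GeneCatalog-class].
#' @param window_bp half-window around the TSS (default 100).
#' @return data.frame `gene_id`, `mean_score`.
#' @export
promoterMeanScore <- function(track, catalog, window_bp = 100L) {
  stopifnot(is(catalog, "GeneCatalog"))
  if (is.character(track)) {
    track <- rtracklayer::import(track, format = "bedGraph")
  }
  g <- geneTable(catalog)
  win <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, g$tss - window_bp),
                              end = g$tss + window_bp))
  hits <- GenomicRanges::findOverlaps(win, track)
  ov <- GenomicRanges::pintersect(win[S4Vectors::queryHits(hits)],
                                  track[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  sc <- track$score[S4Vectors::subjectHits(hits)]
  qi <- S4Vectors::queryHits(hits)
  num <- tapply(w * sc, qi, sum)
  den <- tapply(w, qi, sum)
  mean_score <- rep(NA_real_, nrow(g))
  mean_score[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  if (anyNA(mean_score)) {
    essLog("promoterMeanScore: %d genes with no covered bases",
           sum(is.na(mean_score)))
  }
  data.frame(gene_id = g$gene_id, mean_score = mean_score,
             stringsAsFactors = FALSE)
}

#' Compare a per-gene metric between two gene sets
#'
#' Generic engine for comparing per-gene metrics (dN/dS, promoter or exon
#' conservation, transcript counts, genotype-quality means, ...) between
#' gene sets by Wilcoxon rank-sum test, with a Z-normalized summary (means
#' of the metric Z-scored over all supplied values).
#'
#' @param metric data.frame `gene_id`, `value` (one row per gene).
#' @param catalog a [GeneCatalog-class].
#' @param setA,setB gene-set names (`"EG"`, `"NLG"`, `"OTHER"`, `"ALL"`) or
#'   character vectors of gene ids.
#' @param alternative passed to [wilcoxonCompare()]; `"less"` tests "setA's
#'   metric is stochastically smaller".
#' @return list with `test` (a [TestResult-class]) and `summary`
#'   (data.frame of n, mean, mean z per set).
#' @export
compareGeneSets <- function(metric, catalog, setA = "EG", setB = "NLG",
                            alternative = "two.sided") {
  stopifnot(all(c("gene_id", "value") %in% names(metric)))
  resolve <- function(s) {
    if (length(s) == 1L && s %in% c("EG", "NLG", "OTHER", "ALL")) {
      geneSet(catalog, s)
    } else s
  }
  idsA <- resolve(setA); idsB <- resolve(setB)
  metric <- metric[!is.na(metric$value), , drop = FALSE]
  va <- metric$value[metric$gene_id %in% idsA]
  vb <- metric$value[metric$gene_id %in% idsB]
  if (!length(va) || !length(vb)) {
    stop("metric undefined on one of the sets", call. = FALSE)
  }
  mu <- mean(metric$value); s <- sd(metric$value)
  zm <- function(v) if (is.na(s) || s == 0) NA_real_ else mean((v - mu) / s)
  list(test = wilcoxonCompare(va, vb, alternative = alternative),
       summary = data.frame(
         set = c(if (is.character(setA) && length(setA) == 1L) setA else "setA",
                 if (is.character(setB) && length(setB) == 1L) setB else "setB"),
         n = c(length(va), length(vb)),
         mean = c(mean(va), mean(vb)),
         mean_z = c(zm(va), zm(vb)),
         stringsAsFactors = FALSE))
}
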