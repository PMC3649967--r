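#' GeneCatalog: the gene universe with essentiality classes and flags
#'
#' An S4 container for the protein-coding gene universe. Each row is one gene
#' with identifiers, TSS coordinate, total exonic length (bp), GC percent,
#' an essentiality class (`EG` = human ortholog of a mouse gene whose
#' homozygous knockout is lethal, `NLG` = ortholog of a gene with a non-lethal
#' homozygous knockout phenotype, `OTHER` = remainder of the universe) and
#' optional logical annotation flags (`hgmd`, `haploinsufficient`,
#' `ubiquitous_top10`, `brain_overexpressed`, `asd_candidate`).
#'
#' @slot genes data.frame with required columns `gene_id`, `symbol`, `chrom`,
#'   `tss`, `strand`, `exon_length_bp`, `gc_pct`, `ess_class`.
#' @seealso [GeneCatalog()], [classifyGenes()], [annotateFlags()]
#' @exportClass GeneCatalog
setClass("GeneCatalog", representation(genes = "data.frame"))

.geneCatalogRequired <- c("gene_id", "symbol", "chrom", "tss", "strand",
                          "exon_length_bp", "gc_pct", "ess_class")

setValidity("GeneCatalog", function(object) {
  g <- object@genes
  missing <- setdiff(.geneCatalogRequired, names(g))
  if (length(missing)) {
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  }
  if (nrow(g) == 0L) return(TRUE)
  if (anyDuplicated(g$gene_id)) return("gene_id values must be unique")
  if (any(g$exon_length_bp <= 0)) return("exon_length_bp must be > 0")
  if (any(g$gc_pct < 0 | g$gc_pct > 100)) return("gc_pct must be in [0, 100]")
  if (!all(g$ess_class %in% c("EG", "NLG", "OTHER"))) {
    return("ess_class must be one of EG, NLG, OTHER")
  }
  if (!all(g$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  TRUE
})

#' Construct a GeneCatalog
#'
#' @param genes data.frame of gene records (see [GeneCatalog-class]).
#' @return A [GeneCatalog-class] object.
#' @examples
#' gc <- GeneCatalog(data.frame(
#'   gene_id = "G1", symbol = "GENE1", chrom = "1", tss = 1000L,
#'   strand = "+", exon_length_bp = 1500, gc_pct = 45, ess_class = "OTHER"))
#' nGenes(gc)
#' @export
GeneCatalog <- function(genes) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes)) rownames(genes) <- genes$gene_id
  new("GeneCatalog", genes = genes)
}

#' VariantCohort: typed biallelic variants with per-sample genotypes
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a `GT` assay of
#' alternate-allele counts (0/1/2, `NA` = missing) and variant annotation in
#' `rowData`: location, assigned gene, raw effect token and effect class,
#' PolyPhen2/SIFT calls and their damaging consensus, allele frequency,
#' rare (<1%) flag and the AVGPOST genotype-quality field.
#'
#' @seealso [VariantCohort()], [parseCohortVCF()], [simulateCohort()]
#' @exportClass VariantCohort
setClass("VariantCohort", contains = "SummarizedExperiment")

.variantCohortRequired <- c("chrom", "pos", "ref", "alt", "gene_id",
                            "raw_effect", "effect_class", "polyphen", "sift",
                            "damaging_consensus", "af", "rare", "avgpost")

setValidity("VariantCohort", function(object) {
  if (!"GT" %in% assayNames(object)) return("assay 'GT' is required")
  rd <- rowData(object)
  missing <- setdiff(.variantCohortRequired, names(rd))
  if (length(missing)) {
    return(paste("missing rowData columns:", paste(missing, collapse = ", ")))
  }
  if (nrow(object) == 0L) return(TRUE)
  gt <- assay(object, "GT")
  if (!all(gt %in% c(0L, 1L, 2L, NA))) return("GT must be 0, 1, 2 or NA")
  if (any(rd$af < 0 | rd$af > 1, na.rm = TRUE)) return("af must be in [0, 1]")
  if (!all(rd$effect_class %in% c("SYNONYMOUS", "MISSENSE_BROAD", "LOF",
                                  "OTHER"))) {
    return("unknown effect_class value")
  }
  TRUE
})

#' Construct a VariantCohort
#'
#' @param variants data.frame/DataFrame of variant records, one row per
#'   biallelic site (columns listed under [VariantCohort-class]).
#' @param genotypes integer matrix of alternate-allele counts, variants in
#'   rows, samples in columns (column names are sample ids).
#' @param truth optional list of generator ground truth, stored in
#'   `metadata()`.
#' @return A [VariantCohort-class] object.
#' @export
VariantCohort <- function(variants, genotypes, truth = NULL) {
  variants <- S4Vectors::DataFrame(variants)
  storage.mode(genotypes) <- "integer"
  se <- SummarizedExperiment(assays = list(GT = genotypes),
                             rowData = variants)
  obj <- new("VariantCohort", se)
  if (!is.null(truth)) metadata(obj)$truth <- truth
  obj
}

#' TestResult: outcome of a two-group or 2x2 comparison
#'
#' @slot statistic numeric test statistic (may be `NA` for exact tests).
#' @slot pValue numeric p-value in `[0, 1]`.
#' @slot sidedness `"one"` or `"two"`.
#' @slot paired logical.
#' @slot oddsRatio numeric(0) or the sample odds ratio.
#' @slot ci95 numeric(0) or `c(low, high)` (Woolf logit interval).
#' @slot note character, e.g. records a continuity correction.
#' @exportClass TestResult
setClass("TestResult", representation(
  statistic = "numeric", pValue = "numeric", sidedness = "character",
  paired = "logical", oddsRatio = "numeric", ci95 = "numeric",
  note = "character"))

setValidity("TestResult", function(object) {
  if (length(object@pValue) != 1L || is.na(object@pValue) ||
      object@pValue < 0 || object@pValue > 1) {
    return("pValue must be a single value in [0, 1]")
  }
  if (!object@sidedness %in% c("one", "two")) {
    return("sidedness must be 'one' or 'two'")
  }
  if (length(object@ci95) == 2L && length(object@oddsRatio) == 1L) {
    if (!is.na(object@oddsRatio) &&
        (object@oddsRatio < object@ci95[1] - 1e-12 ||
         object@oddsRatio > object@ci95[2] + 1e-12)) {
      return("oddsRatio must lie within ci95")
    }
  }
  TRUE
})

TestResult <- function(statistic = NA_real_, pValue, sidedness = "two",
                       paired = FALSE, oddsRatio = numeric(0),
                       ci95 = numeric(0), note = character(0)) {
  new("TestResult", statistic = as.numeric(statistic),
      pValue = as.numeric(pValue), sidedness = sidedness, paired = paired,
      oddsRatio = as.numeric(oddsRatio), ci95 = as.numeric(ci95), note = note)
}

#' DenovoStudyResult: one study's matched-permutation enrichment result
#'
#' @slot studyId character study label.
#' @slot arm `"case"` or `"control"`.
#' @slot nEvents integer number of de novo events tested.
#' @slot obsInSet integer events observed in the gene set.
#' @slot expInSet numeric permutation mean of in-set events.
#' @slot expExact numeric exact expectation `sum(|pool ∩ set| / |pool|)`.
#' @slot logAdjOR numeric log adjusted odds ratio.
#' @slot seLogOR numeric SD of replicate log-odds (meta-analysis SE).
#' @slot permPOne,permPTwo numeric add-one permutation p-values (one-sided
#'   enrichment; two-sided by doubling, capped at 1).
#' @slot nPerm integer number of permutation replicates.
#' @exportClass DenovoStudyResult
setClass("DenovoStudyResult", representation(
  studyId = "character", arm = "character", nEvents = "integer",
  obsInSet = "integer", expInSet = "numeric", expExact = "numeric",
  logAdjOR = "numeric", seLogOR = "numeric", permPOne = "numeric",
  permPTwo = "numeric", nPerm = "integer"))

setValidity("DenovoStudyResult", function(object) {
  if (object@seLogOR < 0) return("seLogOR must be >= 0")
  if (object@expInSet < 0 || object@expInSet > object@nEvents) {
    return("expInSet must be in [0, nEvents]")
  }
  if (object@obsInSet < 0 || object@obsInSet > object@nEvents) {
    return("obsInSet must be in [0, nEvents]")
  }
  TRUE
})

#' DenovoMetaResult: fixed-effects combination of study results
#'
#' @slot combinedOR numeric combined odds ratio.
#' @slot ci95 numeric `c(low, high)` 95% CI.
#' @slot metaP numeric two-sided p from the normal deviate.
#' @slot cochranQ numeric heterogeneity statistic.
#' @slot qDf integer `n_studies - 1`.
#' @slot qP numeric chi-square upper-tail p for Q.
#' @slot studies data.frame of the per-study inputs.
#' @exportClass DenovoMetaResult
setClass("DenovoMetaResult", representation(
  combinedOR = "numeric", ci95 = "numeric", metaP = "numeric",
  cochranQ = "numeric", qDf = "integer", qP = "numeric",
  studies = "data.frame"))

setValidity("DenovoMetaResult", function(object) {
  if (length(object@ci95) != 2L) return("ci95 must have length 2")
  if (object@qDf != nrow(object@studies) - 1L) {
    return("qDf must equal n_studies - 1")
  }
  lo <- min(object@studies$log_adj_or)
  hi <- max(object@studies$log_adj_or)
  if (log(object@combinedOR) < lo - 1e-9 || log(object@combinedOR) > hi + 1e-9) {
    return("combined log-OR must lie within the range of study log-ORs")
  }
  TRUE
})
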