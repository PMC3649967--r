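# Generics and accessor/show methods for the core classes.

#' @describeIn GeneCatalog-class the underlying gene data.frame.
#' @param x,object a `GeneCatalog`.
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @export
setMethod("geneTable", "GeneCatalog", function(x) x@genes)

#' @describeIn GeneCatalog-class number of genes.
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @export
setMethod("nGenes", "GeneCatalog", function(x) nrow(x@genes))

#' @describeIn GeneCatalog-class character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setMethod("geneIds", "GeneCatalog", function(x) x@genes$gene_id)

#' @describeIn GeneCatalog-class essentiality class, named by gene id.
#' @export
setGeneric("essClass", function(x) standardGeneric("essClass"))

#' @export
setMethod("essClass", "GeneCatalog", function(x) {
  setNames(x@genes$ess_class, x@genes$gene_id)
})

#' Gene ids belonging to a gene set
#'
#' @param x a `GeneCatalog`.
#' @param set `"EG"`, `"NLG"`, `"OTHER"` or `"ALL"` (the whole universe).
#' @return character vector of gene ids.
#' @export
setGeneric("geneSet", function(x, set) standardGeneric("geneSet"))

#' @export
setMethod("geneSet", "GeneCatalog", function(x, set = c("EG", "NLG", "OTHER",
                                                        "ALL")) {
  set <- match.arg(set)
  if (set == "ALL") return(x@genes$gene_id)
  x@genes$gene_id[x@genes$ess_class == set]
})

setMethod("show", "GeneCatalog", function(object) {
  tab <- table(factor(object@genes$ess_class,
                      levels = c("EG", "NLG", "OTHER")))
  cat("GeneCatalog with", nrow(object@genes), "genes\n")
  cat(sprintf("  EG: %d  NLG: %d  OTHER: %d\n", tab["EG"], tab["NLG"],
              tab["OTHER"]))
  flags <- intersect(c("hgmd", "haploinsufficient", "ubiquitous_top10",
                       "brain_overexpressed", "asd_candidate"),
                     names(object@genes))
  if (length(flags)) cat("  flags:", paste(flags, collapse = ", "), "\n")
})

#' @describeIn VariantCohort-class variant annotation as a data.frame.
#' @param x,object a `VariantCohort`.
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @export
setMethod("variantInfo", "VariantCohort", function(x) {
  as.data.frame(rowData(x))
})

#' @describeIn VariantCohort-class integer matrix of alt-allele counts.
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @export
setMethod("genotypeMatrix", "VariantCohort", function(x) assay(x, "GT"))

#' @describeIn VariantCohort-class sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setMethod("sampleIds", "VariantCohort", function(x) colnames(x))

setMethod("show", "VariantCohort", function(object) {
  cls <- table(factor(rowData(object)$effect_class,
                      levels = c("SYNONYMOUS", "MISSENSE_BROAD", "LOF",
                                 "OTHER")))
  cat("VariantCohort:", nrow(object), "biallelic sites x", ncol(object),
      "samples\n")
  cat(sprintf("  synonymous: %d  missense(broad, non-LoF): %d  LoF: %d  other: %d\n",
              cls[1], cls[2], cls[3], cls[4]))
  cat(sprintf("  rare (<1%%): %d  damaging consensus: %d\n",
              sum(rowData(object)$rare), sum(rowData(object)$damaging_consensus)))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult (%s-sided%s): p = %.4g\n", object@sidedness,
              if (object@paired) ", paired" else "", object@pValue))
  if (length(object@oddsRatio)) {
    cat(sprintf("  OR = %.4g", object@oddsRatio))
    if (length(object@ci95) == 2L) {
      cat(sprintf(" (95%% CI %.4g-%.4g)", object@ci95[1], object@ci95[2]))
    }
    cat("\n")
  }
  if (length(object@note)) cat("  note:", object@note, "\n")
})

#' @describeIn TestResult-class the p-value.
#' @param x,object a result object.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @describeIn TestResult-class the sample odds ratio (or `NA`).
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @export
setMethod("oddsRatio", "TestResult", function(x) {
  if (length(x@oddsRatio)) x@oddsRatio else NA_real_
})

#' @describeIn TestResult-class 95% confidence interval `c(low, high)`.
#' @export
setGeneric("ci95", function(x) standardGeneric("ci95"))

#' @export
setMethod("ci95", "TestResult", function(x) {
  if (length(x@ci95) == 2L) x@ci95 else c(NA_real_, NA_real_)
})

#' @describeIn DenovoStudyResult-class length and GC adjusted odds ratio.
#' @export
setGeneric("adjustedOR", function(x) standardGeneric("adjustedOR"))

#' @export
setMethod("adjustedOR", "DenovoStudyResult", function(x) exp(x@logAdjOR))

#' @describeIn DenovoStudyResult-class observed events in the gene set.
#' @export
setGeneric("obsInSet", function(x) standardGeneric("obsInSet"))

#' @export
setMethod("obsInSet", "DenovoStudyResult", function(x) x@obsInSet)

#' @describeIn DenovoStudyResult-class permutation mean of in-set events.
#' @export
setGeneric("expInSet", function(x) standardGeneric("expInSet"))

#' @export
setMethod("expInSet", "DenovoStudyResult", function(x) x@expInSet)

#' @describeIn DenovoStudyResult-class one-sided add-one permutation p.
#' @export
setGeneric("permP", function(x) standardGeneric("permP"))

#' @export
setMethod("permP", "DenovoStudyResult", function(x) x@permPOne)

setMethod("show", "DenovoStudyResult", function(object) {
  cat(sprintf("DenovoStudyResult '%s' (%s arm): %d events\n", object@studyId,
              object@arm, object@nEvents))
  cat(sprintf("  obs in set = %d, exp = %.2f (exact %.2f), adj OR = %.3f\n",
              object@obsInSet, object@expInSet, object@expExact,
              exp(object@logAdjOR)))
  cat(sprintf("  perm p (one-sided) = %.4g over %d permutations\n",
              object@permPOne, object@nPerm))
})

#' @describeIn DenovoMetaResult-class combined odds ratio.
#' @export
setGeneric("combinedOR", function(x) standardGeneric("combinedOR"))

#' @export
setMethod("combinedOR", "DenovoMetaResult", function(x) x@combinedOR)

#' @export
setMethod("pValue", "DenovoMetaResult", function(x) x@metaP)

#' @export
setMethod("ci95", "DenovoMetaResult", function(x) x@ci95)

#' @describeIn DenovoMetaResult-class Cochran's Q heterogeneity statistic.
#' @export
setGeneric("cochranQ", function(x) standardGeneric("cochranQ"))

#' @export
setMethod("cochranQ", "DenovoMetaResult", function(x) x@cochranQ)

setMethod("show", "DenovoMetaResult", function(object) {
  cat(sprintf("DenovoMetaResult over %d studies (fixed effects)\n",
              nrow(object@studies)))
  cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              object@combinedOR, object@ci95[1], object@ci95[2],
              object@metaP))
  cat(sprintf("  Cochran's Q = %.3f (df %d), p = %.4g\n", object@cochranQ,
              object@qDf, object@qP))
})
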