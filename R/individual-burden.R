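# Individual burden module: per-sample mutational-load accounting over gene
# sets and frequency strata.

#' Per-sample mutational load over a gene set and frequency stratum
#'
#' A variant counts for a sample iff the sample carries at least one
#' alternate allele at the site (site-level counting: a hom-alt genotype
#' counts the variant once; het/hom LoF tallies are tracked separately for
#' the het/hom ratio). Counts are restricted to genes in `gene_set` and, for
#' the `rare` stratum, to variants with allele frequency < 1%.
#'
#' Chromosome-Y genes are excluded when the cohort declares no Y genotypes
#' (mirroring call sets without Y data).
#'
#' @param cohort a [VariantCohort-class].
#' @param catalog a [GeneCatalog-class].
#' @param gene_set `"EG"`, `"NLG"`, `"OTHER"`, `"ALL"` or a character vector
#'   of gene ids.
#' @param stratum `"all"` or `"rare"`.
#' @return data.frame with one row per sample: `sample_id`, `gene_set`,
#'   `stratum`, `n_missense_broad`, `n_synonymous`, `ns_ratio` (`NA` when no
#'   synonymous variants), `n_damaging`, `n_lof`, `lof_fraction` (`NA` when
#'   no broad-missense variants), `n_lof_het`, `n_lof_hom`, `genes_hit`.
#' @export
perSampleLoad <- function(cohort, catalog, gene_set = "ALL",
                          stratum = c("all", "rare")) {
  stratum <- match.arg(stratum)
  stopifnot(is(cohort, "VariantCohort"), is(catalog, "GeneCatalog"))
  v <- variantInfo(cohort)
  gt <- genotypeMatrix(cohort)
  set_label <- if (length(gene_set) == 1L &&
                   gene_set %in% c("EG", "NLG", "OTHER", "ALL")) {
    gene_set
  } else "custom"
  ids <- if (set_label == "custom") gene_set else geneSet(catalog, set_label)
  g <- geneTable(catalog)
  if (!any(v$chrom == "Y")) {
    ids <- setdiff(ids, g$gene_id[g$chrom == "Y"])
  }

  keep <- v$gene_id %in% ids
  if (stratum == "rare") keep <- keep & v$rare
  v <- v[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  carrier <- !is.na(gt) & gt > 0

  broad <- isBroadMissense(v$effect_class)
  lof <- v$effect_class == "LOF"
  syn <- v$effect_class == "SYNONYMOUS"
  dam <- broad & v$damaging_consensus

  cnt <- function(sel) as.integer(colSums(carrier[sel, , drop = FALSE]))
  n_mis <- cnt(broad)
  n_syn <- cnt(syn)
  n_dam <- cnt(dam)
  n_lof <- cnt(lof)
  n_lof_het <- as.integer(colSums(!is.na(gt[lof, , drop = FALSE]) &
                                    gt[lof, , drop = FALSE] == 1L))
  n_lof_hom <- as.integer(colSums(!is.na(gt[lof, , drop = FALSE]) &
                                    gt[lof, , drop = FALSE] == 2L))
  exonic <- broad | syn
  genes_hit <- vapply(seq_len(ncol(gt)), function(j) {
    length(unique(v$gene_id[exonic & carrier[, j]]))
  }, integer(1))

  data.frame(
    sample_id = colnames(gt), gene_set = set_label, stratum = stratum,
    n_missense_broad = n_mis, n_synonymous = n_syn,
    ns_ratio = ifelse(n_syn > 0, n_mis / n_syn, NA_real_),
    n_damaging = n_dam, n_lof = n_lof,
    lof_fraction = ifelse(n_mis > 0, n_lof / n_mis, NA_real_),
    n_lof_het = n_lof_het, n_lof_hom = n_lof_hom, genes_hit = genes_hit,
    stringsAsFactors = FALSE)
}

#' Per-sample loads over several gene sets and strata
#'
#' @inheritParams perSampleLoad
#' @param gene_sets,strata character vectors of sets / strata.
#' @return long data.frame of [perSampleLoad()] rows.
#' @export
sampleLoads <- function(cohort, catalog, gene_sets = c("EG", "NLG", "ALL"),
                        strata = c("all", "rare")) {
  out <- lapply(strata, function(st) {
    do.call(rbind, lapply(gene_sets, function(gs) {
      perSampleLoad(cohort, catalog, gene_set = gs, stratum = st)
    }))
  })
  do.call(rbind, out)
}

#' Cohort summary of per-sample loads with paired set comparisons
#'
#' Means and sample standard deviations per gene set and stratum for the
#' chosen load measure, plus paired one-sided Wilcoxon signed-rank tests of
#' EG versus NLG within samples (the paired test is used because two
#' properties of the same individuals are compared). Samples with an
#' undefined measure (e.g. an `ns_ratio` with zero synonymous count) are
#' excluded pairwise from the test.
#'
#' @param loads data.frame from [sampleLoads()].
#' @param measure load column to summarize (e.g. `"n_missense_broad"`,
#'   `"n_damaging"`, `"n_lof"`, `"ns_ratio"`, `"lof_fraction"`).
#' @param alternative alternative for the EG-vs-NLG paired test (default
#'   `"less"`: EG load smaller).
#' @return list with `summary` (set x stratum means/SDs) and `tests`
#'   (data.frame of paired EG-vs-NLG p-values per stratum; `NA` when either
#'   set is absent from `loads`).
#' @export
cohortSummary <- function(loads, measure = "n_missense_broad",
                          alternative = "less") {
  stopifnot(measure %in% names(loads))
  if (length(unique(loads$sample_id)) < 2L) {
    stop("cohort summary requires >= 2 samples", call. = FALSE)
  }
  spl <- split(loads, list(loads$gene_set, loads$stratum), drop = TRUE)
  summary <- do.call(rbind, lapply(spl, function(d) {
    data.frame(gene_set = d$gene_set[1], stratum = d$stratum[1],
               n_samples = nrow(d), mean = mean(d[[measure]], na.rm = TRUE),
               sd = sd(d[[measure]][!is.na(d[[measure]])]),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  tests <- do.call(rbind, lapply(unique(loads$stratum), function(st) {
    eg <- loads[loads$gene_set == "EG" & loads$stratum == st, ]
    nlg <- loads[loads$gene_set == "NLG" & loads$stratum == st, ]
    if (!nrow(eg) || !nrow(nlg)) {
      return(data.frame(stratum = st, p = NA_real_))
    }
    nlg <- nlg[match(eg$sample_id, nlg$sample_id), ]
    res <- wilcoxonCompare(eg[[measure]], nlg[[measure]],
                           alternative = alternative, paired = TRUE)
    data.frame(stratum = st, p = pValue(res), stringsAsFactors = FALSE)
  }))
  list(summary = summary, tests = tests)
}

#' Fraction of samples carrying at least one LoF variant
#'
#' @param loads data.frame from [sampleLoads()] or [perSampleLoad()].
#' @return data.frame `gene_set`, `stratum`, `n_samples`, `n_with_lof`,
#'   `fraction`.
#' @export
fractionSamplesWithLof <- function(loads) {
  spl <- split(loads, list(loads$gene_set, loads$stratum), drop = TRUE)
  out <- do.call(rbind, lapply(spl, function(d) {
    data.frame(gene_set = d$gene_set[1], stratum = d$stratum[1],
               n_samples = nrow(d), n_with_lof = sum(d$n_lof >= 1L),
               fraction = mean(d$n_lof >= 1L), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
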