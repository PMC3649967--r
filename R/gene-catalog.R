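# Gene catalog module: EG / NLG / OTHER classification from mouse phenotype
# annotations plus an ortholog map, and per-gene annotation flags.

#' Classify universe genes into EG / NLG / OTHER
#'
#' A gene is `EG` iff its mouse ortholog carries at least one homozygous
#' lethal-code annotation and has a one-to-one human ortholog; if a gene has
#' both lethal and non-lethal annotations it is assigned to EG (lethal wins).
#' A gene is `NLG` iff it carries at least one homozygous non-lethal
#' annotation, no homozygous lethal annotation, and has a one-to-one
#' ortholog. Phenotypes observed only in the heterozygote state are
#' disregarded. All remaining universe genes are `OTHER`.
#'
#' Mouse genes mapping to more than one human gene (or human genes mapped by
#' more than one mouse gene) are excluded with a warning; phenotype rows for
#' mouse genes absent from the ortholog map are excluded.
#'
#' @param phenotypes data.frame `mouse_gene`, `phenotype_code`, `zygosity`
#'   (`hom`/`het`).
#' @param lethal_codes character vector (or data.frame with column `code`)
#'   of lethal phenotype codes.
#' @param orthologs data.frame `mouse_gene`, `human_gene`.
#' @param universe a [GeneCatalog-class]; its `ess_class` is recomputed.
#' @return A [GeneCatalog-class] with `ess_class` assigned.
#' @export
classifyGenes <- function(phenotypes, lethal_codes, orthologs, universe) {
  stopifnot(is(universe, "GeneCatalog"),
            all(c("mouse_gene", "phenotype_code", "zygosity") %in%
                  names(phenotypes)),
            all(c("mouse_gene", "human_gene") %in% names(orthologs)))
  if (is.data.frame(lethal_codes)) lethal_codes <- lethal_codes$code
  if (!length(lethal_codes)) stop("lethal code set is empty", call. = FALSE)
  if (!all(phenotypes$zygosity %in% c("hom", "het"))) {
    stop("zygosity must be 'hom' or 'het'", call. = FALSE)
  }

  # enforce one-to-one orthology
  orthologs <- unique(orthologs[, c("mouse_gene", "human_gene")])
  multi_m <- unique(orthologs$mouse_gene[duplicated(orthologs$mouse_gene)])
  multi_h <- unique(orthologs$human_gene[duplicated(orthologs$human_gene)])
  drop <- orthologs$mouse_gene %in% multi_m |
    orthologs$human_gene %in% multi_h
  if (any(drop)) {
    warning(sprintf("dropped %d ortholog rows that are not one-to-one",
                    sum(drop)), call. = FALSE)
    orthologs <- orthologs[!drop, , drop = FALSE]
  }
  map <- setNames(orthologs$human_gene, orthologs$mouse_gene)

  hom <- phenotypes[phenotypes$zygosity == "hom", , drop = FALSE]
  unmapped <- setdiff(unique(hom$mouse_gene), names(map))
  if (length(unmapped)) {
    essLog("classifyGenes: %d annotated mouse genes have no one-to-one ortholog; excluded",
           length(unmapped))
  }
  hom <- hom[hom$mouse_gene %in% names(map), , drop = FALSE]
  hom$human_gene <- unname(map[hom$mouse_gene])

  g <- geneTable(universe)
  known <- hom$human_gene %in% g$gene_id
  if (any(!known)) {
    warning(sprintf("%d phenotype rows map to genes outside the universe; excluded",
                    sum(!known)), call. = FALSE)
    hom <- hom[known, , drop = FALSE]
  }

  lethal <- hom$phenotype_code %in% lethal_codes
  eg <- unique(hom$human_gene[lethal])
  nlg <- setdiff(unique(hom$human_gene[!lethal]), eg)
  g$ess_class <- "OTHER"
  g$ess_class[g$gene_id %in% eg] <- "EG"
  g$ess_class[g$gene_id %in% nlg] <- "NLG"
  essLog("classifyGenes: %d EG, %d NLG, %d OTHER", length(eg), length(nlg),
         nrow(g) - length(eg) - length(nlg))
  GeneCatalog(g)
}

#' Coefficient of variation (sample SD over mean)
#'
#' @param values numeric expression values for one gene.
#' @return `sd(values) / mean(values)` using the sample standard deviation.
#' @examples
#' expressionCV(c(2, 4))  # 0.4714
#' @export
expressionCV <- function(values) {
  stopifnot(length(values) >= 2)
  sd(values) / mean(values)
}

#' Attach per-gene annotation flags
#'
#' Membership flags are set by list inclusion; `ubiquitous_top10` is set iff
#' the gene's expression-CV rank falls within the lowest `top_frac` of
#' ranked genes (low CV = ubiquitous expression); `brain_overexpressed` is
#' set iff the brain over-expression p-value is `<= brain_p_threshold`
#' (inclusive). Unknown gene ids in flag lists are logged and ignored.
#'
#' @param catalog a [GeneCatalog-class].
#' @param flag_lists named list of gene-id character vectors (e.g. `hgmd`,
#'   `haploinsufficient`, `asd_candidate`).
#' @param expression_cv data.frame `gene_id`, `cv` (optional).
#' @param brain_p data.frame `gene_id`, `p` (optional).
#' @param top_frac fraction of ranked genes flagged ubiquitous (default 0.10).
#' @param brain_p_threshold inclusive p threshold (default 1e-4).
#' @return The catalog with logical flag columns added.
#' @export
annotateFlags <- function(catalog, flag_lists = list(), expression_cv = NULL,
                          brain_p = NULL, top_frac = 0.10,
                          brain_p_threshold = 1e-4) {
  stopifnot(is(catalog, "GeneCatalog"), top_frac > 0, top_frac <= 1)
  g <- geneTable(catalog)
  for (nm in names(flag_lists)) {
    ids <- flag_lists[[nm]]
    unknown <- setdiff(ids, g$gene_id)
    if (length(unknown)) {
      essLog("annotateFlags: %d unknown ids in flag '%s' ignored",
             length(unknown), nm)
    }
    g[[nm]] <- g$gene_id %in% ids
  }
  if (!is.null(expression_cv)) {
    stopifnot(all(c("gene_id", "cv") %in% names(expression_cv)))
    ranked <- expression_cv[expression_cv$gene_id %in% g$gene_id, ,
                            drop = FALSE]
    n_top <- max(1L, floor(top_frac * nrow(ranked) + 1e-9))
    top <- ranked$gene_id[order(ranked$cv)][seq_len(min(n_top, nrow(ranked)))]
    g$ubiquitous_top10 <- g$gene_id %in% top
  }
  if (!is.null(brain_p)) {
    stopifnot(all(c("gene_id", "p") %in% names(brain_p)))
    hit <- brain_p$gene_id[brain_p$p <= brain_p_threshold]
    g$brain_overexpressed <- g$gene_id %in% hit
  }
  GeneCatalog(g)
}

#' Per-class counts and a 2x2 table for a flag
#'
#' For flag `F` returns the contingency table
#' `[[|EG & F|, |EG & !F|], [|NLG & F|, |NLG & !F|]]` (rows may be chosen
#' with `classes`), the shape consumed by [fisher2x2()].
#'
#' @param catalog a [GeneCatalog-class] with the flag column present.
#' @param flag name of a logical flag column.
#' @param classes the two row classes (default `c("EG", "NLG")`).
#' @return 2x2 integer matrix.
#' @export
setCounts <- function(catalog, flag, classes = c("EG", "NLG")) {
  stopifnot(is(catalog, "GeneCatalog"), length(classes) == 2L)
  g <- geneTable(catalog)
  if (!flag %in% names(g)) stop("unknown flag column: ", flag, call. = FALSE)
  f <- as.logical(g[[flag]])
  rows <- lapply(classes, function(cl) {
    inc <- g$ess_class == cl
    c(sum(inc & f), sum(inc & !f))
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(classes, c("flag", "no_flag"))
  m
}

#' Read / write the annotated gene table
#'
#' TSV columns: `gene_id`, `symbol`, `chrom`, `tss`, `strand`,
#' `exon_length_bp`, `gc_pct`, `ess_class` plus any flag columns.
#'
#' @param path file path.
#' @param catalog a [GeneCatalog-class] (for writing).
#' @return [readGeneTable()] returns a [GeneCatalog-class];
#'   [writeGeneTable()] returns the path invisibly.
#' @export
readGeneTable <- function(path) {
  g <- readTsv(path)
  g$chrom <- as.character(g$chrom)
  GeneCatalog(g)
}

#' @rdname readGeneTable
#' @export
writeGeneTable <- function(catalog, path) {
  writeTsv(geneTable(catalog), path)
}
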