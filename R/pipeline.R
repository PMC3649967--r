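# Pipeline module: config-driven end-to-end runs. `writeInputBundle`
# materializes a full synthetic input bundle (the `simulate` stage);
# `runReport` consumes a bundle and emits one TSV per figure-style panel
# plus a reproducibility manifest (the `report` stage). A thin CLI wrapper
# with these two subcommands ships in inst/scripts/essvar-cli.R.

#' Default run configuration
#'
#' Thresholds: rare allele frequency < 0.01, brain over-expression
#' p <= 1e-4, ubiquitous top fraction 0.10, matching tolerances
#' +/- 100 bp exon length and +/- 2.5% GC.
#'
#' @param out_dir output directory.
#' @param n_genes,n_samples synthetic universe / cohort size.
#' @param n_studies number of de novo studies.
#' @param true_or ground-truth case enrichment odds for EG.
#' @param n_perm permutation replicates per study.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
runConfig <- function(out_dir = ".", n_genes = 2000L, n_samples = 100L,
                      n_studies = 4L, true_or = 1.4, n_perm = 1000L,
                      seed = 1L) {
  structure(list(out_dir = out_dir, n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_studies = as.integer(n_studies), true_or = true_or,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 rare_af = 0.01, brain_p = 1e-4, ubiquitous_top_frac = 0.10,
                 len_tol = 100, gc_tol = 2.5),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' Unset keys fall back to [runConfig()] defaults.
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- runConfig()
  for (nm in intersect(names(y), names(cfg))) cfg[[nm]] <- y[[nm]]
  cfg$n_genes <- as.integer(cfg$n_genes)
  cfg$n_samples <- as.integer(cfg$n_samples)
  cfg$n_studies <- as.integer(cfg$n_studies)
  cfg$n_perm <- as.integer(cfg$n_perm)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Write a full synthetic input bundle
#'
#' Generates and writes every pipeline input: gene universe TSV, phenotype
#' and ortholog TSVs, multi-sample annotated VCF, conservation bedGraph,
#' substitution-rate TSV, expression CV and brain-p TSVs, de novo study
#' TSV, and a truth-record YAML holding the generating parameters.
#'
#' @param cfg a [runConfig()].
#' @return invisible named list of written paths.
#' @export
writeInputBundle <- function(cfg = runConfig()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- deriveSeeds(cfg$seed, 6L + cfg$n_studies)
  p <- function(f) file.path(cfg$out_dir, f)

  universe <- generateGeneUniverse(universeConfig(n_genes = cfg$n_genes,
                                                  seed = seeds[1]))
  writeGeneTable(universe, p("gene_universe.tsv"))

  ph <- simulatePhenotypes(universe, seed = seeds[2])
  writeTsv(ph$phenotypes, p("phenotypes.tsv"))
  writeTsv(ph$orthologs, p("orthologs.tsv"))

  cohort <- simulateCohort(universe, cohortConfig(n_samples = cfg$n_samples,
                                                  seed = seeds[3]))
  writeCohortVCF(cohort, p("cohort.vcf"))

  track <- simulateConservationTrack(universe, seed = seeds[4])
  rtracklayer::export(track, p("conservation.bedGraph"), format = "bedGraph")

  writeTsv(simulateSubstitutionRates(universe, seed = seeds[5]),
           p("substitution_rates.tsv"))
  expr <- simulateExpressionTables(universe, seed = seeds[6])
  writeTsv(expr$cv, p("expression_cv.tsv"))
  writeTsv(expr$brain_p, p("brain_p.tsv"))

  studies <- do.call(rbind, lapply(seq_len(cfg$n_studies), function(i) {
    simulateDenovoStudy(universe, denovoStudyConfig(
      study_id = sprintf("study%d", i), n_case_events = 300L,
      n_control_events = 150L, true_or = cfg$true_or,
      seed = seeds[6L + i]))
  }))
  writeDenovoEvents(studies, p("denovo_events.tsv"))

  truth <- list(seed = cfg$seed, n_genes = cfg$n_genes,
                n_samples = cfg$n_samples, n_studies = cfg$n_studies,
                true_or = cfg$true_or,
                class_counts = as.list(table(essClass(universe))))
  yaml::write_yaml(truth, p("truth.yaml"))
  essLog("writeInputBundle: %d genes, %d samples, %d studies -> %s",
         cfg$n_genes, cfg$n_samples, cfg$n_studies, cfg$out_dir)
  invisible(list(
    universe = p("gene_universe.tsv"), phenotypes = p("phenotypes.tsv"),
    orthologs = p("orthologs.tsv"), vcf = p("cohort.vcf"),
    conservation = p("conservation.bedGraph"),
    substitution_rates = p("substitution_rates.tsv"),
    expression_cv = p("expression_cv.tsv"), brain_p = p("brain_p.tsv"),
    denovo = p("denovo_events.tsv"), truth = p("truth.yaml")))
}

#' Run the full analysis over an input bundle and write report tables
#'
#' Reads a bundle written by [writeInputBundle()] (or equivalently shaped
#' real inputs), re-derives the gene classification from the phenotype and
#' ortholog tables, and writes one TSV per analysis panel: flag enrichment
#' 2x2 Fisher panels, length-corrected rate comparisons and SFS shift,
#' per-sample burden summaries, promoter conservation and dN/dS
#' comparisons, the per-study and meta de novo enrichment results, and a
#' run manifest with input checksums.
#'
#' @param bundle_dir directory holding the input bundle.
#' @param cfg a [runConfig()] (thresholds, permutations, seed); `out_dir`
#'   names the report directory.
#' @return invisible named list of result objects.
#' @export
runReport <- function(bundle_dir, cfg = runConfig()) {
  stopifnot(dir.exists(bundle_dir))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  bp <- function(f) {
    fp <- file.path(bundle_dir, f)
    if (!file.exists(fp)) stop("missing bundle input: ", fp, call. = FALSE)
    fp
  }
  op <- function(f) file.path(cfg$out_dir, f)

  universe <- readGeneTable(bp("gene_universe.tsv"))
  phenotypes <- readTsv(bp("phenotypes.tsv"))
  orthologs <- readTsv(bp("orthologs.tsv"))
  catalog <- suppressWarnings(
    classifyGenes(phenotypes, readLethalCodes(), orthologs, universe))
  expr_cv <- readTsv(bp("expression_cv.tsv"))
  brain_p <- readTsv(bp("brain_p.tsv"))
  catalog <- annotateFlags(catalog, expression_cv = expr_cv,
                           brain_p = brain_p,
                           top_frac = cfg$ubiquitous_top_frac,
                           brain_p_threshold = cfg$brain_p)
  writeGeneTable(catalog, op("gene_catalog.tsv"))

  # flag enrichment panels (Fisher 2x2, EG vs NLG)
  panels <- do.call(rbind, lapply(c("ubiquitous_top10", "brain_overexpressed"),
    function(fl) {
      tab <- setCounts(catalog, fl)
      res <- fisher2x2(tab)
      data.frame(flag = fl, eg_flag = tab[1, 1], eg_noflag = tab[1, 2],
                 nlg_flag = tab[2, 1], nlg_noflag = tab[2, 2],
                 or = oddsRatio(res), ci_low = ci95(res)[1],
                 ci_high = ci95(res)[2], p = pValue(res),
                 stringsAsFactors = FALSE)
    }))
  writeTsv(panels, op("flag_enrichment.tsv"))

  # variant-level constraint panels
  cohort <- parseCohortVCF(bp("cohort.vcf"))
  rates <- lengthCorrectedRate(cohort, catalog, "missense_broad")
  rate_tests <- do.call(rbind, lapply(c(NLG = "NLG", OTHER = "OTHER"),
    function(cmp) {
      res <- wilcoxonCompare(rates$rate[rates$ess_class == "EG"],
                             rates$rate[rates$ess_class == cmp],
                             alternative = "less")
      data.frame(comparison = paste0("EG_vs_", cmp), p = pValue(res))
    }))
  writeTsv(cbind(rate_tests,
                 mean_z_eg = mean(rates$z[rates$ess_class == "EG"])),
           op("rate_comparison.tsv"))

  v <- variantInfo(cohort)
  eg_af <- v$af[v$gene_id %in% geneSet(catalog, "EG") &
                  isBroadMissense(v$effect_class)]
  all_af <- v$af[isBroadMissense(v$effect_class)]
  sfs <- sfsRelativeExcess(eg_af, all_af)
  writeTsv(cbind(sfs$table, p_rarer = pValue(sfs$test)), op("sfs_shift.tsv"))

  # burden panels
  loads <- sampleLoads(cohort, catalog)
  writeTsv(loads, op("sample_loads.tsv"))
  bs <- cohortSummary(loads, "n_missense_broad")
  writeTsv(merge(bs$summary, bs$tests, by = "stratum", all.x = TRUE),
           op("burden_summary.tsv"))
  writeTsv(fractionSamplesWithLof(loads), op("lof_sample_fraction.tsv"))

  # conservation and substitution-rate panels
  prom <- promoterMeanScore(bp("conservation.bedGraph"), catalog,
                            window_bp = 100L)
  prom_cmp <- compareGeneSets(
    data.frame(gene_id = prom$gene_id, value = prom$mean_score),
    catalog, "EG", "NLG", alternative = "greater")
  subs <- readTsv(bp("substitution_rates.tsv"))
  dnds_cmp <- compareGeneSets(
    data.frame(gene_id = subs$gene_id[subs$species == "rhesus"],
               value = subs$dnds[subs$species == "rhesus"]),
    catalog, "EG", "NLG", alternative = "less")
  writeTsv(data.frame(
    metric = c("promoter_phylop", "dnds_rhesus"),
    p = c(pValue(prom_cmp$test), pValue(dnds_cmp$test)),
    mean_eg = c(prom_cmp$summary$mean[1], dnds_cmp$summary$mean[1]),
    mean_nlg = c(prom_cmp$summary$mean[2], dnds_cmp$summary$mean[2])),
    op("conservation_comparison.tsv"))

  # de novo enrichment (per-study + meta, case and control arms)
  events <- readDenovoEvents(bp("denovo_events.tsv"))
  dn <- runDenovoAnalysis(events, catalog, gene_set = "EG",
                          include_synonymous = FALSE, n_perm = cfg$n_perm,
                          seed = cfg$seed, len_tol_bp = cfg$len_tol,
                          gc_tol_pct = cfg$gc_tol)
  dn_tab <- do.call(rbind, lapply(c("case", "control"), function(arm) {
    if (is.null(dn[[arm]])) return(NULL)
    st <- dn[[arm]]$meta@studies
    st$arm <- arm
    st$adj_or <- exp(st$log_adj_or)
    st
  }))
  writeTsv(dn_tab, op("denovo_per_study.tsv"))
  meta_tab <- do.call(rbind, lapply(c("case", "control"), function(arm) {
    if (is.null(dn[[arm]])) return(NULL)
    m <- dn[[arm]]$meta
    data.frame(arm = arm, or = combinedOR(m), ci_low = ci95(m)[1],
               ci_high = ci95(m)[2], p = pValue(m), q = cochranQ(m),
               q_df = m@qDf, q_p = m@qP, stringsAsFactors = FALSE)
  }))
  writeTsv(meta_tab, op("denovo_meta.tsv"))

  # manifest: inputs, checksums, seed, versions
  inputs <- list.files(bundle_dir, full.names = TRUE)
  manifest <- data.frame(
    file = basename(inputs), md5 = unname(tools::md5sum(inputs)),
    stringsAsFactors = FALSE)
  yaml::write_yaml(list(package = "essvar",
                        version = as.character(utils::packageVersion("essvar")),
                        r_version = as.character(getRversion()),
                        seed = cfg$seed, n_perm = cfg$n_perm,
                        thresholds = cfg[c("rare_af", "brain_p",
                                           "ubiquitous_top_frac", "len_tol",
                                           "gc_tol")],
                        inputs = setNames(as.list(manifest$md5),
                                          manifest$file)),
                   op("manifest.yaml"))
  essLog("runReport: report written to %s", cfg$out_dir)
  invisible(list(catalog = catalog, panels = panels, rates = rates,
                 sfs = sfs, loads = loads, denovo = dn))
}
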