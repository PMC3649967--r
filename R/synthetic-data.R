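# Synthetic-data module: generates every pipeline input from explicit
# distributions with known ground truth, so the analysis can be exercised
# and calibrated without external downloads.

.effectTokens <- list(
  synonymous = "SYNONYMOUS_CODING",
  missense   = c("NON_SYNONYMOUS_CODING", "START_LOST", "START_GAINED"),
  lof        = c("SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_DONOR", "STOP_GAINED",
                 "STOP_LOST"))

#' Configuration for the synthetic gene universe
#'
#' Total exonic length is log-normal; essential genes (EG) are longer on
#' average by `eg_length_multiplier` (matching the observation that essential
#' genes have longer coding sequence). GC percent is truncated normal on
#' `[20, 80]`. Defaults describe a genome-scale universe with EG/NLG
#' fractions equal to 2472/20029 and 3811/20029.
#'
#' @param n_genes number of genes.
#' @param eg_fraction,nlg_fraction class proportions (sum must be <= 1).
#' @param length_law `c(meanlog, sdlog)` of the log-normal over exon length.
#' @param eg_length_multiplier multiplicative length effect for EG (> 0).
#' @param gc_law `c(mean, sd)` of the truncated normal over GC percent.
#' @param seed integer RNG seed.
#' @return A validated list of class `universe_config`.
#' @export
universeConfig <- function(n_genes = 20000L, eg_fraction = 2472 / 20029,
                           nlg_fraction = 3811 / 20029,
                           length_law = c(meanlog = 7.3, sdlog = 0.8),
                           eg_length_multiplier = 1.5,
                           gc_law = c(mean = 46, sd = 9), seed = 1L) {
  stopifnot(n_genes >= 0, eg_fraction >= 0, nlg_fraction >= 0,
            length(length_law) == 2L, length_law[2] >= 0,
            eg_length_multiplier > 0, length(gc_law) == 2L, gc_law[2] >= 0)
  if (eg_fraction + nlg_fraction > 1 + 1e-12) {
    stop("eg_fraction + nlg_fraction must be <= 1", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), eg_fraction = eg_fraction,
                 nlg_fraction = nlg_fraction, length_law = length_law,
                 eg_length_multiplier = eg_length_multiplier, gc_law = gc_law,
                 seed = as.integer(seed)),
            class = "universe_config")
}

#' Generate a synthetic gene universe
#'
#' @param cfg a [universeConfig()].
#' @return A [GeneCatalog-class] with `ess_class` labels in the configured
#'   proportions; deterministic for a fixed seed. Lengths are floored at
#'   100 bp; GC lies in `[20, 80]`.
#' @examples
#' gu <- generateGeneUniverse(universeConfig(n_genes = 100, seed = 7))
#' table(essClass(gu))
#' @export
generateGeneUniverse <- function(cfg) {
  stopifnot(inherits(cfg, "universe_config"))
  n <- cfg$n_genes
  if (n == 0L) {
    return(GeneCatalog(data.frame(gene_id = character(0),
      symbol = character(0), chrom = character(0), tss = integer(0),
      strand = character(0), exon_length_bp = numeric(0),
      gc_pct = numeric(0), ess_class = character(0))))
  }
  withSeed(cfg$seed, {
    n_eg <- round(n * cfg$eg_fraction)
    n_nlg <- min(round(n * cfg$nlg_fraction), n - n_eg)
    cls <- sample(rep(c("EG", "NLG", "OTHER"),
                      c(n_eg, n_nlg, n - n_eg - n_nlg)))
    len <- rlnorm(n, cfg$length_law[1], cfg$length_law[2])
    len <- len * ifelse(cls == "EG", cfg$eg_length_multiplier, 1)
    len <- pmax(100, round(len))
    gc <- rtruncnorm(n, cfg$gc_law[1], cfg$gc_law[2], 20, 80)
    ids <- sprintf("G%05d", seq_len(n))
    GeneCatalog(data.frame(
      gene_id = ids,
      symbol = sprintf("GENE%d", seq_len(n)),
      chrom = as.character(sample(c(1:22, "X"), n, replace = TRUE)),
      tss = sample.int(2e8, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      exon_length_bp = len,
      gc_pct = gc,
      ess_class = cls,
      stringsAsFactors = FALSE))
  })
}

#' Generate mouse phenotype annotations and an ortholog map from known labels
#'
#' Emulates a phenotype dump (mouse gene, phenotype code, zygosity) and a
#' mouse-to-human ortholog table such that [classifyGenes()] recovers the
#' catalog's `ess_class` labels exactly. The tables deliberately exercise the
#' classification rules: EG genes may carry extra non-lethal and
#' heterozygous-lethal rows (lethal-wins), NLG genes may carry
#' heterozygous-lethal rows (disregarded), some OTHER genes carry
#' heterozygous-only lethal annotations, and decoy mouse genes with
#' one-to-many ortholog rows are included (they must be dropped).
#'
#' @param catalog a [GeneCatalog-class] with class labels.
#' @param lethal_codes character vector of lethal phenotype codes (default:
#'   the first three codes of the shipped synthetic lethal-code list).
#' @param nonlethal_codes character vector of non-lethal phenotype codes.
#' @param p_extra_nonlethal probability an EG gene also has a non-lethal row.
#' @param p_het_lethal probability of an extra heterozygous lethal row.
#' @param n_decoys number of one-to-many decoy mouse genes.
#' @param seed integer RNG seed.
#' @return list with `phenotypes` (mouse_gene, phenotype_code, zygosity) and
#'   `orthologs` (mouse_gene, human_gene) data.frames.
#' @export
simulatePhenotypes <- function(catalog, lethal_codes = NULL,
                               nonlethal_codes = sprintf("MP:NL%04d", 1:20),
                               p_extra_nonlethal = 0.3, p_het_lethal = 0.2,
                               n_decoys = 2L, seed = 1L) {
  stopifnot(is(catalog, "GeneCatalog"))
  if (is.null(lethal_codes)) lethal_codes <- readLethalCodes()$code[1:3]
  g <- geneTable(catalog)
  if (nrow(g) == 0L) stop("empty gene catalog", call. = FALSE)
  withSeed(seed, {
    mouse <- setNames(paste0("Mm_", g$gene_id), g$gene_id)
    orth <- data.frame(mouse_gene = unname(mouse), human_gene = g$gene_id,
                       stringsAsFactors = FALSE)
    rows <- list()
    addRow <- function(mg, code, zyg) {
      rows[[length(rows) + 1L]] <<- data.frame(mouse_gene = mg,
        phenotype_code = code, zygosity = zyg, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(g))) {
      mg <- mouse[[g$gene_id[i]]]
      cls <- g$ess_class[i]
      if (cls == "EG") {
        addRow(mg, sample(lethal_codes, 1L), "hom")
        if (runif(1) < p_extra_nonlethal) {
          addRow(mg, sample(nonlethal_codes, 1L), "hom")
        }
        if (runif(1) < p_het_lethal) addRow(mg, sample(lethal_codes, 1L), "het")
      } else if (cls == "NLG") {
        addRow(mg, sample(nonlethal_codes, 1L), "hom")
        if (runif(1) < p_het_lethal) addRow(mg, sample(lethal_codes, 1L), "het")
      } else if (runif(1) < 0.1) {
        # some OTHER genes have het-only lethal annotations (disregarded)
        addRow(mg, sample(lethal_codes, 1L), "het")
      }
    }
    # decoy mouse genes mapping to two human genes; classifyGenes must drop
    # them regardless of their (lethal) annotations
    if (n_decoys > 0L && nrow(g) >= 2L) {
      for (k in seq_len(n_decoys)) {
        dm <- sprintf("Mm_DECOY%02d", k)
        pool <- g$gene_id[g$ess_class == "OTHER"]
        if (length(pool) < 2L) pool <- g$gene_id
        tg <- sample(pool, 2L)
        orth <- rbind(orth, data.frame(mouse_gene = dm, human_gene = tg))
        addRow(dm, sample(lethal_codes, 1L), "hom")
      }
    }
    list(phenotypes = do.call(rbind, rows), orthologs = orth)
  })
}

#' Configuration for the synthetic diploid cohort
#'
#' Per-gene site counts per variant class are Poisson with mean
#' `site_rate[class] * exon_length * constraint_multiplier[class, ess_class]`.
#' Allele frequencies are drawn from a discretized law `f(x) ~ x^(-af_alpha)`
#' on the grid `j / (2 n_samples)`; essential-gene sites get an exponent
#' increment `rare_skew_eg`, shifting their spectrum towards rare alleles.
#' Genotypes are Hardy-Weinberg draws at the site frequency. PolyPhen2 and
#' SIFT calls are drawn independently given a latent damaging state so the
#' consensus logic is exercised.
#'
#' @param n_samples diploid individuals (>= 1).
#' @param site_rate named numeric, variants per bp per variant class
#'   (`synonymous`, `missense` = broad missense excluding LoF tokens,
#'   `lof`) for the unconstrained baseline.
#' @param constraint_multiplier numeric matrix, rows `synonymous`,
#'   `missense`, `lof`; columns `EG`, `NLG`, `OTHER`; entries in `[0, 1]`.
#' @param af_alpha shape of the allele-frequency law (>= 0).
#' @param rare_skew_eg extra exponent on rare frequencies for EG sites.
#' @param damaging_prob probability a (broad) missense site is latently
#'   damaging.
#' @param damaging_concordance probability each predictor matches the latent
#'   state.
#' @param seed integer RNG seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohortConfig <- function(n_samples = 100L,
                         site_rate = c(synonymous = 2e-3, missense = 2.2e-3,
                                       lof = 1.5e-4),
                         constraint_multiplier = defaultConstraintMultiplier(),
                         af_alpha = 1, rare_skew_eg = 0.5,
                         damaging_prob = 0.35, damaging_concordance = 0.9,
                         seed = 1L) {
  stopifnot(n_samples >= 1, all(site_rate >= 0),
            all(c("synonymous", "missense", "lof") %in% names(site_rate)),
            is.matrix(constraint_multiplier),
            all(constraint_multiplier >= 0 & constraint_multiplier <= 1),
            af_alpha >= 0, rare_skew_eg >= 0,
            damaging_prob >= 0, damaging_prob <= 1,
            damaging_concordance >= 0, damaging_concordance <= 1)
  structure(list(n_samples = as.integer(n_samples), site_rate = site_rate,
                 constraint_multiplier = constraint_multiplier,
                 af_alpha = af_alpha, rare_skew_eg = rare_skew_eg,
                 damaging_prob = damaging_prob,
                 damaging_concordance = damaging_concordance,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default constraint multipliers (variant class x essentiality class)
#'
#' Synonymous sites are unconstrained in every class; broad missense and LoF
#' rates are reduced in EG (and mildly in NLG), reproducing the qualitative
#' constraint signature: fewer missense variants per bp, lower LoF fraction.
#' @return 3x3 numeric matrix.
#' @export
defaultConstraintMultiplier <- function() {
  m <- rbind(synonymous = c(1, 1, 1),
             missense   = c(0.5, 0.9, 1),
             lof        = c(0.3, 0.8, 1))
  colnames(m) <- c("EG", "NLG", "OTHER")
  m
}

# Discretized allele-frequency law on the grid j/(2N), j = 1..N (max 0.5):
# weights proportional to x^(-alpha).
drawAlleleFrequencies <- function(n, n_chrom, alpha) {
  j <- seq_len(max(1L, floor(n_chrom / 2)))
  x <- j / n_chrom
  w <- x^(-alpha)
  sample(x, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate an annotated diploid cohort over a gene universe
#'
#' @param catalog a non-empty [GeneCatalog-class].
#' @param cfg a [cohortConfig()].
#' @return A [VariantCohort-class]; `metadata()$truth` records the config and
#'   the realized per-gene site counts per variant class.
#' @examples
#' gu <- generateGeneUniverse(universeConfig(n_genes = 50, seed = 2))
#' vc <- simulateCohort(gu, cohortConfig(n_samples = 20, seed = 3))
#' vc
#' @export
simulateCohort <- function(catalog, cfg) {
  stopifnot(is(catalog, "GeneCatalog"), inherits(cfg, "cohort_config"))
  g <- geneTable(catalog)
  if (nrow(g) == 0L) stop("gene catalog is empty", call. = FALSE)
  withSeed(cfg$seed, {
    n_chrom <- 2L * cfg$n_samples
    classes <- c("synonymous", "missense", "lof")
    per <- expand.grid(gi = seq_len(nrow(g)), vclass = classes,
                       stringsAsFactors = FALSE)
    lam <- cfg$site_rate[per$vclass] * g$exon_length_bp[per$gi] *
      cfg$constraint_multiplier[cbind(per$vclass, g$ess_class[per$gi])]
    per$n <- rpois(nrow(per), lam)
    tot <- sum(per$n)
    if (tot == 0L) {
      emptyVariants <- S4Vectors::DataFrame(chrom = character(0),
        pos = integer(0), ref = character(0), alt = character(0),
        gene_id = character(0), raw_effect = character(0),
        effect_class = character(0), polyphen = character(0),
        sift = character(0), damaging_consensus = logical(0),
        af = numeric(0), rare = logical(0), avgpost = numeric(0))
      gt <- matrix(integer(0), 0, cfg$n_samples,
                   dimnames = list(NULL, sprintf("S%04d",
                                                 seq_len(cfg$n_samples))))
      return(VariantCohort(emptyVariants, gt,
                           truth = list(config = cfg, site_counts = per)))
    }
    gi <- rep(per$gi, per$n)
    vclass <- rep(per$vclass, per$n)
    raw <- character(tot)
    raw[vclass == "synonymous"] <- .effectTokens$synonymous
    nm <- sum(vclass == "missense")
    raw[vclass == "missense"] <- sample(.effectTokens$missense, nm,
                                        replace = TRUE,
                                        prob = c(0.9, 0.05, 0.05))
    nl <- sum(vclass == "lof")
    raw[vclass == "lof"] <- sample(.effectTokens$lof, nl, replace = TRUE)

    is_eg <- g$ess_class[gi] == "EG"
    f <- numeric(tot)
    f[!is_eg] <- drawAlleleFrequencies(sum(!is_eg), n_chrom, cfg$af_alpha)
    f[is_eg] <- drawAlleleFrequencies(sum(is_eg), n_chrom,
                                      cfg$af_alpha + cfg$rare_skew_eg)

    # HWE genotypes at the drawn frequency
    gt <- matrix(rbinom(tot * cfg$n_samples, 2L, rep(f, cfg$n_samples)),
                 nrow = tot, ncol = cfg$n_samples,
                 dimnames = list(NULL, sprintf("S%04d",
                                               seq_len(cfg$n_samples))))

    # predictor calls for (broad) missense sites only; LoF and synonymous
    # sites carry no PolyPhen/SIFT predictions
    is_mis <- vclass == "missense"
    latent <- is_mis & (runif(tot) < cfg$damaging_prob)
    conc <- cfg$damaging_concordance
    pp <- sift <- rep("missing", tot)
    agree1 <- runif(tot) < conc
    agree2 <- runif(tot) < conc
    pp[is_mis] <- ifelse(xor(latent[is_mis], !agree1[is_mis]),
                         "damaging", "benign")
    sift[is_mis] <- ifelse(xor(latent[is_mis], !agree2[is_mis]),
                           "damaging", "tolerated")

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, tot, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    pos <- g$tss[gi] + floor(runif(tot) * g$exon_length_bp[gi])

    variants <- data.frame(
      chrom = g$chrom[gi], pos = as.integer(pos), ref = ref, alt = unname(alt),
      gene_id = g$gene_id[gi], raw_effect = raw,
      effect_class = classifyEffect(raw),
      polyphen = pp, sift = sift,
      damaging_consensus = consensusDamaging(pp, sift),
      af = NA_real_, rare = NA,
      avgpost = round(1 - rbeta(tot, 1, 30) * 0.3, 4),
      stringsAsFactors = FALSE)

    ord <- order(variants$chrom, variants$pos)
    variants <- variants[ord, , drop = FALSE]
    gt <- gt[ord, , drop = FALSE]
    variants$af <- as.numeric(rowSums(gt) / (2 * rowSums(!is.na(gt))))
    variants$rare <- isRare(variants$af)
    rownames(variants) <- NULL
    VariantCohort(variants, gt,
                  truth = list(config = cfg,
                               site_counts = per,
                               af_truth_mean_eg = mean(f[is_eg]),
                               af_truth_mean_other = mean(f[!is_eg])))
  })
}

#' Configuration for one synthetic de novo study
#'
#' Event genes are drawn with weight
#' `exon_length * gc_weight * (true_or if gene is EG and arm is case)`,
#' where `gc_weight = max(1 + gamma * (GC - mean GC) / sd GC, 0.1)` models
#' the positive correlation between GC content and de novo event counts.
#'
#' @param study_id study label.
#' @param n_case_events,n_control_events event counts per arm.
#' @param true_or ground-truth enrichment odds for EG in cases (> 0).
#' @param synonymous_fraction proportion of events annotated synonymous.
#' @param gc_gamma GC-weight slope (0 disables the GC effect).
#' @param seed integer RNG seed.
#' @return A validated list of class `denovo_study_config`.
#' @export
denovoStudyConfig <- function(study_id = "study1", n_case_events = 200L,
                              n_control_events = 100L, true_or = 1,
                              synonymous_fraction = 0.25, gc_gamma = 0.2,
                              seed = 1L) {
  stopifnot(true_or > 0, n_case_events >= 0, n_control_events >= 0,
            synonymous_fraction >= 0, synonymous_fraction <= 1)
  structure(list(study_id = study_id,
                 n_case_events = as.integer(n_case_events),
                 n_control_events = as.integer(n_control_events),
                 true_or = true_or,
                 synonymous_fraction = synonymous_fraction,
                 gc_gamma = gc_gamma, seed = as.integer(seed)),
            class = "denovo_study_config")
}

.denovoCodingTypes <- c("missense", "nonsense", "frameshift", "stoploss",
                        "del_aa", "inframe", "splice")

denovoGcWeight <- function(gc, gamma) {
  if (gamma == 0 || sd(gc) == 0) return(rep(1, length(gc)))
  pmax(1 + gamma * (gc - mean(gc)) / sd(gc), 0.1)
}

#' Simulate one de novo mutation study
#'
#' @param catalog a [GeneCatalog-class] with class labels.
#' @param cfg a [denovoStudyConfig()].
#' @return data.frame of events: `study`, `arm`, `gene_id`, `mutation_type`.
#' @export
simulateDenovoStudy <- function(catalog, cfg) {
  stopifnot(is(catalog, "GeneCatalog"), inherits(cfg, "denovo_study_config"))
  g <- geneTable(catalog)
  if (nrow(g) == 0L) stop("gene catalog is empty", call. = FALSE)
  withSeed(cfg$seed, {
    gcw <- denovoGcWeight(g$gc_pct, cfg$gc_gamma)
    base_w <- g$exon_length_bp * gcw
    case_w <- base_w * ifelse(g$ess_class == "EG", cfg$true_or, 1)
    drawArm <- function(n, w, arm) {
      if (n == 0L) {
        return(data.frame(study = character(0), arm = character(0),
                          gene_id = character(0),
                          mutation_type = character(0)))
      }
      idx <- sample.int(nrow(g), n, replace = TRUE, prob = w)
      syn <- runif(n) < cfg$synonymous_fraction
      mt <- ifelse(syn, "synonymous",
                   sample(.denovoCodingTypes, n, replace = TRUE,
                          prob = c(0.55, 0.1, 0.12, 0.02, 0.03, 0.05, 0.13)))
      data.frame(study = cfg$study_id, arm = arm, gene_id = g$gene_id[idx],
                 mutation_type = mt, stringsAsFactors = FALSE)
    }
    rbind(drawArm(cfg$n_case_events, case_w, "case"),
          drawArm(cfg$n_control_events, base_w, "control"))
  })
}

#' Simulate a per-base conservation track around gene TSSs
#'
#' Emulates a PhyloP-style bedGraph: per-base scores in a window around each
#' TSS, normally distributed with a class-dependent mean so essential-gene
#' promoters score higher (`eg_shift`).
#'
#' @param catalog a [GeneCatalog-class].
#' @param window_bp half-window around the TSS (default 100).
#' @param eg_shift additive mean shift for EG promoters.
#' @param seed integer RNG seed.
#' @return A [GenomicRanges::GRanges] with per-base `score`.
#' @export
simulateConservationTrack <- function(catalog, window_bp = 100L,
                                      eg_shift = 0.5, seed = 1L) {
  g <- geneTable(catalog)
  withSeed(seed, {
    w <- 2L * window_bp + 1L
    starts <- rep(g$tss - window_bp, each = w) +
      rep(seq_len(w) - 1L, times = nrow(g))
    mu <- rep(ifelse(g$ess_class == "EG", eg_shift, 0), each = w)
    GenomicRanges::GRanges(
      seqnames = rep(g$chrom, each = w),
      ranges = IRanges::IRanges(start = starts, width = 1L),
      score = rnorm(length(starts), mean = mu, sd = 1))
  })
}

#' Simulate per-gene substitution-rate (dN/dS) tables
#'
#' Log-normal dN/dS per species pair, multiplied by `eg_multiplier` for
#' essential genes (purifying selection lowers dN/dS).
#'
#' @param catalog a [GeneCatalog-class].
#' @param species species-pair labels.
#' @param eg_multiplier multiplicative dN/dS effect for EG (< 1 = stronger
#'   constraint).
#' @param seed integer RNG seed.
#' @return data.frame `gene_id`, `species`, `dn`, `ds`, `dnds`.
#' @export
simulateSubstitutionRates <- function(catalog,
                                      species = c("rhesus", "chimp", "mouse",
                                                  "rat"),
                                      eg_multiplier = 0.6, seed = 1L) {
  g <- geneTable(catalog)
  withSeed(seed, {
    out <- lapply(species, function(sp) {
      ds <- rlnorm(nrow(g), log(0.05), 0.4)
      ratio <- rlnorm(nrow(g), log(0.25), 0.6) *
        ifelse(g$ess_class == "EG", eg_multiplier, 1)
      data.frame(gene_id = g$gene_id, species = sp, dn = ds * ratio, ds = ds,
                 dnds = ratio, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate expression-variability and brain-expression tables
#'
#' Produces a per-gene coefficient-of-variation table (low CV = ubiquitous
#' expression; EG skew towards low CV) and a per-gene brain over-expression
#' p-value table (a configurable fraction of genes at p <= 1e-4).
#'
#' @param catalog a [GeneCatalog-class].
#' @param eg_cv_shift multiplicative CV shift for EG (< 1 = more ubiquitous).
#' @param brain_fraction fraction of genes flagged brain over-expressed.
#' @param seed integer RNG seed.
#' @return list of data.frames `cv` (gene_id, cv) and `brain_p` (gene_id, p).
#' @export
simulateExpressionTables <- function(catalog, eg_cv_shift = 0.7,
                                     brain_fraction = 0.11, seed = 1L) {
  g <- geneTable(catalog)
  withSeed(seed, {
    cv <- rlnorm(nrow(g), log(0.5), 0.5) *
      ifelse(g$ess_class == "EG", eg_cv_shift, 1)
    p <- rbeta(nrow(g), 0.5, 3)
    hit <- runif(nrow(g)) < brain_fraction
    p[hit] <- runif(sum(hit), 0, 1e-4)
    list(cv = data.frame(gene_id = g$gene_id, cv = cv,
                         stringsAsFactors = FALSE),
         brain_p = data.frame(gene_id = g$gene_id, p = p,
                              stringsAsFactors = FALSE))
  })
}

#' Read the shipped lethal phenotype-code list
#'
#' The package ships a configurable stand-in list of 46 lethal phenotype
#' codes (synthetic placeholders shaped like MP ontology terms, spanning
#' prenatal, perinatal and postnatal lethality); replace with your own
#' curated code list via the `path` argument.
#'
#' @param path path to a TSV with columns `code` and `description`.
#' @return data.frame with columns `code`, `description`.
#' @export
readLethalCodes <- function(path = system.file("extdata",
                                               "synthetic_lethal_codes.tsv",
                                               package = "essvar")) {
  codes <- readTsv(path)
  stopifnot(nrow(codes) > 0, "code" %in% names(codes))
  codes
}
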