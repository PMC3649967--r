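test_that("degenerate universe configurations behave as specified", {
  empty <- generateGeneUniverse(universeConfig(n_genes = 0))
  expect_equal(nGenes(empty), 0L)

  all_eg <- generateGeneUniverse(universeConfig(n_genes = 50,
                                                eg_fraction = 1,
                                                nlg_fraction = 0, seed = 4))
  expect_true(all(essClass(all_eg) == "EG"))

  expect_error(universeConfig(eg_fraction = 0.7, nlg_fraction = 0.5),
               "<= 1")
})

test_that("universe respects its length and GC laws", {
  cfg <- universeConfig(n_genes = 20000, length_law = c(7.3, 0.8),
                        eg_length_multiplier = 1.5, seed = 11)
  gu <- generateGeneUniverse(cfg)
  g <- geneTable(gu)
  expect_true(all(g$exon_length_bp >= 100))
  expect_true(all(g$gc_pct >= 20 & g$gc_pct <= 80))

  # Monte-Carlo oracle: resample the same log-normal law independently and
  # measure the spread of the EG/OTHER mean-length ratio
  n_eg <- sum(g$ess_class == "EG"); n_o <- sum(g$ess_class == "OTHER")
  set.seed(99)
  oracle <- replicate(100, {
    mean(pmax(100, round(rlnorm(n_eg, 7.3, 0.8) * 1.5))) /
      mean(pmax(100, round(rlnorm(n_o, 7.3, 0.8))))
  })
  ratio <- mean(g$exon_length_bp[g$ess_class == "EG"]) /
    mean(g$exon_length_bp[g$ess_class == "OTHER"])
  expect_lt(abs(ratio - mean(oracle)), 3 * sd(oracle))

  # bit-reproducible for a fixed seed
  expect_identical(geneTable(generateGeneUniverse(cfg)), g)
})

test_that("cohort site counts follow the Poisson law with class multipliers", {
  # zero multiplier: no missense records in EG genes
  cat2 <- makeCatalog(c(2000, 2000), c(45, 45), c("EG", "OTHER"))
  mult <- defaultConstraintMultiplier()
  mult["missense", "EG"] <- 0
  vc <- simulateCohort(cat2, cohortConfig(n_samples = 10,
                                          site_rate = c(synonymous = 0,
                                                        missense = 5e-3,
                                                        lof = 0),
                                          constraint_multiplier = mult,
                                          seed = 2))
  v <- variantInfo(vc)
  expect_false(any(v$gene_id == "G001"))
  expect_gt(sum(v$gene_id == "G002"), 0)

  # Poisson-mean oracle: 10,000 iid genes, lambda = 1e-3 * 1000 = 1
  big <- makeCatalog(rep(1000, 10000), rep(45, 10000), rep("OTHER", 10000))
  vc2 <- simulateCohort(big, cohortConfig(n_samples = 2,
                                          site_rate = c(synonymous = 0,
                                                        missense = 1e-3,
                                                        lof = 0),
                                          seed = 3))
  counts <- table(factor(variantInfo(vc2)$gene_id, levels = geneIds(big)))
  m <- mean(counts)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(m - 1), 3 * se)

  # determinism
  vc3 <- simulateCohort(big, cohortConfig(n_samples = 2,
                                          site_rate = c(synonymous = 0,
                                                        missense = 1e-3,
                                                        lof = 0),
                                          seed = 3))
  expect_identical(variantInfo(vc2), variantInfo(vc3))
  expect_identical(genotypeMatrix(vc2), genotypeMatrix(vc3))
})

test_that("allele-frequency law is rare-skewed and monotone for alpha >= 1", {
  draws <- essvar:::drawAlleleFrequencies(2e4, 200L, alpha = 1)
  bins <- cut(draws, breaks = seq(0, 0.5, by = 0.1), include.lowest = TRUE)
  counts <- as.integer(table(bins))
  expect_true(all(diff(counts) <= 0))
  expect_true(all(draws > 0 & draws <= 0.5))

  # higher alpha shifts mass towards rare frequencies
  skewed <- essvar:::drawAlleleFrequencies(2e4, 200L, alpha = 1.5)
  expect_lt(mean(skewed), mean(draws))
})

test_that("genotypes are Hardy-Weinberg at the drawn frequency", {
  cat1 <- makeCatalog(rep(3000, 100), rep(45, 100), rep("OTHER", 100))
  vc <- simulateCohort(cat1, cohortConfig(n_samples = 300,
                                          site_rate = c(synonymous = 2e-3,
                                                        missense = 2e-3,
                                                        lof = 0),
                                          af_alpha = 0.3, seed = 8))
  gt <- genotypeMatrix(vc)
  af <- variantInfo(vc)$af
  informative <- which(af > 0.05 & af < 0.45)
  pvals <- vapply(informative, function(i) {
    x <- gt[i, ]
    p <- mean(x) / 2
    exp_counts <- length(x) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(x + 1L, 3L)
    stat <- sum((obs - exp_counts)^2 / exp_counts)
    pchisq(stat, df = 1, lower.tail = FALSE)  # af estimated from the data
  }, numeric(1))
  expect_gte(mean(pvals > 0.001), 0.95)
})

test_that("de novo event sampling follows the closed-form gene weights", {
  uni <- homogeneousUniverse(n = 100, eg_share = 0.5)

  # neutral weights: P(event in EG) equals the EG length share
  ev <- simulateDenovoStudy(uni, denovoStudyConfig(n_case_events = 4000,
                                                   n_control_events = 0,
                                                   true_or = 1, gc_gamma = 0,
                                                   seed = 5))
  frac <- mean(ev$gene_id %in% geneSet(uni, "EG"))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4000))

  # true_or = 2 with length share 0.5: P = 2 * 0.5 / (2 * 0.5 + 0.5) = 2/3
  ev2 <- simulateDenovoStudy(uni, denovoStudyConfig(n_case_events = 4000,
                                                    n_control_events = 0,
                                                    true_or = 2, gc_gamma = 0,
                                                    seed = 6))
  frac2 <- mean(ev2$gene_id %in% geneSet(uni, "EG"))
  expect_lt(abs(frac2 - 2 / 3), 3 * sqrt(2 / 9 / 4000))

  # empty case arm
  ev3 <- simulateDenovoStudy(uni, denovoStudyConfig(n_case_events = 0,
                                                    n_control_events = 10,
                                                    seed = 7))
  expect_equal(sum(ev3$arm == "case"), 0L)
  expect_equal(sum(ev3$arm == "control"), 10L)

  expect_error(simulateDenovoStudy(
    generateGeneUniverse(universeConfig(n_genes = 0)),
    denovoStudyConfig()), "empty")
})

test_that("case and control arms are exchangeable under the null", {
  uni <- homogeneousUniverse(n = 100, eg_share = 0.5)
  eg <- geneSet(uni, "EG")
  case_hits <- control_hits <- 0L
  n_case <- n_control <- 0L
  for (s in 1:20) {
    ev <- simulateDenovoStudy(uni, denovoStudyConfig(n_case_events = 100,
                                                     n_control_events = 100,
                                                     true_or = 1, seed = s))
    case_hits <- case_hits + sum(ev$arm == "case" & ev$gene_id %in% eg)
    control_hits <- control_hits + sum(ev$arm == "control" &
                                         ev$gene_id %in% eg)
    n_case <- n_case + sum(ev$arm == "case")
    n_control <- n_control + sum(ev$arm == "control")
  }
  pt <- prop.test(c(case_hits, control_hits), c(n_case, n_control))
  expect_gt(pt$p.value, 0.01)
})
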