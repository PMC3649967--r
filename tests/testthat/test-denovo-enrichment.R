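test_that("event filtering applies coding>synonymous and universe rules", {
  uni <- makeCatalog(rep(1000, 3), rep(45, 3), c("EG", "NLG", "OTHER"))
  ev <- data.frame(
    study = "s1", arm = "case",
    gene_id = c("G001", "G002", "G003", "NOT_IN_UNIVERSE"),
    mutation_type = c("missense,synonymous", "synonymous", "nonsense",
                      "missense"),
    stringsAsFactors = FALSE)

  kept <- filterEvents(ev, uni, include_synonymous = FALSE)
  expect_equal(kept$gene_id, c("G001", "G003"))
  expect_equal(kept$mutation_type[1], "missense")  # most damaging wins

  with_syn <- filterEvents(ev, uni, include_synonymous = TRUE)
  expect_equal(nrow(with_syn), 3L)
  expect_true("synonymous" %in% with_syn$mutation_type)

  expect_error(filterEvents(transform(ev, mutation_type = "weird_type"),
                            uni), "weird_type")
})

test_that("match pools respect both tolerances and include the target", {
  uni <- makeCatalog(c(1000, 1050, 1200, 1000), c(40, 41, 40, 45),
                     rep("OTHER", 4))
  pool <- buildMatchPool("G001", uni)
  expect_setequal(pool, c("G001", "G002"))   # G003 fails length, G004 GC

  expect_setequal(buildMatchPool("G001", uni, len_tol_bp = Inf,
                                 gc_tol_pct = Inf), geneIds(uni))

  lone <- makeCatalog(c(1000, 5000), c(40, 70), rep("OTHER", 2))
  expect_equal(buildMatchPool("G001", lone), "G001")
})

test_that("identity permutation is exactly null", {
  # every gene's only match is itself
  uni <- makeCatalog(c(1000, 2000, 4000, 8000), c(25, 35, 45, 55),
                     c("EG", "EG", "OTHER", "OTHER"))
  ev <- data.frame(study = "s", arm = "case",
                   gene_id = c("G001", "G003", "G004"),
                   mutation_type = "missense")
  r <- permuteStudy(ev, uni, "EG", n_perm = 50, seed = 1,
                    unmatched = "self")
  expect_equal(expInSet(r), obsInSet(r))
  expect_equal(adjustedOR(r), 1)
  expect_equal(permP(r), 1)
  expect_equal(r@seLogOR, 0)

  # default policy: unexchangeable events are dropped instead
  expect_error(permuteStudy(ev, uni, "EG", n_perm = 50, seed = 1),
               "unmatchable")
})

test_that("permutation expectation matches exact pool enumeration", {
  # 6-gene enumerable universe: exchange pools (excluding the event gene
  # itself) computed by hand from the +/-100 bp and +/-2.5% GC tolerances:
  #   G001 (1000, 40) -> {G002, G003}      EG fraction 1/2
  #   G003 (1080, 42) -> {G001, G002, G004} EG fraction 1/3
  #   G006 (5000, 60) -> {G006} (self-swap) EG fraction 0
  uni <- makeCatalog(
    lengths = c(1000, 1050, 1080, 1000, 2000, 5000),
    gcs     = c(40,   41,   42,   43,   50,   60),
    classes = c("EG", "OTHER", "EG", "OTHER", "EG", "OTHER"))
  ev <- data.frame(study = "s", arm = "case",
                   gene_id = c("G001", "G003", "G006"),
                   mutation_type = "missense")
  exact <- 1 / 2 + 1 / 3 + 0
  n_perm <- 20000L
  r <- permuteStudy(ev, uni, "EG", n_perm = n_perm, seed = 3,
                    check_pools = TRUE)
  expect_equal(r@expExact, exact, tolerance = 1e-12)
  mc_se <- sqrt(0.25 + 2 / 9) / sqrt(n_perm)
  expect_lt(abs(expInSet(r) - exact), 3 * mc_se)

  # per-gene swap mode agrees in expectation here (all genes distinct)
  r2 <- permuteStudy(ev, uni, "EG", n_perm = n_perm, seed = 4,
                     per_gene = TRUE)
  expect_equal(r2@expExact, exact, tolerance = 1e-12)
  expect_lt(abs(expInSet(r2) - exact), 3 * mc_se)
})

test_that("permutation p is add-one and monotone in the observed count", {
  counts <- c(0L, 1L, 1L, 2L, 3L, 5L)
  p <- vapply(0:6, function(obs) {
    essvar:::permPValueFromCounts(counts, obs)
  }, numeric(1))
  expect_equal(p[1], 1)                      # obs = 0: all counts >= 0
  expect_equal(p[7], 1 / 7)                  # obs above all counts
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0))
})

test_that("fixed-effects meta-analysis reproduces the closed form", {
  m <- metaFixedEffects(data.frame(log_adj_or = c(0.2, 0.4),
                                   se_log_or = c(0.1, 0.2)))
  expect_equal(log(combinedOR(m)), 0.24, tolerance = 1e-12)
  expect_equal(log(ci95(m)[2] / combinedOR(m)) / 1.96, 0.0894427,
               tolerance = 1e-6)
  expect_equal(cochranQ(m), 0.8, tolerance = 1e-12)
  expect_equal(m@qP, 0.3711, tolerance = 1e-4)

  # two identical studies: no heterogeneity
  m2 <- metaFixedEffects(data.frame(log_adj_or = c(0.3, 0.3),
                                    se_log_or = c(0.1, 0.1)))
  expect_equal(cochranQ(m2), 0)

  # one study: combined equals the study, df-0 policy
  m1 <- metaFixedEffects(data.frame(log_adj_or = 0.5, se_log_or = 0.2))
  expect_equal(log(combinedOR(m1)), 0.5)
  expect_equal(m1@qP, 1)
  expect_equal(m1@qDf, 0L)

  # order invariance and equal-SE reduction to the unweighted mean
  th <- c(0.1, 0.5, -0.2); se <- c(0.1, 0.3, 0.2)
  ma <- metaFixedEffects(data.frame(log_adj_or = th, se_log_or = se))
  mb <- metaFixedEffects(data.frame(log_adj_or = rev(th),
                                    se_log_or = rev(se)))
  expect_equal(combinedOR(ma), combinedOR(mb))
  meq <- metaFixedEffects(data.frame(log_adj_or = th,
                                     se_log_or = rep(0.2, 3)))
  expect_equal(log(combinedOR(meq)), mean(th))
  # combined estimate lies within the study range (validity-enforced)
  expect_true(log(combinedOR(ma)) >= min(th) && log(combinedOR(ma)) <= max(th))
})

test_that("meta-analysis agrees with an independent implementation", {
  skip_if_not_installed("metafor")
  set.seed(17)
  th <- rnorm(4, 0.3, 0.2); se <- runif(4, 0.05, 0.3)
  m <- metaFixedEffects(data.frame(log_adj_or = th, se_log_or = se))
  rma <- metafor::rma(yi = th, sei = se, method = "FE")
  expect_equal(log(combinedOR(m)), as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(pValue(m), rma$pval, tolerance = 1e-10)
  expect_equal(cochranQ(m), rma$QE, tolerance = 1e-10)
  expect_equal(m@qP, rma$QEp, tolerance = 1e-10)
})

test_that("permutation respects matching tolerances on every replicate", {
  gu <- generateGeneUniverse(universeConfig(n_genes = 300, seed = 51))
  ev <- simulateDenovoStudy(gu, denovoStudyConfig(n_case_events = 40,
                                                  n_control_events = 0,
                                                  seed = 52))
  # check_pools asserts |dL| <= 100 and |dGC| <= 2.5 for every drawn gene
  expect_no_error(permuteStudy(ev, gu, "EG", n_perm = 50, seed = 53,
                               check_pools = TRUE))
})

test_that("end-to-end analysis separates enriched cases from null controls", {
  uni <- homogeneousUniverse(n = 200, eg_share = 0.5)
  wins <- 0L
  for (s in 1:3) {
    ev <- do.call(rbind, lapply(1:2, function(i) {
      simulateDenovoStudy(uni, denovoStudyConfig(
        study_id = sprintf("study%d", i), n_case_events = 200,
        n_control_events = 200, true_or = 2, synonymous_fraction = 0.2,
        seed = 100 * s + i))
    }))
    res <- runDenovoAnalysis(ev, uni, gene_set = "EG", n_perm = 300,
                             seed = s)
    wins <- wins + (combinedOR(res$case$meta) > combinedOR(res$control$meta))
  }
  expect_gte(wins, 2L)  # majority of replicates

  # determinism of the full analysis for a fixed seed
  ev <- simulateDenovoStudy(uni, denovoStudyConfig(n_case_events = 100,
                                                   n_control_events = 50,
                                                   true_or = 1.5, seed = 9))
  r1 <- runDenovoAnalysis(ev, uni, n_perm = 200, seed = 5)
  r2 <- runDenovoAnalysis(ev, uni, n_perm = 200, seed = 5)
  expect_equal(combinedOR(r1$case$meta), combinedOR(r2$case$meta))
  expect_equal(r1$case$studies[[1]]@expInSet, r2$case$studies[[1]]@expInSet)
})
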