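test_that("length-corrected rates and Z-scores follow the stated arithmetic", {
  cat2 <- makeCatalog(c(100, 100), c(45, 45), c("EG", "NLG"))
  v <- data.frame(
    chrom = "1", pos = c(1, 2, 3), ref = "A", alt = "T",
    gene_id = c("G001", "G001", "G002"),
    raw_effect = c("NON_SYNONYMOUS_CODING", "NON_SYNONYMOUS_CODING",
                   "SYNONYMOUS_CODING"),
    polyphen = "missing", sift = "missing", stringsAsFactors = FALSE)
  gt <- matrix(1L, 3, 2, dimnames = list(NULL, c("S1", "S2")))
  vc <- makeCohort(v, gt)

  r <- lengthCorrectedRate(vc, cat2, "missense_broad")
  expect_equal(r$count, c(2L, 0L))
  expect_equal(r$rate, c(0.02, 0))
  expect_equal(r$z, c(0.7071, -0.7071), tolerance = 1e-4)
  # Z-scores over the universe have mean 0, sd 1 by construction
  expect_equal(mean(r$z), 0, tolerance = 1e-12)
  expect_equal(sd(r$z), 1, tolerance = 1e-12)
  # log1p transform: count 0 maps to 0 before Z-normalization
  expect_equal(r$log1p_count, c(log(3), 0))
})

test_that("Wilcoxon comparisons match exact enumeration and degenerate rules", {
  # enumeration: all C(6,3) = 20 rank splits, only one as extreme -> 0.05
  expect_equal(pValue(wilcoxonCompare(1:3, 4:6, alternative = "less")), 0.05)
  expect_equal(pValue(wilcoxonCompare(4:6, 1:3, alternative = "greater")),
               0.05)
  # identical multisets carry no evidence
  expect_gte(pValue(wilcoxonCompare(c(1, 2, 3), c(1, 2, 3))), 0.99)
  expect_equal(pValue(wilcoxonCompare(rep(1, 5), rep(1, 5))), 1)
  # paired degenerate and error cases
  expect_equal(pValue(wilcoxonCompare(1:4, 1:4, paired = TRUE)), 1)
  expect_error(wilcoxonCompare(1:3, 1:4, paired = TRUE), "equal lengths")
  # paired test detects a constant within-sample shift
  set.seed(9)
  a <- rnorm(30)
  expect_lt(pValue(wilcoxonCompare(a, a + 1, alternative = "less",
                                   paired = TRUE)), 1e-4)
})

test_that("Fisher 2x2 reproduces the printed brain-overexpression panel", {
  res <- fisher2x2(rbind(c(399, 2073), c(588, 3223)))
  expect_equal(round(oddsRatio(res), 2), 1.05)
  expect_equal(round(ci95(res), 2), c(0.92, 1.21))
  expect_equal(pValue(res), 0.46, tolerance = 0.01)
})

test_that("Fisher exact p matches full hypergeometric enumeration", {
  # worked small table: sample OR and enumeration p
  res <- fisher2x2(rbind(c(3, 7), c(6, 4)), or_method = "sample")
  expect_equal(oddsRatio(res), 3 * 4 / (7 * 6), tolerance = 1e-12)
  expect_equal(pValue(res), fisherEnumOracle(3, 7, 6, 4), tolerance = 1e-12)

  # exhaustive: every table with total n <= 16
  for (n in 2:16) {
    for (a in 0:n) for (b in 0:(n - a)) for (c_ in 0:(n - a - b)) {
      d <- n - a - b - c_
      expect_equal(pValue(fisher2x2(rbind(c(a, b), c(c_, d)))),
                   fisherEnumOracle(a, b, c_, d), tolerance = 1e-12)
    }
  }
  # random larger tables up to n = 60, cross-checked against fisher.test
  set.seed(5)
  for (i in 1:200) {
    n <- sample(17:60, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    tab <- rbind(c(cuts[1], cuts[2] - cuts[1]),
                 c(cuts[3] - cuts[2], n - cuts[3]))
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) next
    expect_equal(pValue(fisher2x2(tab)),
                 fisherEnumOracle(tab[1, 1], tab[1, 2], tab[2, 1],
                                  tab[2, 2]),
                 tolerance = 1e-12)
    expect_equal(pValue(fisher2x2(tab)), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
    if (all(tab > 0)) {
      # sample cross-product and conditional estimates stay close away
      # from zero cells
      expect_equal(log(oddsRatio(fisher2x2(tab, or_method = "sample"))),
                   log(oddsRatio(fisher2x2(tab))), tolerance = 0.5)
    }
  }
})

test_that("odds-ratio symmetries hold and symmetric tables are null", {
  sym <- fisher2x2(rbind(c(5, 5), c(5, 5)))
  expect_equal(oddsRatio(sym), 1, tolerance = 1e-6)
  expect_equal(pValue(sym), 1)

  tab <- rbind(c(8, 3), c(4, 9))
  or <- oddsRatio(fisher2x2(tab, or_method = "sample"))
  # swapping both rows and both columns leaves OR invariant
  expect_equal(oddsRatio(fisher2x2(tab[2:1, 2:1], or_method = "sample")), or)
  # swapping rows (or columns) alone inverts it
  expect_equal(oddsRatio(fisher2x2(tab[2:1, ], or_method = "sample")), 1 / or)
  expect_equal(oddsRatio(fisher2x2(tab[, 2:1], or_method = "sample")), 1 / or)

  # zero cell: continuity-corrected OR, flagged
  zc <- fisher2x2(rbind(c(0, 10), c(5, 5)))
  expect_match(zc@note, "continuity")
  expect_equal(oddsRatio(zc), (0.5 * 5.5) / (10.5 * 5.5))
})

test_that("SFS relative excess measures the rare-variant shift", {
  # identity: no excess anywhere
  ident <- sfsRelativeExcess(c(0.001, 0.02, 0.3), c(0.001, 0.02, 0.3))
  expect_equal(ident$table$excess, rep(0, nrow(ident$table)))

  # worked example with two bins: (+0.5, -0.5)
  ex <- sfsRelativeExcess(rep(0.001, 10), c(rep(0.001, 5), rep(0.5, 5)),
                          bins = c(0, 0.01, 0.5))
  expect_equal(ex$table$excess, c(0.5, -0.5))

  # excess sums to zero over bins (random spectra)
  set.seed(7)
  for (i in 1:5) {
    s <- runif(50, 0, 0.5); a <- runif(200, 0, 0.5)
    expect_equal(sum(sfsRelativeExcess(s, a)$table$excess), 0,
                 tolerance = 1e-12)
  }

  # singleton-frequency set vs uniform comparator: lowest bin positive,
  # and the one-sided test calls the set rarer
  sing <- sfsRelativeExcess(rep(0.0005, 40), seq(0.001, 0.5, length = 200))
  expect_gt(sing$table$excess[1], 0)
  expect_lt(pValue(sing$test), 0.001)
  expect_error(sfsRelativeExcess(numeric(0), c(0.1)), "empty")
})

test_that("promoter window means are strand-symmetric per-base averages", {
  cat1 <- GeneCatalog(data.frame(
    gene_id = c("P1", "P2"), symbol = c("P1", "P2"), chrom = "1",
    tss = c(101L, 101L), strand = c("+", "-"), exon_length_bp = 1000,
    gc_pct = 45, ess_class = "OTHER"))
  # track covering positions 1..201 with score = position
  track <- GenomicRanges::GRanges("1", IRanges::IRanges(1:201, width = 1),
                                  score = 1:201)
  m <- promoterMeanScore(track, cat1, window_bp = 100L)
  expect_equal(m$mean_score, c(101, 101))  # mean of 1..201; strands agree

  const <- GenomicRanges::GRanges("1", IRanges::IRanges(1, 500), score = 1)
  expect_equal(promoterMeanScore(const, cat1)$mean_score, c(1, 1))

  # gene with no covered bases -> NA
  far <- GeneCatalog(data.frame(
    gene_id = "P3", symbol = "P3", chrom = "1", tss = 10000L, strand = "+",
    exon_length_bp = 1000, gc_pct = 45, ess_class = "OTHER"))
  expect_true(is.na(promoterMeanScore(track, far)$mean_score))
})

test_that("gene-set metric comparison detects constructed constraint", {
  # constant metric: no evidence
  cat4 <- makeCatalog(rep(1000, 40), rep(45, 40), rep(c("EG", "NLG"), 20))
  met <- data.frame(gene_id = geneIds(cat4), value = 1)
  expect_gte(pValue(compareGeneSets(met, cat4)$test), 0.99)

  # setA = setB: no evidence
  met2 <- data.frame(gene_id = geneIds(cat4), value = rnorm(40))
  expect_gte(pValue(compareGeneSets(met2, cat4, "EG", "EG")$test), 0.99)

  # simulation oracle: EG dN/dS scaled by 0.5 -> one-sided p < 0.05 in
  # at least 19 of 20 replicates at n = 200 genes per set
  cat400 <- makeCatalog(rep(1000, 400), rep(45, 400),
                        rep(c("EG", "NLG"), each = 200))
  hits <- 0L
  set.seed(13)
  for (i in 1:20) {
    val <- rlnorm(400, log(0.25), 0.6) *
      ifelse(geneTable(cat400)$ess_class == "EG", 0.5, 1)
    met3 <- data.frame(gene_id = geneIds(cat400), value = val)
    p <- pValue(compareGeneSets(met3, cat400, "EG", "NLG",
                                alternative = "less")$test)
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 19L)
})
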