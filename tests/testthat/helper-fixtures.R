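# Fixtures built in code: tiny catalogs, hand cohorts, and the 20-gene
# classification fixture with hand-assigned expected labels.

options(essvar.quiet = TRUE)

# catalog where every gene has the given (length, gc); class labels supplied
makeCatalog <- function(lengths, gcs, classes,
                        ids = sprintf("G%03d", seq_along(lengths)),
                        chrom = "1") {
  GeneCatalog(data.frame(
    gene_id = ids, symbol = toupper(ids), chrom = chrom,
    tss = seq_along(lengths) * 10000L, strand = "+",
    exon_length_bp = lengths, gc_pct = gcs, ess_class = classes,
    stringsAsFactors = FALSE))
}

# homogeneous universe: all genes identical length/GC, eg_share EG
homogeneousUniverse <- function(n = 100L, eg_share = 0.5, length_bp = 1000,
                                gc = 45) {
  n_eg <- round(n * eg_share)
  makeCatalog(rep(length_bp, n), rep(gc, n),
              rep(c("EG", "OTHER"), c(n_eg, n - n_eg)))
}

# hand cohort: explicit variants + genotypes over a supplied catalog
makeCohort <- function(variants, genotypes) {
  variants$effect_class <- classifyEffect(variants$raw_effect)
  variants$damaging_consensus <- consensusDamaging(variants$polyphen,
                                                   variants$sift)
  called <- rowSums(!is.na(genotypes))
  variants$af <- as.numeric(rowSums(genotypes, na.rm = TRUE) / (2 * called))
  variants$rare <- isRare(variants$af)
  if (is.null(variants$avgpost)) variants$avgpost <- 0.99
  VariantCohort(variants, genotypes)
}

# 20-gene classification fixture (phenotypes + orthologs + expected labels):
# exercises lethal-wins, heterozygote-disregard and the ortholog filters
classificationFixture <- function() {
  ids <- sprintf("H%02d", 1:20)
  universe <- makeCatalog(rep(1000, 20), rep(45, 20), rep("OTHER", 20),
                          ids = ids)
  lethal <- c("MP:LETH1", "MP:LETH2")
  nonlethal <- c("MP:NL1", "MP:NL2")
  orth <- data.frame(mouse_gene = paste0("Mm", ids), human_gene = ids,
                     stringsAsFactors = FALSE)
  # H03: mouse gene maps to two human genes -> both rows dropped
  orth <- rbind(orth, data.frame(mouse_gene = "MmH03", human_gene = "H20x"))
  # H04 has phenotype but no ortholog row at all
  orth <- orth[orth$human_gene != "H04", ]

  ph <- rbind(
    data.frame(mouse_gene = "MmH01", phenotype_code = lethal[1],
               zygosity = "hom"),                        # plain lethal -> EG
    data.frame(mouse_gene = "MmH02", phenotype_code = c(lethal[2],
               nonlethal[1]), zygosity = "hom"),         # lethal wins -> EG
    data.frame(mouse_gene = "MmH03", phenotype_code = lethal[1],
               zygosity = "hom"),                        # 1:2 map -> dropped
    data.frame(mouse_gene = "MmH04", phenotype_code = lethal[1],
               zygosity = "hom"),                        # no ortholog
    data.frame(mouse_gene = "MmH05", phenotype_code = lethal[1],
               zygosity = "het"),                        # het-only lethal
    data.frame(mouse_gene = "MmH06", phenotype_code = c(lethal[1],
               nonlethal[1]), zygosity = c("het", "hom")), # het lethal + hom NL -> NLG
    data.frame(mouse_gene = "MmH07", phenotype_code = nonlethal[1],
               zygosity = "hom"),                        # plain non-lethal -> NLG
    data.frame(mouse_gene = "MmH08", phenotype_code = c(nonlethal[1],
               nonlethal[2]), zygosity = "hom"),         # two NL rows -> NLG
    data.frame(mouse_gene = "MmH09", phenotype_code = c(lethal[1],
               lethal[2]), zygosity = "hom"),            # two lethal -> EG
    data.frame(mouse_gene = "MmH10", phenotype_code = nonlethal[2],
               zygosity = "het")                         # het-only NL -> OTHER
  )
  expected <- setNames(rep("OTHER", 20), ids)
  expected[c("H01", "H02", "H09")] <- "EG"
  expected[c("H06", "H07", "H08")] <- "NLG"
  list(universe = universe, phenotypes = ph, orthologs = orth,
       lethal = lethal, expected = expected)
}

# independent full-enumeration Fisher oracle (factorial form, two-sided)
fisherEnumOracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  pr <- exp(logp)
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
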