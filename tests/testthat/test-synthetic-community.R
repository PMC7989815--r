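# Mock-community generator: design contracts, exact bookkeeping, determinism.

test_that("family fractions are normalized and reflect depth multipliers", {
  d <- communityDesign(seed = 1L, replicateSdLog = 0)
  for (s in designSamples(d)) {
    expect_equal(sum(familyFractions(d, s)), 1, tolerance = 1e-9)
  }
  # with noise disabled the fractions are exactly baseline * multiplier,
  # renormalized; the deep multiplier of Anaerolineaceae is applied as-is
  fams <- d@families
  raw <- fams$baseline * fams$d20_50
  expect_equal(unname(familyFractions(d, "CT_20-50_P1")),
               unname(raw / sum(raw)))
  # before renormalization the 20-50 cm fraction of a family with a 2x deep
  # multiplier is exactly twice its baseline contribution
  fams$d20_50 <- 1; fams$d20_50[fams$family == "Nitrospiraceae"] <- 2
  d2 <- communityDesign(families = fams, seed = 1L, replicateSdLog = 0)
  f10 <- familyFractions(d2, "CT_0-10_P1")
  f50 <- familyFractions(d2, "CT_20-50_P1")
  # undo the renormalization constants to compare pre-normalization masses
  base <- fams$baseline[fams$family == "Nitrospiraceae"] *
    fams$d0_10[fams$family == "Nitrospiraceae"]
  expect_equal(f50[["Nitrospiraceae"]] * sum(fams$baseline * fams$d20_50),
               2 * fams$baseline[fams$family == "Nitrospiraceae"])
  expect_gt(f50[["Nitrospiraceae"]], f10[["Nitrospiraceae"]])
})

test_that("identical seeds give identical designs, reads and truth", {
  d1 <- communityDesign(nReads = 200L, seed = 42L)
  d2 <- communityDesign(nReads = 200L, seed = 42L)
  expect_identical(d1@families, d2@families)
  s1 <- simulateSample(d1, "RT_10-20_P2")
  s2 <- simulateSample(d2, "RT_10-20_P2")
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(as.character(Biostrings::quality(s1$reads)),
                   as.character(Biostrings::quality(s2$reads)))
  expect_identical(s1$origins, s2$origins)
  d3 <- communityDesign(nReads = 200L, seed = 43L)
  s3 <- simulateSample(d3, "RT_10-20_P2")
  expect_false(identical(as.character(s1$reads), as.character(s3$reads)))
})

test_that("read bookkeeping is exact and planted fractions are recovered", {
  # a gene planted at fraction 0.01 of reads: single family, no background
  fams <- syntheticFamilies()[2, ]  # Chitinophagaceae
  fams$baseline <- 1
  d <- communityDesign(
    families = fams, repertoire = list(Chitinophagaceae = "wza"),
    nReads = 10000L, backgroundFraction = 0,
    mix = c(target = 0.01, decoy = 0, housekeeping = 0.99),
    errorRate = 0, seed = 5L)
  s <- simulateSample(d, "CT_0-10_P1")
  n_wza <- s$geneCounts$count[s$geneCounts$gene == "wza"]
  expect_lt(abs(n_wza - 100), 3 * sqrt(10000 * 0.01 * 0.99))
  # exact bookkeeping: gene counts sum to (1 - background) * n
  d2 <- communityDesign(nReads = 500L, backgroundFraction = 0.3, seed = 6L)
  s2 <- simulateSample(d2, "RT_20-50_P3")
  expect_identical(sum(s2$geneCounts$count), 350L)
  expect_identical(sum(s2$origins$gene == "background"), 150L)
  # background reads never originate from a peptide
  expect_true(all(is.na(
    s2$origins$peptide[s2$origins$gene == "background"])))
  expect_true(all(!is.na(
    s2$origins$peptide[s2$origins$gene != "background"])))
})

test_that("every repertoire gene resolves to a reference peptide", {
  d <- communityDesign(nReads = 50L, seed = 1L)
  w <- syntheticWorld()
  info <- as.data.frame(referenceInfo(w$reference))
  for (fam in names(d@repertoire)) {
    lin <- d@families$lineage[d@families$family == fam]
    have <- info$gene[info$lineage == lin & info$type == "target"]
    expect_true(all(d@repertoire[[fam]] %in% have), label = fam)
  }
  # a repertoire gene with no peptide is a configuration error
  d@repertoire$Solibacteraceae <- c("epsG", "sacB")  # sacB not in that family
  expect_error(simulateSample(d, "CT_0-10_P1"), "configuration error")
})

test_that("repertoires are proper subsets of the target gene set", {
  d <- communityDesign(seed = 1L)
  allGenes <- table1Manifest()$gene
  for (fam in names(d@repertoire)) {
    expect_lt(length(d@repertoire[[fam]]), length(allGenes))
    expect_true(all(d@repertoire[[fam]] %in% allGenes))
  }
  fams <- d@families
  expect_error(communityDesign(
    repertoire = modifyList(syntheticRepertoire(),
                            list(Solibacteraceae = allGenes)),
    seed = 1L), "proper subset")
})

test_that("truth tables round-trip losslessly through TSV", {
  d <- communityDesign(nReads = 120L, seed = 9L)
  sim <- simulateStudy(d)
  path <- tempfile(fileext = ".tsv")
  writeTruthTable(sim$truth, path)
  back <- readTruthTable(path)
  expect_equal(back$origins, sim$truth$origins, ignore_attr = TRUE)
  gc1 <- sim$truth$geneCounts[order(sim$truth$geneCounts$sample,
                                    sim$truth$geneCounts$gene), ]
  gc2 <- back$geneCounts[order(back$geneCounts$sample,
                               back$geneCounts$gene), ]
  expect_equal(gc2$count, gc1$count)
  expect_equal(back$familyFractions[rownames(sim$truth$familyFractions), ],
               sim$truth$familyFractions, tolerance = 1e-12)
  # 18 samples -> 18 summary blocks
  expect_identical(sum(grepl("^##SAMPLE ", readLines(path))), 18L)
  # empty truth -> header-only read section
  empty <- list(origins = sim$truth$origins[0, ],
                geneCounts = sim$truth$geneCounts[0, ],
                familyFractions = sim$truth$familyFractions[0, , drop = FALSE])
  p2 <- tempfile(fileext = ".tsv")
  writeTruthTable(empty, p2)
  back2 <- readTruthTable(p2)
  expect_identical(nrow(back2$origins), 0L)
})
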