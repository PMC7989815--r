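# Translated search, hit ranking, consistency KO calls, concordance,
# rarefaction.

test_that("alignment raw scores match BLOSUM62 sums and the banded DP
           equals the full DP whenever the band covers the matrix", {
  B <- polyglue:::blosum62Matrix()
  r <- polyglue:::cpp_sw_align("WWW", "WWW", B, 11, 1, 0, 50)
  expect_identical(r$score, 33)            # three W:W matches at 11 each
  expect_identical(r$nmatch, 3L)
  set.seed(13)
  for (i in 1:200) {
    q <- randomAA(30); s <- randomAA(30)
    full <- polyglue:::cpp_sw_align(q, s, B, 11, 1, 0, 60)$score
    expect_identical(full, swOracle(q, s))
  }
})

test_that("seeded search finds homologs and honors the E threshold", {
  w <- syntheticWorld()
  info <- as.data.frame(referenceInfo(w$koReference))
  seqs <- as.character(referenceSequences(w$koReference))
  q <- substr(seqs[info$gene == "wza"][1], 30, 120)
  hits <- translatedSearch(q, w$koReference)
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$evalue <= 0.01))
  expect_true(all(hits$gene == "wza"))
  expect_gte(max(hits$pident), 99)
  # empty reference: no hits
  empty <- polyglue:::koReferenceFromInfo(
    Biostrings::AAStringSet(),
    S4Vectors::DataFrame(seq_id = character(0), ko = character(0),
                         gene = character(0), pathway = character(0),
                         lineage = character(0), type = character(0)))
  expect_identical(nrow(translatedSearch(q, empty)), 0L)
})

test_that("hit ranking truncates to 25 with deterministic tie-breaks", {
  set.seed(19)
  hits <- data.frame(
    subject = sprintf("s%02d", 1:30),
    ko = "K01991",
    bitscore = round(stats::runif(30, 40, 120), 3),
    stringsAsFactors = FALSE)
  hits$evalue <- 2^(-hits$bitscore) * 1e6
  ranked <- rankHits(hits)
  expect_identical(nrow(ranked), 25L)
  expect_true(all(diff(ranked$evalue) >= 0))
  # equal E: higher bit score first
  tie <- data.frame(subject = c("b", "a"), ko = "K1",
                    bitscore = c(55, 60), evalue = c(1e-5, 1e-5))
  expect_identical(rankHits(tie)$bitscore, c(60, 55))
  # equal E and bits: lexicographic subject
  tie2 <- data.frame(subject = c("b", "a"), ko = "K1",
                     bitscore = c(60, 60), evalue = c(1e-5, 1e-5))
  expect_identical(rankHits(tie2)$subject, c("a", "b"))
  # fewer than 25: all retained
  expect_identical(nrow(rankHits(hits[1:3, ])), 3L)
})

test_that("KO assignment requires consistency of the considered hits", {
  mk <- function(kos) data.frame(
    subject = sprintf("s%02d", seq_along(kos)), ko = kos,
    bitscore = 100 - seq_along(kos), evalue = 1e-20 * seq_along(kos),
    stringsAsFactors = FALSE)
  r <- assignKO(rankHits(mk(rep("K01991", 25))))
  expect_identical(r$status, "assigned")
  expect_identical(r$ko, "K01991")
  expect_identical(r$n_hits_considered, 25L)
  # one discordant hit among 25 blocks the call under strict reading
  r2 <- assignKO(rankHits(mk(c(rep("K01991", 24), "K16081"))))
  expect_identical(r2$status, "unassigned")
  # three consistent hits are enough
  r3 <- assignKO(rankHits(mk(rep("K11720", 3))))
  expect_identical(r3$status, "assigned")
  expect_identical(r3$ko, "K11720")
  # empty hit list
  r4 <- assignKO(mk(character(0)))
  expect_identical(r4$status, "unassigned")
  expect_identical(r4$n_hits_considered, 0L)
  # majority mode is available but off by default
  r5 <- assignKO(rankHits(mk(c(rep("K01991", 24), "K16081"))),
                 majority = 0.8)
  expect_identical(r5$status, "assigned")
  # a KO never assigned unless present among the hits
  set.seed(29)
  for (i in 1:20) {
    kos <- sample(c("K01991", "K16081", "K11720"), sample(1:25, 1), TRUE)
    r <- assignKO(rankHits(mk(kos)))
    if (r$status == "assigned") expect_true(r$ko %in% kos)
  }
})

test_that("E-values are strictly decreasing in the raw score", {
  raws <- seq(20, 300, by = 7)
  ev <- alignmentEvalue(alignmentBits(raws), m = 100, n = 5e4)
  expect_true(all(diff(ev) < 0))
})

test_that("a read and its reverse complement get identical KO calls", {
  w <- syntheticWorld()
  d <- communityDesign(nReads = 40L, backgroundFraction = 0,
                       errorRate = 0, seed = 77L)
  s <- simulateSample(d, "CT_0-10_P1", w)
  callFor <- function(reads) {
    orfs <- predictOrfs(reads)
    hmmHits <- scanOrfs(orfs, w$hmms)
    orfs <- orfs[orfs$read_id %in% hmmHits$read_id, ]
    if (!nrow(orfs)) return(NULL)
    hits <- translatedSearch(orfs$aa, w$koReference)
    hits$read_id <- orfs$read_id[hits$query]
    callKOs(hits)
  }
  fwd <- Biostrings::DNAStringSet(s$reads)
  rc <- Biostrings::reverseComplement(fwd)
  names(rc) <- names(fwd)
  c1 <- callFor(fwd); c2 <- callFor(rc)
  expect_false(is.null(c1))
  expect_identical(c1[order(c1$read_id), c("read_id", "status", "ko")],
                   c2[order(c2$read_id), c("read_id", "status", "ko")])
})

test_that("noise-free synthetic reads are recovered exactly per gene", {
  w <- syntheticWorld()
  d <- communityDesign(nReads = 600L, errorRate = 0, seed = 101L)
  sim <- simulateStudy(d, w)
  picks <- c("CT_0-10_P1", "RT_20-50_P3")
  res <- runPipeline(sim$reads[picks], d@samples, w)
  truth <- sim$truth$geneCounts
  truth <- truth[truth$sample %in% picks &
                 truth$gene %in% table1Manifest()$gene, ]
  tt <- tapply(truth$count, truth$gene, sum)
  pp <- rowSums(res$geneCounts)
  for (g in names(tt)) expect_identical(as.integer(pp[g]), as.integer(tt[g]),
                                        label = g)
})

test_that("HMM concordance hits its bounds", {
  w <- syntheticWorld()
  info <- as.data.frame(referenceInfo(w$koReference))
  seqs <- as.character(referenceSequences(w$koReference))
  q <- substr(seqs[info$gene == "wza"][1], 35, 130)
  orfs <- data.frame(read_id = "r1", frame = 1L, start = 0L,
                     end = 3L * nchar(q), aa = q, stringsAsFactors = FALSE)
  calls <- data.frame(read_id = "r1", status = "assigned", ko = "K01991",
                      n_hits_considered = 4L, stringsAsFactors = FALSE)
  expect_identical(hmmConcordance(calls, orfs, w$hmms["PF02563"]), 100)
  # an unrelated model never matches
  expect_identical(hmmConcordance(calls, orfs, w$hmms["PF02435"]), 0)
  # no assigned reads: undefined
  none <- calls; none$status <- "unassigned"
  expect_true(is.na(hmmConcordance(none, orfs, w$hmms)))
})

test_that("rarefaction is seeded, capped and plateaus at the true richness", {
  genes <- rep(c("wza", "lptF", "lptG", "wzt", "sacB"), times = 40)
  rc <- rarefactionCurve(genes, c(0, 5, 25, 100, 200), nReps = 20, seed = 4L)
  expect_identical(rc$mean_genes[rc$depth == 0], 0)
  expect_identical(rc$mean_genes[rc$depth == 200], 5)
  expect_true(all(diff(rc$mean_genes) >= 0))
  rc2 <- rarefactionCurve(genes, c(0, 5, 25, 100, 200), nReps = 20, seed = 4L)
  expect_identical(rc, rc2)
  expect_warning(rc3 <- rarefactionCurve(genes, 500, seed = 1L), "capped")
  expect_identical(rc3$depth, 200)
})
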