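# LCA binning: hit filtering, lowest common ancestor, family aggregation.

mkHits <- function(bitscore, evalue = 1e-10, subject = NULL,
                   lineage = "Bacteria;P;C;O;F") {
  n <- length(bitscore)
  data.frame(read_id = "r1",
             subject = if (is.null(subject)) sprintf("s%02d", seq_len(n))
                       else subject,
             bitscore = bitscore,
             evalue = rep_len(evalue, n),
             lineage = rep_len(lineage, n),
             stringsAsFactors = FALSE)
}

test_that("LCA hit filtering applies score, E and top-percent rules", {
  h <- mkHits(c(100, 95, 89, 60))
  f <- filterHitsLCA(h)
  # 10% of the best (100) keeps >= 90 bits only
  expect_identical(f$bitscore, c(100, 95))
  # bitscore below MinScore is removed regardless of E
  h2 <- mkHits(c(49, 52), evalue = 1e-30)
  expect_identical(filterHitsLCA(h2)$bitscore, 52)
  # E above MaxExpected is removed
  h3 <- mkHits(c(80, 82), evalue = c(0.5, 1e-5))
  expect_identical(filterHitsLCA(h3)$bitscore, 82)
  # all hits failing leaves the read unassigned
  expect_identical(nrow(filterHitsLCA(mkHits(30, evalue = 0.5))), 0L)
  # truncation to the 25 lowest-E hits
  h4 <- mkHits(rep(100, 30), evalue = seq(1e-30, 1e-25, length.out = 30))
  expect_identical(nrow(filterHitsLCA(h4)), 25L)
})

test_that("the LCA is the longest common lineage prefix", {
  sameOrder <- c(
    "Bacteria;Bacteroidetes;Sphingobacteriia;Sphingobacteriales;Chitinophagaceae",
    "Bacteria;Bacteroidetes;Sphingobacteriia;Sphingobacteriales;Cytophagaceae")
  l <- lcaLineage(sameOrder)
  expect_identical(l$rank, "order")
  expect_identical(l$lineage,
                   "Bacteria;Bacteroidetes;Sphingobacteriia;Sphingobacteriales")
  # single hit keeps its full lineage
  l2 <- lcaLineage(sameOrder[1])
  expect_identical(l2$rank, "family")
  expect_identical(l2$lineage, sameOrder[1])
  # hits spanning two domains resolve at the root
  l3 <- lcaLineage(c("Bacteria;P;C", "Archaea;Q;D"))
  expect_identical(l3$depth, 0L)
  expect_identical(l3$rank, "root")
  # order-invariant and idempotent under duplication
  set.seed(37)
  lin <- c("Bacteria;A;B;C;D", "Bacteria;A;B;C;E", "Bacteria;A;B;X;Y")
  for (i in 1:10) {
    perm <- sample(lin)
    expect_identical(lcaLineage(perm)$lineage, lcaLineage(lin)$lineage)
    expect_identical(lcaLineage(c(lin, lin))$lineage,
                     lcaLineage(lin)$lineage)
  }
})

test_that("taxonomyCalls matches the per-read filter + LCA composition", {
  hits <- rbind(
    mkHits(c(100, 95, 89), lineage = c("Bacteria;A;B;C;D",
                                       "Bacteria;A;B;C;E",
                                       "Archaea;Z;Z;Z;Z")),
    within(mkHits(c(70, 68), lineage = "Bacteria;A;B;C;D"),
           read_id <- "r2"))
  tc <- taxonomyCalls(hits)
  # r1: the 89-bit hit is dropped by top-percent, LCA of D and E is C
  expect_identical(tc$lineage[tc$read_id == "r1"], "Bacteria;A;B;C")
  expect_identical(tc$rank[tc$read_id == "r1"], "order")
  # r2: both hits agree at family depth
  expect_identical(tc$lineage[tc$read_id == "r2"], "Bacteria;A;B;C;D")
  expect_identical(tc$depth[tc$read_id == "r2"], 5L)
})

test_that("family aggregation projects deep ranks and excludes shallow ones", {
  tc <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    lineage = c("Bacteria;A;B;C;FamX;GenusG",   # genus depth -> FamX
                "Bacteria;A;B;C;FamX",          # family depth -> FamX
                "Bacteria;A",                   # phylum: excluded
                "Bacteria;A;B;C;FamY"),
    depth = c(6L, 5L, 2L, 5L),
    rank = c("rank6", "family", "phylum", "family"),
    n_hits = 1L,
    sample = c("s1", "s1", "s1", "s2"),
    stringsAsFactors = FALSE)
  m <- aggregateFamilies(tc)
  expect_identical(m["FamX", "s1"], 2L)
  expect_identical(m["FamY", "s2"], 1L)
  expect_identical(sum(m), 3L)
  # minSupport zeroes weakly supported cells
  m2 <- aggregateFamilies(tc, minSupport = 2L)
  expect_identical(m2["FamX", "s1"], 2L)
  expect_identical(m2["FamY", "s2"], 0L)
  # column sums never exceed reads assigned at family rank or deeper
  expect_lte(sum(m[, "s1"]), sum(tc$sample == "s1" & tc$depth >= 5L))
})

test_that("the family x gene join books unclassified reads separately", {
  ko <- data.frame(read_id = c("r1", "r2", "r3"),
                   status = c("assigned", "assigned", "unassigned"),
                   ko = c("K01991", "K07091", NA),
                   n_hits_considered = 5L,
                   sample = "s1", stringsAsFactors = FALSE)
  tax <- data.frame(read_id = "r1", lineage = "Bacteria;A;B;C;FamX",
                    depth = 5L, rank = "family", n_hits = 3L,
                    sample = "s1", stringsAsFactors = FALSE)
  fg <- familyGeneTable(ko, tax)
  expect_identical(fg$count[fg$family == "FamX" & fg$gene == "wza"], 1L)
  expect_identical(fg$count[fg$family == "unclassified" &
                            fg$gene == "lptF"], 1L)
  expect_identical(sum(fg$count), 2L)
  # empty KO calls give an empty table
  expect_identical(nrow(familyGeneTable(ko[0, ], tax)), 0L)
})

test_that("coding reads recover their true family at zero error rate", {
  w <- syntheticWorld()
  d <- communityDesign(nReads = 300L, errorRate = 0, seed = 55L)
  s <- simulateSample(d, "RT_0-10_P2", w)
  res <- runPipeline(list("RT_0-10_P2" = s$reads), d@samples, w)
  tc <- res$taxCalls
  truth <- s$origins
  fam <- polyglue:::familyOf(tc$lineage, tc$depth)
  names(fam) <- tc$read_id
  coding <- truth[truth$gene != "background", ]
  called <- fam[coding$read_id]
  called <- called[!is.na(called)]
  expect_gt(length(called), 0.9 * nrow(coding))
  expect_true(all(called == coding$family[match(names(called),
                                                coding$read_id)]))
})
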