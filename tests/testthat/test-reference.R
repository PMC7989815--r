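# Curated manifest, labelled-FASTA indexing and the curation screens.

test_that("the target manifest carries the 14-gene mapping", {
  man <- table1Manifest()
  expect_identical(nrow(man), 14L)
  expect_identical(length(unique(man$ko)), 14L)
  expect_identical(length(unique(man$gene)), 14L)
  expect_identical(length(manifestAccessions()), 16L)
  expect_identical(anyDuplicated(manifestAccessions()), 0L)
  expect_setequal(man$pathway, c("EPS", "LPS"))
  expect_identical(sum(man$pathway == "EPS"), 10L)
  expect_identical(sum(man$pathway == "LPS"), 4L)
  expect_identical(man$ko[man$gene == "wza"], "K01991")
  expect_identical(man$hmm[man$gene == "wza"], "PF02563")
  expect_identical(sort(strsplit(man$hmm[man$gene == "lptG"], ",")[[1]]),
                   c("PF03739", "TIGR04408"))
  expect_identical(sort(strsplit(man$hmm[man$gene == "lptC"], ",")[[1]]),
                   c("PF06835", "TIGR04409"))
})

test_that("the candidate list counts 81 KOs split 67 EPS / 14 LPS", {
  cand <- candidateManifest()
  expect_identical(nrow(cand), 81L)
  expect_identical(sum(cand$pathway == "EPS"), 67L)
  expect_identical(sum(cand$pathway == "LPS"), 14L)
  expect_identical(sum(cand$retained), 14L)
  expect_setequal(cand$ko[cand$retained], table1Manifest()$ko)
})

test_that("labelled FASTA references build, reject and round-trip", {
  w <- syntheticWorld()
  path <- tempfile(fileext = ".fasta")
  writeReference(w$koReference, path)
  ref <- buildReference(path)
  expect_identical(referenceSize(ref), referenceSize(w$koReference))
  kos <- unique(referenceInfo(ref)$ko)
  expect_identical(length(kos[kos != "none"]), 14L)
  # records without ko= or lineage= are rejected with a logged reason
  lines <- readLines(path)
  extra <- c(">orphan some description", "MKKKKKKKKKKW", lines)
  p2 <- tempfile(); writeLines(extra, p2)
  expect_message(ref2 <- buildReference(p2), "rejected 1")
  expect_identical(referenceSize(ref2), referenceSize(ref))
  # duplicated seq_id keeps the first record
  dup <- c(lines, lines[1:2])
  p3 <- tempfile(); writeLines(dup, p3)
  expect_message(ref3 <- buildReference(p3), "duplicated")
  expect_identical(referenceSize(ref3), referenceSize(ref))
  # empty reference warns and yields an empty index
  p4 <- tempfile(); writeLines(character(0), p4)
  expect_warning(ref4 <- buildReference(p4), "empty")
  expect_identical(referenceSize(ref4), 0L)
})

test_that("domain-presence screen retains KOs by passing fraction", {
  w <- syntheticWorld()
  hmm <- w$hmms[["PF02563"]]
  # all true wza members carry the modelled domain
  res <- verifyDomainPresence(w$koReference, "K01991", hmm)
  expect_true(res$retain)
  expect_identical(res$nPass, res$nSeq)
  # a KO set of shuffled members is discarded
  info <- as.data.frame(referenceInfo(w$koReference))
  seqs <- as.character(referenceSequences(w$koReference))
  set.seed(7)
  shuf <- vapply(seqs[info$gene == "wza"], function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1))
  fake <- polyglue:::koReferenceFromInfo(
    Biostrings::AAStringSet(stats::setNames(shuf, paste0("s", seq_along(shuf)))),
    S4Vectors::DataFrame(seq_id = paste0("s", seq_along(shuf)),
                         ko = "K01991", gene = "wza", pathway = "EPS",
                         lineage = "Bacteria", type = "target"))
  expect_false(verifyDomainPresence(fake, "K01991", hmm)$retain)
  # 8 of 10 passing at a 90% threshold is below the bar
  ten <- c(seqs[info$gene == "wza"][1:1], shuf[1])
  mix <- polyglue:::koReferenceFromInfo(
    Biostrings::AAStringSet(stats::setNames(
      c(rep(seqs[info$gene == "wza"][1], 8), shuf[1:2]),
      paste0("m", 1:10))),
    S4Vectors::DataFrame(seq_id = paste0("m", 1:10),
                         ko = "K01991", gene = "wza", pathway = "EPS",
                         lineage = "Bacteria", type = "target"))
  resMix <- verifyDomainPresence(mix, "K01991", hmm, minFraction = 0.9)
  expect_identical(resMix$nPass, 8L)
  expect_false(resMix$retain)
  expect_true(verifyDomainPresence(mix, "K01991", hmm,
                                   minFraction = 0.8)$retain)
})

test_that("the specificity screen samples assigned reads against the oracle", {
  assignments <- data.frame(
    read_id = sprintf("r%02d", 1:40),
    ko = c(rep("K01991", 30), rep("K11720", 10)),
    stringsAsFactors = FALSE)
  oracle <- c(stats::setNames(rep("wza", 30), sprintf("r%02d", 1:30)),
              stats::setNames(c(rep("lptG", 9), "lptG_like"),
                              sprintf("r%02d", 31:40)))
  # 30 on-function reads: pass (25 sampled)
  r1 <- specificityScreen(assignments, oracle, "K01991", seed = 2L)
  expect_identical(r1$verdict, "pass")
  expect_identical(r1$nSampled, 25L)
  # 10 assigned (all sampled), one of decoy origin: fail
  r2 <- specificityScreen(assignments, oracle, "K11720", seed = 2L)
  expect_identical(r2$verdict, "fail")
  expect_identical(r2$nSampled, 10L)
  expect_identical(r2$offending, "r40")
  # seeded sampling is reproducible
  r3 <- specificityScreen(assignments, oracle, "K01991", seed = 2L)
  expect_identical(r1$sampled, r3$sampled)
  # no assigned reads: vacuous pass flagged untested
  r4 <- specificityScreen(assignments, oracle, "K00692", seed = 2L)
  expect_identical(r4$verdict, "untested")
})
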