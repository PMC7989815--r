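# End-to-end orchestration: QC -> ORFs -> profile-HMM filter -> translated
# search -> consistency KO calls -> LCA taxonomy -> community statistics.

#' Default pipeline parameters
#'
#' The stated defaults of every stage: terminal Phred 15, minimum length
#' 50 bp, HMM filter E <= 1e-5, alignment E <= 0.01, top-25 consistency,
#' LCA filters (MinScore 50, MaxExpected 0.01, TopPercent 10, MinSupport 1,
#' MinComplexity 0 as a no-op), dominance thresholds 0.5\% (families) and
#' 0.005\% (genes), and the 2-of-3 core rule.
#'
#' @return named list of parameters.
#' @export
pipelineParams <- function() {
  list(minTerminalQ = 15L, minLen = 50L, minAaLen = 20L,
       hmmEvalue = 1e-5, alignEvalue = 0.01, topN = 25L,
       lcaMinScore = 50, lcaMaxExpected = 0.01, lcaTopPercent = 10,
       lcaMinSupport = 1L, lcaMinComplexity = 0,
       domFamily = 0.5, domGene = 0.005,
       taxMinOrfAa = 25L, taxOrfsPerRead = 2L)
}

# taxonomy-stage ORF subset: the two longest ORFs (>= minAa) per read,
# deterministic under reverse complement (length, then sequence, tie-break)
taxonomyOrfs <- function(orfs, minAa = 25L, perRead = 2L) {
  orfs <- orfs[nchar(orfs$aa) >= minAa, ]
  if (!nrow(orfs)) return(orfs)
  ord <- order(orfs$read_id, -nchar(orfs$aa), orfs$aa)
  orfs <- orfs[ord, ]
  idx <- stats::ave(seq_len(nrow(orfs)), orfs$read_id,
                    FUN = seq_along) <= perRead
  orfs[idx, ]
}

#' Run the annotation pipeline on a set of samples
#'
#' @param reads named list (per sample) of \code{QualityScaledDNAStringSet}.
#' @param meta data.frame(sample, tillage, depth, plot).
#' @param world synthetic world (or a list with elements
#'   \code{koReference}, \code{reference}, \code{hmms}).
#' @param params parameter list (\code{\link{pipelineParams}}).
#' @param contaminants optional contaminant reference for the QC screen.
#' @param verbose log stage progress to stderr.
#' @return list with per-read calls (koCalls, taxCalls), count matrices
#'   (geneCounts, familyCounts), SummarizedExperiments (genes, families),
#'   familyGene table, summary data.frame, and the resolved params.
#' @export
runPipeline <- function(reads, meta, world = syntheticWorld(),
                        params = pipelineParams(), contaminants = NULL,
                        verbose = FALSE) {
  stopifnot(all(names(reads) %in% meta$sample))
  if (!length(world$hmms)) stop("preflight: no profile HMMs supplied")
  if (!referenceSize(world$koReference))
    stop("preflight: empty KO reference")
  log <- function(...) if (verbose) message(sprintf(...))
  koCalls <- taxCalls <- qcRows <- list()
  totalFiltered <- stats::setNames(integer(length(reads)), names(reads))

  for (s in names(reads)) {
    log("[%s] QC", s)
    qc <- runQC(reads[[s]], params$minTerminalQ, params$minLen, contaminants)
    totalFiltered[[s]] <- length(qc$reads)
    qcRows[[s]] <- cbind(sample = s, qc$summary)
    log("[%s] ORF prediction on %d reads", s, length(qc$reads))
    orfs <- predictOrfs(qc$reads, params$minAaLen)
    log("[%s] profile scan of %d ORFs", s, nrow(orfs))
    hmmHits <- scanOrfs(orfs, world$hmms, params$hmmEvalue)
    passing <- unique(hmmHits$read_id)
    log("[%s] %d reads pass the domain filter", s, length(passing))

    # KO annotation: all ORFs of HMM-passing reads vs the KO reference
    koOrfs <- orfs[orfs$read_id %in% passing, ]
    kc <- if (nrow(koOrfs)) {
      hits <- translatedSearch(koOrfs$aa, world$koReference,
                               maxEvalue = params$alignEvalue)
      if (nrow(hits)) {
        hits$read_id <- koOrfs$read_id[hits$query]
        callKOs(hits, params$topN)
      } else NULL
    } else NULL
    if (is.null(kc))
      kc <- data.frame(read_id = character(0), status = character(0),
                       ko = character(0), n_hits_considered = integer(0))
    kc$sample <- if (nrow(kc)) s else character(0)
    koCalls[[s]] <- kc

    # taxonomy: longest ORFs of every filtered read vs the full reference
    tOrfs <- taxonomyOrfs(orfs, params$taxMinOrfAa, params$taxOrfsPerRead)
    log("[%s] taxonomy search on %d ORFs", s, nrow(tOrfs))
    tc <- if (nrow(tOrfs)) {
      hits <- translatedSearch(tOrfs$aa, world$reference,
                               maxEvalue = params$lcaMaxExpected)
      if (nrow(hits)) {
        hits$read_id <- tOrfs$read_id[hits$query]
        info <- world$reference@info
        hits$lineage <- info$lineage[match(hits$subject, info$seq_id)]
        dt <- data.table::as.data.table(hits)
        dt <- dt[order(evalue, -bitscore), .SD[1],
                 by = .(read_id, subject)]
        taxonomyCalls(as.data.frame(dt),
                      minScore = params$lcaMinScore,
                      maxExpected = params$lcaMaxExpected,
                      topPercent = params$lcaTopPercent,
                      topN = params$topN)
      } else NULL
    } else NULL
    if (is.null(tc))
      tc <- data.frame(read_id = character(0), lineage = character(0),
                       depth = integer(0), rank = character(0),
                       n_hits = integer(0))
    tc$sample <- if (nrow(tc)) s else character(0)
    taxCalls[[s]] <- tc
  }

  koCalls <- do.call(rbind, koCalls)
  taxCalls <- do.call(rbind, taxCalls)
  rownames(koCalls) <- rownames(taxCalls) <- NULL

  man <- table1Manifest()
  assigned <- koCalls[koCalls$status == "assigned", ]
  assigned$gene <- man$gene[match(assigned$ko, man$ko)]
  geneCounts <- matrix(0L, nrow(man), length(reads),
                       dimnames = list(man$gene, names(reads)))
  if (nrow(assigned)) {
    tab <- table(assigned$gene, assigned$sample)
    geneCounts[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  familyCounts <- aggregateFamilies(taxCalls, params$lcaMinSupport)

  meta2 <- meta[match(names(reads), meta$sample), ]
  meta2$total_filtered <- unname(totalFiltered[meta2$sample])
  genes <- abundanceTable(geneCounts, meta2)
  families <- if (nrow(familyCounts))
    abundanceTable(familyCounts[, names(reads), drop = FALSE], meta2)
  else NULL

  fg <- familyGeneTable(koCalls, taxCalls)
  summary <- data.frame(
    sample = names(reads),
    total_filtered = unname(totalFiltered),
    reads_family_assigned = if (nrow(familyCounts))
      colSums(familyCounts)[names(reads)] else 0L,
    reads_ko_assigned = vapply(names(reads), function(s)
      sum(assigned$sample == s), integer(1)),
    row.names = NULL
  )
  summary$pct_target_genes <- relativeAbundance(
    summary$reads_ko_assigned, summary$total_filtered)

  list(koCalls = koCalls, taxCalls = taxCalls,
       geneCounts = geneCounts, familyCounts = familyCounts,
       genes = genes, families = families, familyGene = fg,
       qc = do.call(rbind, qcRows), summary = summary,
       params = params)
}

#' Simulate the default study and run the full pipeline
#'
#' Generates the 18-sample synthetic study at the packaged study
#' conditions, runs the pipeline, and derives the headline community
#' tables (dominant families, gene abundances, family x gene matrix, core
#' sets) plus truth-recovery diagnostics.
#'
#' @param seed integer root seed.
#' @param nReads reads per sample (default 10,000).
#' @param outDir optional directory to write TSV outputs into.
#' @param verbose log progress.
#' @param design optional \linkS4class{CommunityDesign} overriding the
#'   default (must still carry the 18-sample layout).
#' @return list(pipeline, truth, design, tables, recovery).
#' @export
runDemo <- function(seed = 1L, nReads = 10000L, outDir = NULL,
                    verbose = FALSE, design = NULL) {
  if (is.null(design))
    design <- communityDesign(nReads = nReads, seed = seed)
  world <- syntheticWorld(design@decoySimilarity)
  sim <- simulateStudy(design, world)
  res <- runPipeline(sim$reads, design@samples, world, verbose = verbose)

  relFam <- if (!is.null(res$families))
    SummarizedExperiment::assay(res$families, "relabund") else NULL
  relGene <- SummarizedExperiment::assay(res$genes, "relabund")
  tables <- list(
    dominantFamilies = if (!is.null(relFam))
      dominantFeatures(relFam, res$params$domFamily) else character(0),
    dominantGenes = dominantFeatures(relGene, res$params$domGene),
    familyGene = res$familyGene,
    core = if (!is.null(res$familyCounts) && nrow(res$familyCounts))
      coreMembership(res$familyCounts, design@samples) else NULL
  )

  # truth recovery: per-gene pipeline counts vs planted counts
  man <- table1Manifest()
  truthGene <- sim$truth$geneCounts
  truthGene <- truthGene[truthGene$gene %in% man$gene, ]
  truthTotals <- tapply(truthGene$count, truthGene$gene, sum)
  pipeTotals <- rowSums(res$geneCounts)
  genes <- man$gene
  tt <- ifelse(is.na(truthTotals[genes]), 0, truthTotals[genes])
  recovery <- list(
    truth = stats::setNames(as.numeric(tt), genes),
    pipeline = pipeTotals[genes],
    spearman = stats::cor(as.numeric(tt), as.numeric(pipeTotals[genes]),
                          method = "spearman")
  )

  out <- list(pipeline = res, truth = sim$truth, design = design,
              tables = tables, recovery = recovery)
  if (!is.null(outDir)) writeDemoOutputs(out, outDir)
  out
}

# TSV outputs for a demo run (deterministic content given the same seed)
writeDemoOutputs <- function(demo, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  res <- demo$pipeline
  wt(res$summary, "summary.tsv")
  wt(res$qc, "qc.tsv")
  wt(res$koCalls, "ko_calls.tsv")
  wt(res$taxCalls, "taxonomy_calls.tsv")
  wt(data.frame(gene = rownames(res$geneCounts), res$geneCounts,
                check.names = FALSE), "gene_counts.tsv")
  if (!is.null(res$familyCounts) && nrow(res$familyCounts))
    wt(data.frame(family = rownames(res$familyCounts), res$familyCounts,
                  check.names = FALSE), "family_counts.tsv")
  wt(res$familyGene, "family_gene.tsv")
  if (!is.null(demo$tables$core)) wt(demo$tables$core, "core_membership.tsv")
  writeTruthTable(demo$truth, file.path(outDir, "truth.tsv"))
  jsonlite::write_json(
    list(seed = demo$design@seed, nReads = demo$design@nReads,
         params = res$params),
    file.path(outDir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
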