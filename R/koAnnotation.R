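# Translated search against the KO reference and the consistency-based KO
# assignment, plus the HMM-concordance check and rarefaction.

#' Raw-to-bit score conversion (Karlin-Altschul)
#'
#' \code{bits = (lambda * raw - ln K) / ln 2} with the configured ungapped
#' BLOSUM62 parameters.
#'
#' @param raw raw alignment score(s).
#' @param lambda,K Karlin-Altschul parameters.
#' @return bit score(s).
#' @export
alignmentBits <- function(raw, lambda = KA_LAMBDA, K = KA_K) {
  (lambda * raw - log(K)) / log(2)
}

#' Alignment E-value for a given search space
#'
#' \code{E = m * n * 2^-bits}; strictly decreasing in the raw score for a
#' fixed search space.
#'
#' @param bits bit score(s).
#' @param m query length (residues).
#' @param n total reference residues.
#' @return E-value(s).
#' @export
alignmentEvalue <- function(bits, m, n) {
  m * n * 2^(-bits)
}

#' Seeded banded translated search against a KO reference
#'
#' Subjects sharing at least \code{minSeeds} exact amino-acid 4-mers with
#' the query are aligned with a banded Smith-Waterman (BLOSUM62, gap open
#' 11, gap extend 1) around the modal seed diagonal; hits with
#' \code{E <= maxEvalue} are returned. The search space is query length
#' times total reference residues.
#'
#' @param queries character vector of peptide queries (typically ORFs).
#' @param ref a \linkS4class{KOReference}.
#' @param band half-width of the alignment band (default 16).
#' @param gapOpen,gapExtend affine gap penalties (a gap of length k costs
#'   open + k * extend).
#' @param minSeeds minimum shared 4-mers to trigger an alignment.
#' @param maxEvalue reporting threshold (default 0.01).
#' @return data.frame(query, subject, ko, gene, raw, bitscore, evalue,
#'   pident, qstart, qend, sstart, send): 0-based half-open ranges.
#' @export
translatedSearch <- function(queries, ref, band = 16L, gapOpen = 11,
                             gapExtend = 1, minSeeds = 2L,
                             maxEvalue = 0.01) {
  empty <- data.frame(query = integer(0), subject = character(0),
                      ko = character(0), gene = character(0),
                      raw = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), pident = numeric(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(queries) || !referenceSize(ref)) return(empty)
  idx <- ref@kmerIndex
  nRes <- sum(Biostrings::width(ref@sequences))
  hits <- cpp_translated_search(queries, as.character(ref@sequences),
                                idx$code, idx$subject, idx$pos,
                                blosum62Matrix(), gapOpen, gapExtend,
                                band, minSeeds, 1)
  if (!nrow(hits)) return(empty)
  bits <- alignmentBits(hits$raw)
  ev <- alignmentEvalue(bits, nchar(queries)[hits$query], nRes)
  keep <- ev <= maxEvalue
  if (!any(keep)) return(empty)
  hits <- hits[keep, ]; bits <- bits[keep]; ev <- ev[keep]
  info <- ref@info
  data.frame(query = hits$query,
             subject = info$seq_id[hits$subject],
             ko = info$ko[hits$subject],
             gene = info$gene[hits$subject],
             raw = hits$raw, bitscore = bits, evalue = ev,
             pident = 100 * hits$nmatch / hits$alnlen,
             qstart = hits$qstart, qend = hits$qend,
             sstart = hits$sstart, send = hits$send,
             stringsAsFactors = FALSE)
}

#' Rank one read's alignment hits
#'
#' Ascending E-value, ties broken by descending bit score then
#' lexicographic subject id, truncated to the top \code{n} (the "top 25
#' blast results").
#'
#' @param hits data.frame of one read's hits (best hit per subject).
#' @param n maximum hits retained (default 25).
#' @return the ranked, truncated data.frame.
#' @export
rankHits <- function(hits, n = 25L) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$evalue, -hits$bitscore, hits$subject)
  utils::head(hits[ord, ], n)
}

#' Consistency-based KO call from ranked hits
#'
#' A KO id is assigned only when every considered hit carries that KO
#' (strict unanimity, the default) or, in the optional majority mode, when
#' at least \code{majority} of the considered hits agree.
#'
#' @param ranked ranked hits from \code{\link{rankHits}}.
#' @param majority unanimity when 1 (default); e.g. 0.8 for a majority rule.
#' @return list(status, ko, n_hits_considered).
#' @export
assignKO <- function(ranked, majority = 1) {
  n <- nrow(ranked)
  if (!n) return(list(status = "unassigned", ko = NA_character_,
                      n_hits_considered = 0L))
  tab <- sort(table(ranked$ko), decreasing = TRUE)
  top <- names(tab)[1]
  ok <- if (majority >= 1) length(tab) == 1L else tab[[1]] / n >= majority
  if (ok) list(status = "assigned", ko = top, n_hits_considered = n)
  else list(status = "unassigned", ko = NA_character_, n_hits_considered = n)
}

#' Call KOs for many reads from their ORF-level hits
#'
#' Per read, only the best-scoring ORF's hits are considered (reads are
#' assigned at read level): the ORF whose best hit has the lowest E-value
#' wins, its per-subject best hits are ranked and the consistency rule is
#' applied.
#'
#' @param hits data.frame from \code{\link{translatedSearch}} with an
#'   additional \code{read_id} column (and \code{query} indexing ORFs).
#' @param topN hits considered per read (default 25).
#' @param majority see \code{\link{assignKO}}.
#' @return data.frame(read_id, status, ko, n_hits_considered).
#' @export
callKOs <- function(hits, topN = 25L, majority = 1) {
  if (!nrow(hits))
    return(data.frame(read_id = character(0), status = character(0),
                      ko = character(0), n_hits_considered = integer(0),
                      stringsAsFactors = FALSE))
  dt <- data.table::as.data.table(hits)
  # best ORF per read: the ORF holding the read's lowest-E hit
  bestOrf <- dt[order(evalue, -bitscore), .(query = query[1]), by = read_id]
  dt <- dt[bestOrf, on = c("read_id", "query")]
  # best hit per subject within the chosen ORF
  dt <- dt[order(evalue, -bitscore), .SD[1], by = .(read_id, subject)]
  calls <- dt[, {
    r <- assignKO(rankHits(.SD, topN), majority)
    list(status = r$status, ko = r$ko,
         n_hits_considered = r$n_hits_considered)
  }, by = read_id]
  as.data.frame(calls)
}

#' HMM concordance of assigned reads
#'
#' Fraction (percent) of KO-assigned reads whose best ORF hits any of the
#' target profile HMMs at \code{E <= threshold}; the sanity check that the
#' alignment-based assignments still look like the modelled domains.
#'
#' @param koCalls data.frame from \code{\link{callKOs}}.
#' @param orfs ORF table for the same reads (\code{\link{predictOrfs}}).
#' @param hmms named list of calibrated models.
#' @param threshold E-value threshold (default 1e-5).
#' @return percent concordance, or NA when no reads are assigned.
#' @export
hmmConcordance <- function(koCalls, orfs, hmms, threshold = 1e-5) {
  assigned <- koCalls$read_id[koCalls$status == "assigned"]
  if (!length(assigned)) return(NA_real_)
  sub <- orfs[orfs$read_id %in% assigned, ]
  hits <- scanOrfs(sub, hmms, threshold)
  100 * length(intersect(assigned, unique(hits$read_id))) / length(assigned)
}

#' Rarefaction of assigned-gene richness
#'
#' Seeded subsampling without replacement of read-level KO calls; the mean
#' and sd of distinct genes recovered at each depth.
#'
#' @param genes character vector: one gene (or KO) label per assigned read.
#' @param depths subsample sizes.
#' @param nReps replicates per depth (default 10).
#' @param seed integer seed.
#' @return data.frame(depth, mean_genes, sd_genes).
#' @export
rarefactionCurve <- function(genes, depths, nReps = 10L, seed = 1L) {
  n <- length(genes)
  over <- depths > n
  if (any(over)) {
    warning("depth(s) exceeding the number of reads capped at ", n)
    depths[over] <- n
  }
  # nested design: each replicate is one permutation read at every depth,
  # so mean richness is monotone non-decreasing in depth by construction
  rich <- withSeed(seed, {
    vapply(seq_len(nReps), function(r) {
      perm <- if (n) sample(genes) else character(0)
      vapply(depths, function(d) {
        if (d == 0) 0L else length(unique(perm[seq_len(d)]))
      }, integer(1))
    }, integer(length(depths)))
  })
  rich <- matrix(rich, nrow = length(depths))
  data.frame(depth = depths,
             mean_genes = rowMeans(rich),
             sd_genes = apply(rich, 1, stats::sd))
}
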