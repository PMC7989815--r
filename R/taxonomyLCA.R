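# Lowest-common-ancestor taxonomic binning of reads from their translated
# alignment hits, with the bit-score / E-value / top-percent filters of the
# metagenome-analyzer convention.

LCA_RANKS <- c("domain", "phylum", "class", "order", "family")

#' Filter one read's hits for taxonomic binning
#'
#' Retains hits with bit score at least \code{minScore} and E-value at most
#' \code{maxExpected}; then hits within \code{topPercent} percent of the
#' best bit score; then the \code{topN} lowest-E hits. \code{minComplexity}
#' is accepted for interface completeness and honored as a no-op.
#'
#' @param hits data.frame with columns bitscore, evalue, subject.
#' @param minScore minimum bit score (default 50).
#' @param maxExpected maximum E-value (default 0.01).
#' @param topPercent keep hits with bitscore >= (1 - topPercent/100) * best
#'   (default 10).
#' @param topN truncation after filtering (default 25).
#' @param minComplexity ignored (no-op, default 0).
#' @return the filtered data.frame (possibly empty).
#' @export
filterHitsLCA <- function(hits, minScore = 50, maxExpected = 0.01,
                          topPercent = 10, topN = 25L, minComplexity = 0) {
  if (!nrow(hits)) return(hits)
  keep <- hits$bitscore >= minScore & hits$evalue <= maxExpected
  hits <- hits[keep, ]
  if (!nrow(hits)) return(hits)
  best <- max(hits$bitscore)
  hits <- hits[hits$bitscore >= (1 - topPercent / 100) * best, ]
  ord <- order(hits$evalue, -hits$bitscore, hits$subject)
  utils::head(hits[ord, ], topN)
}

#' Lowest common ancestor of lineage paths
#'
#' The longest common prefix of the semicolon-separated ranked lineages;
#' order-invariant and idempotent under duplication.
#'
#' @param lineages character vector of lineage strings.
#' @return list(lineage = common-prefix string ("" at root), depth = number
#'   of shared ranks, rank = rank name of the assignment).
#' @export
lcaLineage <- function(lineages) {
  lineages <- lineages[!is.na(lineages)]
  if (!length(lineages)) return(list(lineage = "", depth = 0L,
                                     rank = "root"))
  parts <- strsplit(lineages, ";", fixed = TRUE)
  ref <- parts[[1]]
  depth <- length(ref)
  for (p in parts[-1]) {
    k <- min(depth, length(p))
    same <- which(ref[seq_len(k)] != p[seq_len(k)])
    depth <- if (length(same)) min(same) - 1L else k
    if (depth == 0L) break
  }
  rank <- if (depth == 0L) "root"
          else if (depth <= length(LCA_RANKS)) LCA_RANKS[depth]
          else paste0("rank", depth)
  list(lineage = paste(ref[seq_len(depth)], collapse = ";"),
       depth = depth, rank = rank)
}

#' Per-read LCA taxonomy calls
#'
#' Applies \code{\link{filterHitsLCA}} per read and assigns the lowest
#' common ancestor of the surviving hits' lineages.
#'
#' @param hits data.frame with read_id, bitscore, evalue, subject, lineage.
#' @param ... filter parameters passed to \code{\link{filterHitsLCA}}.
#' @return data.frame(read_id, lineage, depth, rank, n_hits).
#' @export
taxonomyCalls <- function(hits, ...) {
  if (!nrow(hits))
    return(data.frame(read_id = character(0), lineage = character(0),
                      depth = integer(0), rank = character(0),
                      n_hits = integer(0), stringsAsFactors = FALSE))
  p <- list(...)
  arg <- function(nm, def) if (!is.null(p[[nm]])) p[[nm]] else def
  minScore <- arg("minScore", 50); maxExpected <- arg("maxExpected", 0.01)
  topPercent <- arg("topPercent", 10); topN <- arg("topN", 25L)
  dt <- data.table::as.data.table(hits)
  # vectorized equivalent of filterHitsLCA applied per read
  dt <- dt[bitscore >= minScore & evalue <= maxExpected]
  if (!nrow(dt))
    return(data.frame(read_id = character(0), lineage = character(0),
                      depth = integer(0), rank = character(0),
                      n_hits = integer(0), stringsAsFactors = FALSE))
  dt[, best := max(bitscore), by = read_id]
  dt <- dt[bitscore >= (1 - topPercent / 100) * best]
  dt <- dt[order(read_id, evalue, -bitscore, subject)]
  dt <- dt[, utils::head(.SD, topN), by = read_id]
  # LCA: single-lineage reads resolve directly; mixed reads enumerate
  calls <- dt[, {
    lin <- unique(lineage)
    if (length(lin) == 1L) {
      d <- lengths(strsplit(lin, ";", fixed = TRUE))
      list(lineage = lin, depth = as.integer(d),
           rank = if (d == 0L) "root"
                  else if (d <= length(LCA_RANKS)) LCA_RANKS[d]
                  else paste0("rank", d),
           n_hits = .N)
    } else {
      l <- lcaLineage(lin)
      list(lineage = l$lineage, depth = l$depth, rank = l$rank,
           n_hits = .N)
    }
  }, by = read_id]
  as.data.frame(calls[!is.na(lineage)])
}

# family name of a lineage assigned at family rank or deeper, else NA
familyOf <- function(lineage, depth) {
  famIdx <- length(LCA_RANKS)
  ifelse(!is.na(depth) & depth >= famIdx,
         vapply(strsplit(lineage, ";", fixed = TRUE),
                function(p) if (length(p) >= famIdx) p[famIdx]
                            else NA_character_, character(1)),
         NA_character_)
}

#' Per-sample family count table from taxonomy calls
#'
#' Reads assigned at family rank or deeper are projected to their family;
#' shallower assignments are excluded. Families supported by fewer than
#' \code{minSupport} reads in a sample are zeroed for that sample.
#'
#' @param taxCalls data.frame from \code{\link{taxonomyCalls}} plus a
#'   \code{sample} column.
#' @param minSupport minimum reads per (sample, family) (default 1).
#' @return matrix families x samples of read counts.
#' @export
aggregateFamilies <- function(taxCalls, minSupport = 1L) {
  fam <- familyOf(taxCalls$lineage, taxCalls$depth)
  keep <- !is.na(fam)
  if (!any(keep)) return(matrix(0, 0, 0))
  tab <- table(family = fam[keep], sample = taxCalls$sample[keep])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m[m < minSupport] <- 0L
  m
}

#' Family-by-gene table of functional reads
#'
#' Joins KO-assigned reads with their family assignment; KO-assigned reads
#' without a family-rank taxonomy call are counted under "unclassified".
#'
#' @param koCalls data.frame from \code{\link{callKOs}} plus \code{sample}.
#' @param taxCalls data.frame from \code{\link{taxonomyCalls}}.
#' @return data.frame(sample, family, gene, count).
#' @export
familyGeneTable <- function(koCalls, taxCalls) {
  assigned <- koCalls[koCalls$status == "assigned", ]
  if (!nrow(assigned))
    return(data.frame(sample = character(0), family = character(0),
                      gene = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  man <- table1Manifest()
  assigned$gene <- man$gene[match(assigned$ko, man$ko)]
  fam <- taxCalls[, c("read_id", "lineage", "depth")]
  assigned$family <- familyOf(
    fam$lineage[match(assigned$read_id, fam$read_id)],
    fam$depth[match(assigned$read_id, fam$read_id)])
  assigned$family[is.na(assigned$family)] <- "unclassified"
  agg <- stats::aggregate(list(count = rep(1L, nrow(assigned))),
                          by = assigned[, c("sample", "family", "gene")],
                          FUN = sum)
  agg[order(agg$sample, agg$family, agg$gene), ]
}
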