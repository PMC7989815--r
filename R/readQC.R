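# Read quality control and six-frame ORF prediction.

qualsOf <- function(reads) {
  qs <- as.character(Biostrings::quality(reads))
  lapply(qs, function(s) utf8ToInt(s) - 33L)
}

#' Trim terminal low-quality bases
#'
#' Bases are removed from each end while the terminal base quality is below
#' \code{minTerminalQ}; interior bases are untouched. Reads trimmed to
#' nothing become zero-width (the discard sentinel; \code{filterLength}
#' drops them).
#'
#' @param reads a \code{QualityScaledDNAStringSet} (Phred-33).
#' @param minTerminalQ minimum terminal Phred quality (default 15).
#' @return the trimmed \code{QualityScaledDNAStringSet}.
#' @export
trimReads <- function(reads, minTerminalQ = 15L) {
  if (!length(reads)) return(reads)
  q <- qualsOf(reads)
  bounds <- vapply(seq_along(reads), function(i) {
    qi <- q[[i]]
    ok <- qi >= minTerminalQ
    if (!any(ok)) return(c(1L, 0L))
    c(which(ok)[1], max(which(ok)))
  }, integer(2))
  out <- IRanges::narrow(reads, start = bounds[1, ], end = bounds[2, ])
  out
}

#' Drop reads shorter than a minimum length
#'
#' @param reads a \code{QualityScaledDNAStringSet}.
#' @param minLen minimum kept length in bp (default 50; a 50 bp read is
#'   kept, a 49 bp read is dropped).
#' @return the filtered set.
#' @export
filterLength <- function(reads, minLen = 50L) {
  reads[Biostrings::width(reads) >= minLen]
}

#' Remove reads matching a contaminant reference
#'
#' A read is removed when it aligns locally to any contaminant sequence
#' (either strand) at \code{>= minIdentity} percent identity over
#' \code{>= minCoverage} percent of its length. Candidate reads are found
#' by shared 11-mers, then verified by local alignment.
#'
#' @param reads a \code{QualityScaledDNAStringSet}.
#' @param contaminants a \code{DNAStringSet} (or FASTA path).
#' @param minIdentity percent identity threshold (default 94).
#' @param minCoverage percent read coverage threshold (default 90).
#' @return the screened read set.
#' @export
removeContaminants <- function(reads, contaminants, minIdentity = 94,
                               minCoverage = 90) {
  if (is.character(contaminants))
    contaminants <- Biostrings::readDNAStringSet(contaminants)
  if (!length(contaminants)) {
    warning("empty contaminant reference; reads passed through unscreened")
    return(reads)
  }
  k <- 11L
  kmerSet <- unique(unlist(lapply(as.character(contaminants), function(s) {
    if (nchar(s) < k) return(character(0))
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  })))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  drop <- vapply(seq_along(reads), function(i) {
    s <- as.character(reads[[i]])
    L <- nchar(s)
    if (L < k) return(FALSE)
    rc <- as.character(Biostrings::reverseComplement(reads[[i]]))
    rk <- unique(c(substring(s, 1:(L - k + 1), k:L),
                   substring(rc, 1:(L - k + 1), k:L)))
    if (!any(rk %in% kmerSet)) return(FALSE)
    for (str in c(s, rc)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(str), contaminants, type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      pid <- Biostrings::pid(aln, type = "PID1")
      cov <- 100 * (BiocGenerics::end(Biostrings::pattern(aln)) -
        BiocGenerics::start(Biostrings::pattern(aln)) + 1) / L
      if (any(pid >= minIdentity & cov >= minCoverage)) return(TRUE)
    }
    FALSE
  }, logical(1))
  reads[!drop]
}

#' Predict open reading frames in all six frames
#'
#' Emits every maximal stop-free stretch (stop-to-stop or to read edge) of
#' at least \code{minAaLen} amino acids in each of the six frames.
#' Ambiguous codons translate to 'X' and never read as a stop. Coordinates
#' are 0-based half-open on the read's forward strand; translating
#' \code{read[start:end]} in the recorded frame reproduces \code{aa}.
#'
#' @param reads a \code{DNAStringSet} (qualities ignored) or single string.
#' @param minAaLen minimum ORF length in amino acids (default 20).
#' @return data.frame(read_id, frame, start, end, aa).
#' @export
predictOrfs <- function(reads, minAaLen = 20L) {
  if (is.character(reads))
    reads <- Biostrings::DNAStringSet(stats::setNames(reads,
      if (is.null(names(reads))) sprintf("read%d", seq_along(reads))
      else names(reads)))
  reads <- Biostrings::DNAStringSet(reads)  # strip qualities if any
  if (is.null(names(reads))) names(reads) <- sprintf("read%d", seq_along(reads))
  L <- Biostrings::width(reads)
  out <- vector("list", 6)
  oi <- 0L
  for (dir in c(1L, -1L)) {
    dna <- if (dir == 1L) reads else Biostrings::reverseComplement(reads)
    for (f in 1:3) {
      keep <- which((L - (f - 1L)) %/% 3L >= 1L)
      if (!length(keep)) next
      k <- (L[keep] - (f - 1L)) %/% 3L
      sub <- Biostrings::subseq(dna[keep], start = f, width = 3L * k)
      aa <- as.character(suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "solve", no.init.codon = TRUE)))
      hits <- gregexpr("[^*]+", aa, perl = TRUE)
      nPer <- vapply(hits, function(h) if (h[1] == -1) 0L else length(h),
                     integer(1))
      idx <- rep.int(seq_along(aa), nPer)
      st <- unlist(hits[nPer > 0], use.names = FALSE)
      len <- unlist(lapply(hits[nPer > 0], attr, "match.length"),
                    use.names = FALSE)
      sel <- len >= minAaLen
      if (!any(sel)) { oi <- oi + 1L; next }
      idx <- idx[sel]; st <- st[sel]; len <- len[sel]
      ri <- keep[idx]
      # aa position -> nt coords in the scanned strand
      s0 <- (f - 1L) + 3L * (st - 1L)
      e0 <- s0 + 3L * len
      if (dir == -1L) { tmp <- s0; s0 <- L[ri] - e0; e0 <- L[ri] - tmp }
      oi <- oi + 1L
      out[[oi]] <- data.frame(read_id = names(reads)[ri], frame = dir * f,
                              start = s0, end = e0,
                              aa = substring(aa[idx], st, st + len - 1L),
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(read_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      aa = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$read_id, res$frame, res$start), ]
}

#' Run the full read-QC stage
#'
#' Terminal quality trimming, minimum-length filtering and (optionally)
#' contaminant screening, with per-stage read counts.
#'
#' @param reads a \code{QualityScaledDNAStringSet}.
#' @param minTerminalQ terminal Phred threshold (default 15).
#' @param minLen minimum read length (default 50).
#' @param contaminants optional contaminant \code{DNAStringSet} or path.
#' @param minIdentity,minCoverage contaminant-screen thresholds.
#' @return list(reads, summary = data.frame(stage, reads)).
#' @export
runQC <- function(reads, minTerminalQ = 15L, minLen = 50L,
                  contaminants = NULL, minIdentity = 94, minCoverage = 90) {
  n0 <- length(reads)
  reads <- trimReads(reads, minTerminalQ)
  reads <- filterLength(reads, minLen)
  n1 <- length(reads)
  if (!is.null(contaminants)) {
    reads <- removeContaminants(reads, contaminants, minIdentity, minCoverage)
  }
  n2 <- length(reads)
  list(reads = reads,
       summary = data.frame(
         stage = c("input", "trim+length", "contaminant"),
         reads = c(n0, n1, n2)))
}
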