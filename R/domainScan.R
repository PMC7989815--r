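# Scanning predicted ORFs against the profile-HMM library.

#' Scan ORFs against a profile-HMM library
#'
#' Computes the best local Viterbi hit of every (ORF, model) pair and keeps
#' hits with E-value at or below \code{threshold}. E-values follow the
#' model-scan convention (database size = number of models scanned, unless
#' overridden). A consensus 4-mer prescreen (analogous to the fast ungapped
#' prefilter of production HMM software) skips pairs that cannot reach the
#' reporting threshold for the packaged models; set
#' \code{prescreen = FALSE} for exhaustive scoring.
#'
#' @param orfs data.frame from \code{\link{predictOrfs}} (columns read_id,
#'   frame, start, end, aa), or a character vector of peptides.
#' @param hmms named list of calibrated \linkS4class{ProfileHMM}s.
#' @param threshold E-value threshold (default 1e-5).
#' @param dbSize effective database size (default \code{length(hmms)}).
#' @param prescreen use the consensus 4-mer prefilter (default TRUE).
#' @return data.frame(orf_row, read_id, hmm, score, evalue, qstart, qend):
#'   one row per passing (ORF, model) pair.
#' @export
scanOrfs <- function(orfs, hmms, threshold = 1e-5, dbSize = length(hmms),
                     prescreen = TRUE) {
  if (is.character(orfs))
    orfs <- data.frame(read_id = sprintf("orf%d", seq_along(orfs)),
                       frame = rep(1L, length(orfs)),
                       start = rep(0L, length(orfs)),
                       end = 3L * nchar(orfs),
                       aa = orfs, stringsAsFactors = FALSE)
  empty <- data.frame(orf_row = integer(0), read_id = character(0),
                      hmm = character(0), score = numeric(0),
                      evalue = numeric(0), qstart = integer(0),
                      qend = integer(0), stringsAsFactors = FALSE)
  if (!nrow(orfs) || !length(hmms)) return(empty)
  for (h in hmms) if (!isCalibrated(h))
    stop("all models must be calibrated before scanning (calibrateHMM)")
  sms <- lapply(hmms, hmmScoringMatrices)
  cons <- lapply(hmms, consensusKmerCodes)
  # only scores that could reach the threshold are worth reporting; the
  # floor is a loose lower bound from the least stringent calibration
  floorBits <- min(vapply(hmms, function(h) {
    mu <- h@calibration[[1]]; lambda <- h@calibration[[2]]
    p <- min(1, threshold / dbSize)
    mu - log(-log1p(-p)) / lambda
  }, numeric(1))) - 5
  res <- cpp_scan_viterbi(orfs$aa,
                          lapply(sms, `[[`, "matLO"),
                          lapply(sms, `[[`, "insLO"),
                          lapply(sms, `[[`, "trans"),
                          cons, prescreen, floorBits)
  if (!nrow(res)) return(empty)
  ev <- vapply(seq_len(nrow(res)), function(i)
    hmmEvalue(hmms[[res$hmm[i]]], res$score[i], dbSize), numeric(1))
  keep <- ev <= threshold
  if (!any(keep)) return(empty)
  data.frame(orf_row = res$orf[keep],
             read_id = orfs$read_id[res$orf[keep]],
             hmm = names(hmms)[res$hmm[keep]],
             score = res$score[keep], evalue = ev[keep],
             qstart = res$qstart[keep], qend = res$qend[keep],
             stringsAsFactors = FALSE)
}

#' Reads passing the profile-HMM filter
#'
#' Per-read aggregation of \code{\link{scanOrfs}} hits: a read passes when
#' at least one of its ORFs carries a passing hit; the single best
#' (ORF, model) hit represents the read.
#'
#' @param hits data.frame from \code{\link{scanOrfs}}.
#' @return data.frame, one row per passing read (best hit first).
#' @export
hmmPassingReads <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$read_id, hits$evalue, -hits$score)
  h <- hits[ord, ]
  h[!duplicated(h$read_id), ]
}
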