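# Profile HMM construction, HMMER3-ASCII IO, calibration and E-values.

#' Construct a ProfileHMM from a domain consensus sequence
#'
#' Builds a position-specific profile in which each match state emits the
#' consensus residue with probability \code{consProb} and spreads the rest
#' uniformly over the other 19 residues. Insert states emit the background.
#' The emission concentration is deliberately high: conserved domain columns
#' must out-score chance matches by more than a chance match gains, so that
#' paralogs sharing only half of the domain columns stay below the reporting
#' threshold (see the methods vignette).
#'
#' @param name model name.
#' @param accession model accession string.
#' @param consensus consensus amino-acid string (one letter per match state).
#' @param consProb emission probability of the consensus residue.
#' @param transitions named numeric vector overriding the default node
#'   transitions (names among mm, mi, md, im, ii, dm, dd).
#' @return a \linkS4class{ProfileHMM} (uncalibrated).
#' @export
makeProfileHMM <- function(name, accession, consensus, consProb = 0.98,
                           transitions = NULL) {
  cons <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(cons %in% AA20))
  M <- length(cons)
  mat <- matrix((1 - consProb) / 19, M, 20, dimnames = list(NULL, AA20))
  mat[cbind(seq_len(M), match(cons, AA20))] <- consProb
  ins <- matrix(1 / 20, M, 20, dimnames = list(NULL, AA20))
  tr <- c(mm = 0.98, mi = 0.01, md = 0.01, im = 0.65, ii = 0.35,
          dm = 0.9, dd = 0.1)
  if (!is.null(transitions)) tr[names(transitions)] <- transitions
  trm <- matrix(rep(tr, each = M), M, 7,
                dimnames = list(NULL, names(tr)))
  new("ProfileHMM", name = name, accession = accession, nstates = M,
      matchEmis = mat, insertEmis = ins, transitions = trm,
      background = rep(1 / 20, 20), calibration = numeric(0))
}

# Log2-odds scoring matrices for the Viterbi kernel. Column 21 scores 'X'
# (and any unknown residue) as background, i.e. log-odds 0.
hmmScoringMatrices <- function(hmm) {
  bg <- hmm@background
  matLO <- cbind(log2(sweep(hmm@matchEmis, 2, bg, "/")), 0)
  insLO <- cbind(log2(sweep(hmm@insertEmis, 2, bg, "/")), 0)
  tr <- hmm@transitions
  trLO <- ifelse(tr > 0, log2(tr), -1e30)
  list(matLO = matLO, insLO = insLO, trans = trLO)
}

#' Best local Viterbi score of a peptide against a profile HMM
#'
#' Scores the best local (Smith-Waterman-style entry/exit) Viterbi path in
#' bits relative to the background model. Entry is uniform over match states
#' (probability 1/M), exit is free; paths start and end in a match state.
#' 'X' residues score as background (log-odds 0).
#'
#' @param hmm a \linkS4class{ProfileHMM}.
#' @param aaSeq amino-acid string.
#' @return list with \code{score} (bits) and the envelope \code{qstart},
#'   \code{qend} (0-based half-open on the peptide).
#' @export
viterbiScore <- function(hmm, aaSeq) {
  stopifnot(nchar(aaSeq) > 0)
  sm <- hmmScoringMatrices(hmm)
  cpp_viterbi_local(toupper(aaSeq), sm$matLO, sm$insLO, sm$trans)
}

#' Fit the Gumbel calibration of a ProfileHMM from a random null
#'
#' When a model file carries no STATS line, the score-to-E-value map is
#' fitted by maximum likelihood on local Viterbi scores of random background
#' sequences (the approach tool-internal calibrations take).
#'
#' @param hmm a \linkS4class{ProfileHMM}.
#' @param n number of null sequences.
#' @param len length of each null sequence (amino acids).
#' @param seed integer seed for the null draw.
#' @return the model with \code{calibration = c(mu, lambda)} filled in.
#' @export
calibrateHMM <- function(hmm, n = 200L, len = 100L, seed = 1L) {
  sm <- hmmScoringMatrices(hmm)
  scores <- withSeed(seed, {
    vapply(seq_len(n), function(i) {
      s <- paste(sample(AA20, len, replace = TRUE, prob = hmm@background),
                 collapse = "")
      cpp_viterbi_local(s, sm$matLO, sm$insLO, sm$trans)$score
    }, numeric(1))
  })
  fit <- fitGumbelML(scores)
  hmm@calibration <- c(mu = unname(fit["mu"]), lambda = unname(fit["lambda"]))
  validObject(hmm)
  hmm
}

# Maximum-likelihood Gumbel fit (location mu, rate lambda).
fitGumbelML <- function(x) {
  stopifnot(length(x) >= 10, stats::sd(x) > 0)
  m <- min(x)
  f <- function(lam) {
    w <- exp(-lam * (x - m))  # exponents <= 0: no overflow
    mean(x) - sum(x * w) / sum(w) - 1 / lam
  }
  lo <- 1e-3 / stats::sd(x); hi <- 100 / stats::sd(x)
  lam <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  mu <- m - log(mean(exp(-lam * (x - m)))) / lam
  c(mu = mu, lambda = lam)
}

#' E-value of a local Viterbi bit score
#'
#' \code{E = dbSize * P(S >= s)} under the Gumbel law with the model's
#' (mu, lambda). The database size follows the model-scan convention:
#' the number of profiles each query is scanned against.
#'
#' @param hmm a calibrated \linkS4class{ProfileHMM}.
#' @param bitscore local Viterbi score in bits.
#' @param dbSize effective database size (number of models).
#' @return E-value (strictly decreasing in \code{bitscore}).
#' @export
hmmEvalue <- function(hmm, bitscore, dbSize = 1) {
  if (!isCalibrated(hmm))
    stop("model '", hmm@name, "' has no calibration; run calibrateHMM() ",
         "or supply a file with STATS lines")
  mu <- hmm@calibration[[1]]; lambda <- hmm@calibration[[2]]
  p <- -expm1(-exp(-lambda * (bitscore - mu)))
  dbSize * p
}

# Consensus residues and their 4-mer codes (prescreen acceleration).
hmmConsensus <- function(hmm) {
  paste(AA20[apply(hmm@matchEmis, 1, which.max)], collapse = "")
}

consensusKmerCodes <- function(hmm) {
  s <- match(strsplit(hmmConsensus(hmm), "")[[1]], AA20) - 1L
  if (length(s) < 4) return(integer(0))
  n <- length(s) - 3L
  code <- integer(n)
  for (k in 0:3) code <- code * 20L + s[(1 + k):(n + k)]
  unique(code)
}

#' Write a ProfileHMM in the HMMER3 ASCII dialect
#'
#' Emits the HMMER3/f subset this package reads back: header (NAME, ACC,
#' LENG, ALPH, optional STATS LOCAL VITERBI), then per-node match emission,
#' insert emission and transition lines as negative natural-log
#' probabilities with \code{*} for impossible transitions.
#'
#' @param hmm a \linkS4class{ProfileHMM}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProfileHMM <- function(hmm, path) {
  fmt <- function(p) ifelse(p <= 0, "*", sprintf("%.5f", -log(p)))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("HMMER3/f [polyglue synthetic profile]")
  w("NAME  ", hmm@name)
  w("ACC   ", hmm@accession)
  w("LENG  ", hmm@nstates)
  w("ALPH  amino")
  if (isCalibrated(hmm))
    w(sprintf("STATS LOCAL VITERBI %.4f %.5f",
              hmm@calibration[[1]], hmm@calibration[[2]]))
  w("HMM          ", paste(sprintf("%8s", AA20), collapse = " "))
  w("            ", paste(sprintf("%8s",
      c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
      collapse = " "))
  for (j in seq_len(hmm@nstates)) {
    w(sprintf("%7d ", j),
      paste(sprintf("%8s", fmt(hmm@matchEmis[j, ])), collapse = " "))
    w("         ",
      paste(sprintf("%8s", fmt(hmm@insertEmis[j, ])), collapse = " "))
    w("         ",
      paste(sprintf("%8s", fmt(hmm@transitions[j, ])), collapse = " "))
  }
  w("//")
  invisible(path)
}

#' Parse a profile HMM from the HMMER3 ASCII dialect subset
#'
#' Reads the amino-acid HMMER3/f subset written by
#' \code{\link{writeProfileHMM}}: header lines NAME / ACC / LENG / ALPH /
#' STATS LOCAL VITERBI, then per-node emission and transition blocks of
#' negative natural-log probabilities. Unrecognized optional header fields
#' are ignored with a warning; non-amino alphabets and malformed node
#' blocks are errors.
#'
#' @param path path to the model file (first model is read).
#' @return a \linkS4class{ProfileHMM}.
#' @export
readProfileHMM <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^HMMER3", lines[1]))
    stop("not a HMMER3 ASCII file: ", path)
  hdrEnd <- grep("^HMM\\s", lines)[1]
  if (is.na(hdrEnd)) stop("no HMM emission header line found in ", path)
  name <- acc <- NA_character_; leng <- NA_integer_
  calibration <- numeric(0)
  known <- c("NAME", "ACC", "LENG", "ALPH", "STATS", "DESC", "MAXL",
             "RF", "MM", "CONS", "CS", "MAP", "DATE", "NSEQ", "EFFN",
             "CKSUM", "GA", "TC", "NC", "COM")
  for (ln in lines[2:(hdrEnd - 1)]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok)) next
    key <- tok[1]
    if (key == "NAME") name <- tok[2]
    else if (key == "ACC") acc <- tok[2]
    else if (key == "LENG") leng <- as.integer(tok[2])
    else if (key == "ALPH") {
      if (tolower(tok[2]) != "amino")
        stop("unsupported alphabet '", tok[2], "': only amino models are read")
    } else if (key == "STATS") {
      if (length(tok) >= 5 && tok[2] == "LOCAL" && tok[3] == "VITERBI")
        calibration <- c(mu = as.numeric(tok[4]), lambda = as.numeric(tok[5]))
    } else if (!key %in% known) {
      warning("ignoring unrecognized header field '", key, "'")
    }
  }
  if (is.na(leng)) stop("missing LENG in ", path)
  num <- function(tok) ifelse(tok == "*", Inf, suppressWarnings(as.numeric(tok)))
  body <- lines[(hdrEnd + 2):length(lines)]
  body <- body[!grepl("^\\s*$", body)]
  if (length(body) && grepl("^\\s*COMPO", body[1])) {
    # COMPO block: average composition + node-0 insert/transition lines
    body <- body[-(1:3)]
  }
  end <- grep("^//", body)[1]
  if (!is.na(end)) body <- body[seq_len(end - 1)]
  if (length(body) != 3L * leng)
    stop("malformed node count: expected ", 3L * leng,
         " node lines, found ", length(body),
         " (near line '", body[min(length(body), 1)], "')")
  mat <- matrix(0, leng, 20, dimnames = list(NULL, AA20))
  ins <- matrix(0, leng, 20, dimnames = list(NULL, AA20))
  trm <- matrix(0, leng, 7,
                dimnames = list(NULL, c("mm", "mi", "md", "im", "ii", "dm", "dd")))
  renorm <- function(v) if (sum(v) > 0) v / sum(v) else v
  for (j in seq_len(leng)) {
    mt <- strsplit(trimws(body[3 * j - 2]), "\\s+")[[1]]
    if (suppressWarnings(as.integer(mt[1])) != j)
      stop("malformed node block at node ", j, " (line '", body[3 * j - 2], "')")
    mat[j, ] <- renorm(exp(-num(mt[2:21])))
    it <- strsplit(trimws(body[3 * j - 1]), "\\s+")[[1]]
    ins[j, ] <- renorm(exp(-num(it[1:20])))
    tt <- strsplit(trimws(body[3 * j]), "\\s+")[[1]]
    tv <- exp(-num(tt[1:7]))
    # renormalize each outgoing triplet (written at finite precision)
    tv[1:3] <- renorm(tv[1:3]); tv[4:5] <- renorm(tv[4:5])
    tv[6:7] <- renorm(tv[6:7])
    trm[j, ] <- tv
  }
  new("ProfileHMM", name = name, accession = acc, nstates = leng,
      matchEmis = mat, insertEmis = ins, transitions = trm,
      background = rep(1 / 20, 20), calibration = calibration)
}
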