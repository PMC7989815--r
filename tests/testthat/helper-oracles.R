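# Independent oracles used by the kernel tests. These re-derive expected
# values by brute force and stay independent of the code paths they check.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomAA <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# Exhaustive path enumeration for the local profile Viterbi score: every
# entry match state, every start position, every M/I/D path, exit from any
# match state. Tractable for M <= 3 and sequences up to ~6 residues.
enumViterbi <- function(hmm, seq) {
  sm <- polyglue:::hmmScoringMatrices(hmm)
  enc <- match(strsplit(seq, "")[[1]], AA)
  enc[is.na(enc)] <- 21L
  M <- hmmLength(hmm)
  L <- length(enc)
  tr <- sm$trans
  entry <- -log2(M)
  best <- -Inf
  rec <- function(state, j, t, sc) {
    if (state == "M") best <<- max(best, sc)
    if (state == "M") {
      if (t <= L && j < M)
        rec("M", j + 1, t + 1, sc + tr[j, 1] + sm$matLO[j + 1, enc[t]])
      if (t <= L)
        rec("I", j, t + 1, sc + tr[j, 2] + sm$insLO[j, enc[t]])
      if (j < M)
        rec("D", j + 1, t, sc + tr[j, 3])
    } else if (state == "I") {
      if (t <= L && j < M)
        rec("M", j + 1, t + 1, sc + tr[j, 4] + sm$matLO[j + 1, enc[t]])
      if (t <= L)
        rec("I", j, t + 1, sc + tr[j, 5] + sm$insLO[j, enc[t]])
    } else {
      if (t <= L && j < M)
        rec("M", j + 1, t + 1, sc + tr[j, 6] + sm$matLO[j + 1, enc[t]])
      if (j < M)
        rec("D", j + 1, t, sc + tr[j, 7])
    }
  }
  for (t0 in seq_len(L)) for (j0 in seq_len(M))
    rec("M", j0, t0 + 1, entry + sm$matLO[j0, enc[t0]])
  best
}

# Random profile HMM with Dirichlet-ish emission rows (for the equivalence
# sweep; transitions stay in the package's standard node layout).
randomHMM <- function(M) {
  remis <- function() {
    m <- matrix(stats::rexp(M * 20), M, 20)
    sweep(m, 1, rowSums(m), "/")
  }
  mat <- remis(); ins <- remis()
  tr3 <- matrix(stats::rexp(M * 3), M, 3); tr3 <- sweep(tr3, 1, rowSums(tr3), "/")
  tr2 <- matrix(stats::rexp(M * 2), M, 2); tr2 <- sweep(tr2, 1, rowSums(tr2), "/")
  td <- matrix(stats::rexp(M * 2), M, 2); td <- sweep(td, 1, rowSums(td), "/")
  trans <- cbind(tr3, tr2, td)
  colnames(trans) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  colnames(mat) <- colnames(ins) <- AA
  methods::new("ProfileHMM", name = "rand", accession = "RAND",
               nstates = as.integer(M), matchEmis = mat, insertEmis = ins,
               transitions = trans, background = rep(1 / 20, 20),
               calibration = numeric(0))
}

# Full unbanded affine-gap Smith-Waterman by direct dynamic programming.
swOracle <- function(q, s, gapOpen = 11, gapExt = 1) {
  B <- polyglue:::blosum62Matrix()
  code <- function(x) {
    i <- match(strsplit(x, "")[[1]], AA)
    i[is.na(i)] <- 21L
    i
  }
  qi <- code(q); si <- code(s)
  n <- length(qi); m <- length(si)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i - 1, j] - gapOpen - gapExt, E[i - 1, j] - gapExt)
    F[i, j] <- max(H[i, j - 1] - gapOpen - gapExt, F[i, j - 1] - gapExt)
    H[i, j] <- max(0, H[i - 1, j - 1] + B[qi[i - 1], si[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# Phred-33 quality-scaled read set builder for QC tests.
makeReads <- function(seqs, quals) {
  if (is.numeric(quals)) quals <- list(quals)
  qs <- vapply(quals, function(q) intToUtf8(q + 33L), character(1))
  r <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(qs))
  names(r) <- sprintf("r%d", seq_along(seqs))
  r
}
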