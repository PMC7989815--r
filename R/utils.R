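# Shared constants and small helpers.

#' @useDynLib polyglue, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# data.table syntax is used inside this package without attaching it
.datatable.aware <- TRUE

# silence NSE notes for data.table column references
utils::globalVariables(c(".", ".SD", "evalue", "bitscore", "query",
                         "read_id", "subject", "lineage"))

# Amino-acid alphabet order shared with the C++ kernels.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Ungapped BLOSUM62 Karlin-Altschul parameters used for translated-search
# E-values; the alignment engine itself is in-package, these are the
# conventional ungapped constants for this matrix.
KA_LAMBDA <- 0.3176
KA_K <- 0.134

.blosum62_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix over the package alphabet
#'
#' Returns BLOSUM62 reindexed to the 20-letter alphabet used by the
#' alignment kernels, with a 21st row/column for 'X' (score 0 against
#' everything, -1 against itself is not used; kept at 0).
#'
#' @return a 21 x 21 numeric matrix.
#' @keywords internal
blosum62Matrix <- function() {
  if (!is.null(.blosum62_cache$m)) return(.blosum62_cache$m)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  b <- get("BLOSUM62", envir = environment())
  m <- matrix(0, 21, 21, dimnames = list(c(AA20, "X"), c(AA20, "X")))
  m[1:20, 1:20] <- b[AA20, AA20]
  .blosum62_cache$m <- m
  m
}

# Deterministic child seeds: derive per-stage seeds below 2^31 from a root.
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483629L)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Phred-33 helpers.
phredToProb <- function(q) 10^(-q / 10)

qualsToString <- function(q) {
  intToUtf8(pmin(pmax(q, 0L), 93L) + 33L)
}

stringToQuals <- function(s) {
  utf8ToInt(s) - 33L
}

#' Extdata path helper
#' @param file file name under inst/extdata
#' @return absolute path
#' @keywords internal
pgExtdata <- function(file) {
  system.file("extdata", file, package = "polyglue", mustWork = TRUE)
}
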