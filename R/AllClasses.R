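# S4 classes for the central data objects.

#' ProfileHMM: a profile hidden Markov model over amino acids
#'
#' Match/insert/delete profile in the HMMER3 node layout: per node, 20 match
#' emission probabilities, 20 insert emission probabilities, and the seven
#' transitions (m->m, m->i, m->d, i->m, i->i, d->m, d->d). Probabilities are
#' stored in linear space; scoring converts to log2-odds against a uniform
#' background. The optional Gumbel calibration (mu, lambda, in bits) drives
#' E-value computation for local Viterbi scores.
#'
#' @slot name model name.
#' @slot accession model accession (e.g. a Pfam or TIGRFAMs id).
#' @slot nstates number of match states (model length M).
#' @slot matchEmis M x 20 matrix of match emission probabilities.
#' @slot insertEmis M x 20 matrix of insert emission probabilities.
#' @slot transitions M x 7 matrix of transition probabilities
#'   (columns mm, mi, md, im, ii, dm, dd).
#' @slot background length-20 background frequencies.
#' @slot calibration numeric(2) c(mu, lambda) or numeric(0) when uncalibrated.
#' @exportClass ProfileHMM
setClass("ProfileHMM",
  representation(
    name = "character",
    accession = "character",
    nstates = "integer",
    matchEmis = "matrix",
    insertEmis = "matrix",
    transitions = "matrix",
    background = "numeric",
    calibration = "numeric"
  )
)

setValidity("ProfileHMM", function(object) {
  M <- object@nstates
  msgs <- character()
  if (M < 1L) msgs <- c(msgs, "model must have at least one match state")
  if (!all(dim(object@matchEmis) == c(M, 20)))
    msgs <- c(msgs, "matchEmis must be M x 20")
  if (!all(dim(object@insertEmis) == c(M, 20)))
    msgs <- c(msgs, "insertEmis must be M x 20")
  if (!all(dim(object@transitions) == c(M, 7)))
    msgs <- c(msgs, "transitions must be M x 7")
  if (nrow(object@matchEmis) == M && M >= 1L) {
    if (max(abs(rowSums(object@matchEmis) - 1)) > 1e-6)
      msgs <- c(msgs, "match emission rows must sum to 1")
    if (max(abs(rowSums(object@insertEmis) - 1)) > 1e-6)
      msgs <- c(msgs, "insert emission rows must sum to 1")
    tr <- object@transitions
    # transition triplets from each state sum to 1 (final node may lack
    # outgoing match/delete transitions; zeros there are tolerated)
    mOut <- rowSums(tr[, 1:3, drop = FALSE])
    iOut <- rowSums(tr[, 4:5, drop = FALSE])
    dOut <- rowSums(tr[, 6:7, drop = FALSE])
    ok <- function(x) abs(x - 1) <= 1e-6 | abs(x) <= 1e-6
    if (!all(ok(mOut)) || !all(ok(iOut)) || !all(ok(dOut)))
      msgs <- c(msgs, "transition triplets must sum to 1 (or be absent)")
  }
  if (length(object@background) != 20 ||
      abs(sum(object@background) - 1) > 1e-6)
    msgs <- c(msgs, "background must be 20 frequencies summing to 1")
  if (!length(object@calibration) %in% c(0L, 2L))
    msgs <- c(msgs, "calibration must be numeric(0) or c(mu, lambda)")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ProfileHMM number of match states
#' @param x a ProfileHMM
#' @export
hmmLength <- function(x) x@nstates

#' @describeIn ProfileHMM model accession
#' @export
hmmAccession <- function(x) x@accession

#' @describeIn ProfileHMM TRUE when Gumbel calibration is present
#' @export
isCalibrated <- function(x) length(x@calibration) == 2L

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM", object@name, paste0("(", object@accession, ")"),
      "with", object@nstates, "match states;",
      if (isCalibrated(object))
        sprintf("calibrated (mu=%.2f, lambda=%.3f)", object@calibration[1],
                object@calibration[2]) else "uncalibrated", "\n")
})

#' CommunityDesign: design of a synthetic soil community study
#'
#' Describes the 18-sample strip-split-plot layout (2 tillage regimes x
#' 3 depth layers x 3 plot replicates), the bacterial families with their
#' baseline fractions and per-depth/per-tillage multipliers, each family's
#' repertoire of EPS/LPS target genes and decoy paralogs, and the read
#' simulation parameters.
#'
#' @slot families data.frame with columns family, lineage, baseline, and one
#'   multiplier column per depth layer and tillage level.
#' @slot repertoire named list: family -> character vector of target gene
#'   symbols carried by that family.
#' @slot samples data.frame with columns sample, tillage, depth, plot.
#' @slot mix named numeric c(target, decoy, housekeeping): how each family's
#'   coding reads split between target-gene, decoy-paralog and housekeeping
#'   peptides; sums to 1.
#' @slot backgroundFraction fraction of reads drawn from non-coding filler.
#' @slot readLength read length in bp.
#' @slot nReads reads per sample.
#' @slot errorRate mean per-base substitution rate implied by the quality
#'   profile (0 disables sequencing error).
#' @slot replicateSdLog lognormal sd of plot-level family abundance noise.
#' @slot decoySimilarity fraction of domain columns preserved in decoys.
#' @slot seed integer root seed.
#' @exportClass CommunityDesign
setClass("CommunityDesign",
  representation(
    families = "data.frame",
    repertoire = "list",
    samples = "data.frame",
    mix = "numeric",
    backgroundFraction = "numeric",
    readLength = "integer",
    nReads = "integer",
    errorRate = "numeric",
    replicateSdLog = "numeric",
    decoySimilarity = "numeric",
    seed = "integer"
  )
)

setValidity("CommunityDesign", function(object) {
  msgs <- character()
  need <- c("family", "lineage", "baseline")
  if (!all(need %in% names(object@families)))
    msgs <- c(msgs, "families needs columns family, lineage, baseline")
  if (!all(names(object@repertoire) %in% object@families$family))
    msgs <- c(msgs, "repertoire names must be families")
  if (nrow(object@samples) && !all(c("sample", "tillage", "depth", "plot")
      %in% names(object@samples)))
    msgs <- c(msgs, "samples needs columns sample, tillage, depth, plot")
  if (object@backgroundFraction < 0 || object@backgroundFraction >= 1)
    msgs <- c(msgs, "backgroundFraction must be in [0, 1)")
  if (!all(c("target", "decoy", "housekeeping") %in% names(object@mix)) ||
      any(object@mix < 0) || abs(sum(object@mix) - 1) > 1e-9)
    msgs <- c(msgs, "mix must be nonnegative (target, decoy, housekeeping) summing to 1")
  allGenes <- table1Manifest()$gene
  for (fam in names(object@repertoire)) {
    rep <- object@repertoire[[fam]]
    if (!all(rep %in% allGenes))
      msgs <- c(msgs, paste0("unknown target gene in repertoire of ", fam))
    if (length(rep) >= length(allGenes))
      msgs <- c(msgs, paste0("repertoire of ", fam,
                             " must be a proper subset of the target genes"))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CommunityDesign sample identifiers of the design
#' @param x a CommunityDesign
#' @export
designSamples <- function(x) x@samples$sample

setMethod("show", "CommunityDesign", function(object) {
  cat("CommunityDesign:", nrow(object@families), "families,",
      nrow(object@samples), "samples,", object@nReads, "reads/sample,",
      "read length", object@readLength, "bp\n")
  cat("  background fraction:", object@backgroundFraction,
      " error rate:", object@errorRate,
      " decoy similarity:", object@decoySimilarity, "\n")
})

#' KOReference: an indexed, lineage-labelled protein reference
#'
#' Wraps an \code{AAStringSet} of reference peptides with per-sequence
#' KO / gene / pathway / lineage annotation and an amino-acid k-mer index
#' for the seeded translated search.
#'
#' @slot sequences an \code{AAStringSet}.
#' @slot info \code{DataFrame} with columns seq_id, ko, gene, pathway,
#'   lineage (semicolon-separated ranked path down to family or deeper).
#' @slot kmerIndex list with the flattened 4-mer index (code, subject, pos).
#' @exportClass KOReference
setClass("KOReference",
  representation(
    sequences = "ANY",
    info = "ANY",
    kmerIndex = "list"
  )
)

setValidity("KOReference", function(object) {
  msgs <- character()
  if (length(object@sequences) != nrow(object@info))
    msgs <- c(msgs, "sequences and info must be parallel")
  need <- c("seq_id", "ko", "gene", "pathway", "lineage")
  if (!all(need %in% colnames(object@info)))
    msgs <- c(msgs, "info needs seq_id, ko, gene, pathway, lineage")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn KOReference number of reference peptides
#' @param x a KOReference
#' @export
referenceSize <- function(x) length(x@sequences)

#' @describeIn KOReference per-sequence annotation table
#' @export
referenceInfo <- function(x) x@info

#' @describeIn KOReference reference peptides as an AAStringSet
#' @export
referenceSequences <- function(x) x@sequences

setMethod("show", "KOReference", function(object) {
  kos <- unique(object@info$ko)
  kos <- kos[!is.na(kos) & kos != ""]
  cat("KOReference:", length(object@sequences), "peptides,",
      length(kos), "KO groups,",
      length(unique(object@info$lineage)), "lineages\n")
})
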