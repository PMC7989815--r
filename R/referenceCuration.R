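# Curated KO reference: manifest, labelled-FASTA indexing, and the
# domain-presence / specificity screens that reduce candidate KOs to the
# retained target set.

#' The curated target manifest (14 EPS/LPS genes)
#'
#' The packaged mapping between the 14 target genes involved in EPS/LPS
#' biosynthesis and export, their KEGG Orthology ids and the profile-HMM
#' accessions of their conserved domains (16 accessions; \emph{lptG} and
#' \emph{lptC} each carry two).
#'
#' @return data.frame with columns protein, ko, hmm (comma-separated
#'   accessions), gene, pathway (EPS or LPS).
#' @export
table1Manifest <- function() {
  utils::read.delim(pgExtdata("table1_manifest.tsv"),
                    stringsAsFactors = FALSE)
}

#' The candidate KO list (synthetic stand-in)
#'
#' The 81-entry candidate list (67 EPS + 14 LPS KOs) from which the curated
#' targets were retained. The packaged table is a synthetic stand-in: the 14
#' retained KOs are real, the remaining ids are placeholders mirroring the
#' structure of the original supplementary candidate table.
#'
#' @return data.frame with columns ko, pathway, retained.
#' @export
candidateManifest <- function() {
  utils::read.delim(pgExtdata("candidate_kos_synthetic.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' All HMM accessions of the target manifest
#' @return character vector of 16 accessions.
#' @export
manifestAccessions <- function() {
  unlist(strsplit(table1Manifest()$hmm, ","))
}

#' Build an indexed KO reference from a labelled FASTA
#'
#' Headers must carry whitespace-separated \code{key=value} annotations:
#' \code{>seqid ko=K01991 gene=wza pathway=EPS lineage=Bacteria;...;Family}.
#' Records missing \code{ko} or \code{lineage} are rejected with a logged
#' reason; duplicated seq_ids keep the first record.
#'
#' @param fasta path to the labelled FASTA file.
#' @return a \linkS4class{KOReference}.
#' @export
buildReference <- function(fasta) {
  seqs <- Biostrings::readAAStringSet(fasta)
  if (!length(seqs)) {
    warning("empty reference FASTA: ", fasta)
    return(koReferenceFromInfo(Biostrings::AAStringSet(),
      S4Vectors::DataFrame(seq_id = character(), ko = character(),
                           gene = character(), pathway = character(),
                           lineage = character(), type = character())))
  }
  hdr <- names(seqs)
  seq_id <- sub("\\s.*$", "", hdr)
  field <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    out <- rep(NA_character_, length(hdr))
    out[grepl(paste0(key, "="), hdr)] <- sub(paste0("^", key, "="), "", m)
    out
  }
  info <- S4Vectors::DataFrame(
    seq_id = seq_id, ko = field("ko"), gene = field("gene"),
    pathway = field("pathway"), lineage = field("lineage"),
    type = ifelse(is.na(field("type")), "target", field("type"))
  )
  bad <- is.na(info$ko) | is.na(info$lineage)
  if (any(bad)) {
    message("rejected ", sum(bad), " record(s) missing ko= or lineage=: ",
            paste(utils::head(seq_id[bad], 5), collapse = ", "))
    seqs <- seqs[!bad]; info <- info[!bad, ]
  }
  dup <- duplicated(info$seq_id)
  if (any(dup)) {
    message("rejected ", sum(dup), " duplicated seq_id(s); first kept")
    seqs <- seqs[!dup]; info <- info[!dup, ]
  }
  names(seqs) <- info$seq_id
  koReferenceFromInfo(seqs, info)
}

# Assemble a KOReference and its amino-acid 4-mer index.
koReferenceFromInfo <- function(seqs, info) {
  idx <- if (length(seqs)) cpp_build_kmer_index(as.character(seqs))
         else list(code = integer(0), subject = integer(0), pos = integer(0))
  new("KOReference", sequences = seqs, info = info, kmerIndex = idx)
}

#' Write a KOReference as a labelled FASTA
#' @param ref a \linkS4class{KOReference}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReference <- function(ref, path) {
  info <- ref@info
  seqs <- ref@sequences
  names(seqs) <- sprintf("%s ko=%s gene=%s pathway=%s lineage=%s type=%s",
                         info$seq_id, info$ko, info$gene, info$pathway,
                         info$lineage, info$type)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Subset a KOReference
#' @param ref a \linkS4class{KOReference}.
#' @param keep logical or integer index over the reference peptides.
#' @return the re-indexed subset.
#' @export
subsetReference <- function(ref, keep) {
  koReferenceFromInfo(ref@sequences[keep], ref@info[keep, ])
}

#' Domain-presence screen for one KO's sequence set
#'
#' A candidate KO is retained only when at least \code{minFraction} of its
#' member peptides carry a passing hit (E <= \code{evalue}) against the
#' KO's conserved-domain profile.
#'
#' @param ref a \linkS4class{KOReference}.
#' @param koId KO id to screen.
#' @param hmm a calibrated \linkS4class{ProfileHMM}.
#' @param evalue E-value threshold.
#' @param minFraction minimum passing fraction for retention.
#' @param dbSize database size for E-values (default: one model).
#' @return list(retain, nPass, nSeq, fraction).
#' @export
verifyDomainPresence <- function(ref, koId, hmm, evalue = 1e-5,
                                 minFraction = 0.9, dbSize = 1) {
  sel <- which(!is.na(ref@info$ko) & ref@info$ko == koId &
               ref@info$type == "target")
  if (!length(sel)) stop("no sequences for KO ", koId)
  sq <- as.character(ref@sequences[sel])
  ev <- vapply(sq, function(s)
    hmmEvalue(hmm, viterbiScore(hmm, s)$score, dbSize), numeric(1))
  nPass <- sum(ev <= evalue)
  frac <- nPass / length(sel)
  list(retain = frac >= minFraction, nPass = nPass,
       nSeq = length(sel), fraction = frac)
}

#' Specificity screen of KO assignments against a label oracle
#'
#' Mirrors the manual screen used during reference curation: per KO, sample
#' \code{min(nSample, n assigned)} assigned reads without replacement and
#' pass only when every sampled read's true function (from the truth table
#' or a user label file) matches the KO's target gene.
#'
#' @param assignments data.frame with columns read_id, ko (assigned reads).
#' @param labelOracle named character vector mapping read_id to the true
#'   origin gene symbol (or "background").
#' @param koId KO id to screen.
#' @param nSample sample size (default 25).
#' @param seed integer seed for the read sample.
#' @return list(verdict = "pass" | "fail" | "untested", nAssigned, nSampled,
#'   sampled read ids, offending read ids, seed).
#' @export
specificityScreen <- function(assignments, labelOracle, koId,
                              nSample = 25L, seed = 1L) {
  man <- table1Manifest()
  gene <- man$gene[man$ko == koId]
  if (!length(gene)) stop("KO ", koId, " is not in the target manifest")
  reads <- assignments$read_id[assignments$ko == koId]
  if (!length(reads)) {
    return(list(verdict = "untested", nAssigned = 0L, nSampled = 0L,
                sampled = character(0), offending = character(0), seed = seed))
  }
  n <- min(nSample, length(reads))
  sampled <- withSeed(seed, sample(reads, n))
  truth <- unname(labelOracle[sampled])
  bad <- sampled[is.na(truth) | truth != gene]
  list(verdict = if (length(bad)) "fail" else "pass",
       nAssigned = length(reads), nSampled = n,
       sampled = sampled, offending = bad, seed = seed)
}

#' Run the specificity screen over every manifest KO
#'
#' @inheritParams specificityScreen
#' @return data.frame(ko, gene, n_assigned, n_sampled, verdict, seed).
#' @export
specificityReport <- function(assignments, labelOracle, nSample = 25L,
                              seed = 1L) {
  man <- table1Manifest()
  rows <- lapply(seq_len(nrow(man)), function(i) {
    r <- specificityScreen(assignments, labelOracle, man$ko[i],
                           nSample, seed + i)
    data.frame(ko = man$ko[i], gene = man$gene[i],
               n_assigned = r$nAssigned, n_sampled = r$nSampled,
               verdict = r$verdict, seed = r$seed)
  })
  do.call(rbind, rows)
}
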