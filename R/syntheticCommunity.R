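# Mock-metagenome generator: family-structured communities with depth/tillage
# multipliers, reverse-translated coding reads with Phred-calibrated
# substitution errors, and an exact read-level truth table.

#' Construct a CommunityDesign
#'
#' @param families data.frame as returned by \code{\link{syntheticFamilies}}.
#' @param repertoire named list family -> target gene symbols.
#' @param nReads reads per sample.
#' @param readLength read length (bp).
#' @param backgroundFraction fraction of reads from random non-coding filler.
#' @param mix named c(target, decoy, housekeeping) coding-read split.
#' @param errorRate mean per-base substitution rate (0 disables errors).
#' @param replicateSdLog lognormal sd of plot-level family abundance noise.
#' @param decoySimilarity fraction of domain columns decoy paralogs preserve.
#' @param seed integer root seed.
#' @return a \linkS4class{CommunityDesign} with the full 18-sample layout
#'   (2 tillage x 3 depths x 3 plot replicates).
#' @export
communityDesign <- function(families = syntheticFamilies(),
                            repertoire = syntheticRepertoire(),
                            nReads = 10000L, readLength = 300L,
                            backgroundFraction = 0.3,
                            mix = c(target = 0.12, decoy = 0.08,
                                    housekeeping = 0.80),
                            errorRate = 0.001, replicateSdLog = 0.15,
                            decoySimilarity = 0.5, seed = 1L) {
  samples <- expand.grid(plot = paste0("P", 1:3),
                         depth = c("0-10", "10-20", "20-50"),
                         tillage = c("CT", "RT"),
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_%s", samples$tillage, samples$depth,
                            samples$plot)
  samples$plot <- paste(samples$tillage, samples$plot, sep = "_")
  samples <- samples[, c("sample", "tillage", "depth", "plot")]
  obj <- new("CommunityDesign", families = families,
             repertoire = repertoire, samples = samples,
             mix = mix, backgroundFraction = backgroundFraction,
             readLength = as.integer(readLength), nReads = as.integer(nReads),
             errorRate = errorRate, replicateSdLog = replicateSdLog,
             decoySimilarity = decoySimilarity, seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Default 18-sample study design
#'
#' The packaged study conditions: 10 families (depth-shifted and
#' surface-enriched guilds), 10,000 reads per sample, 300 bp reads, 30\%
#' non-coding background, decoys at 50\% domain-column similarity and a
#' mean substitution rate of 0.001.
#'
#' @param seed integer root seed.
#' @return a \linkS4class{CommunityDesign}.
#' @export
defaultCommunityDesign <- function(seed = 1L) {
  communityDesign(seed = seed)
}

#' True family fractions for one sample
#'
#' Baseline fractions times the sample's depth and tillage multipliers,
#' times seeded plot-level lognormal noise, renormalized to sum to 1.
#'
#' @param design a \linkS4class{CommunityDesign}.
#' @param sampleId a sample id of the design.
#' @return named numeric vector over families (sums to 1).
#' @export
familyFractions <- function(design, sampleId) {
  row <- design@samples[design@samples$sample == sampleId, ]
  if (!nrow(row)) stop("unknown sample: ", sampleId)
  fams <- design@families
  depthCol <- c("0-10" = "d0_10", "10-20" = "d10_20", "20-50" = "d20_50")
  tillCol <- c(CT = "ct", RT = "rt")
  f <- fams$baseline * fams[[depthCol[[row$depth]]]] *
    fams[[tillCol[[row$tillage]]]]
  if (design@replicateSdLog > 0) {
    noise <- withSeed(deriveSeed(design@seed, paste0("frac_", sampleId)),
                      stats::rlnorm(length(f), 0, design@replicateSdLog))
    f <- f * noise
  }
  stats::setNames(f / sum(f), fams$family)
}

# Quality profile and the per-cycle substitution rates it encodes.
qualityProfile <- function(design) {
  L <- design@readLength
  if (design@errorRate <= 0) {
    rate <- rep(0, L); q <- rep(37L, L)
  } else {
    rate <- design@errorRate * seq(0.5, 1.5, length.out = L)
    q <- as.integer(round(-10 * log10(rate)))
  }
  list(rate = rate, quals = q, qualString = qualsToString(q))
}

# AA -> codon table for reverse translation (uniform synonymous choice).
codonChoices <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA20]
}

#' Simulate one sample's reads and truth slice
#'
#' Coding reads reverse-translate a random window of a source peptide with
#' uniform synonymous codons, on a random strand, then receive substitution
#' errors at the Phred-implied per-cycle rate. Background reads are uniform
#' random DNA. Bookkeeping is exact: background reads are exactly
#' \code{round(backgroundFraction * nReads)}.
#'
#' @param design a \linkS4class{CommunityDesign}.
#' @param sampleId sample id.
#' @param world the synthetic protein world (defaults to the packaged one
#'   at the design's decoy similarity).
#' @return list(reads = \code{QualityScaledDNAStringSet}, origins =
#'   per-read truth data.frame, geneCounts = per-gene read counts,
#'   familyFractions = the sample's true fractions).
#' @export
simulateSample <- function(design, sampleId,
                           world = syntheticWorld(design@decoySimilarity)) {
  fr <- familyFractions(design, sampleId)
  info <- as.data.frame(world$reference@info)
  pepSeqs <- as.character(world$reference@sequences)
  # resolve each (family, category) to candidate peptides
  missing <- unlist(lapply(names(design@repertoire), function(fam) {
    g <- design@repertoire[[fam]]
    g[!g %in% info$gene[info$lineage ==
        design@families$lineage[design@families$family == fam]]]
  }))
  if (length(missing))
    stop("configuration error: no reference peptide for repertoire gene(s) ",
         paste(unique(missing), collapse = ", "))

  n <- design@nReads
  nbg <- as.integer(round(design@backgroundFraction * n))
  ncod <- n - nbg
  prof <- qualityProfile(design)
  L <- design@readLength
  nc <- L %/% 3L
  cod <- codonChoices()
  maxCod <- max(lengths(cod))
  codMat <- matrix(NA_character_, 20, maxCod, dimnames = list(AA20, NULL))
  for (a in AA20) codMat[a, seq_along(cod[[a]])] <- cod[[a]]
  nCod <- stats::setNames(lengths(cod), AA20)

  out <- withSeed(deriveSeed(design@seed, paste0("reads_", sampleId)), {
    famDraw <- if (ncod > 0)
      sample(names(fr), ncod, replace = TRUE, prob = fr) else character(0)
    pepIdx <- integer(ncod); geneSym <- character(ncod)
    for (fam in unique(famDraw)) {
      sel <- which(famDraw == fam)
      lin <- design@families$lineage[design@families$family == fam]
      finfo <- info[info$lineage == lin, ]
      tg <- which(finfo$type == "target" &
                  finfo$gene %in% design@repertoire[[fam]])
      dc <- which(finfo$type == "decoy")
      hk <- which(finfo$type == "housekeeping")
      w <- c(rep(design@mix[["target"]] / max(1, length(tg)), length(tg)),
             rep(design@mix[["decoy"]] / max(1, length(dc)), length(dc)),
             rep(design@mix[["housekeeping"]] / max(1, length(hk)), length(hk)))
      cand <- c(tg, dc, hk)
      keep <- w > 0
      pick <- cand[keep][sample.int(sum(keep), length(sel), replace = TRUE,
                                    prob = w[keep])]
      # map back to global peptide rows
      pick <- match(finfo$seq_id[pick], info$seq_id)
      pepIdx[sel] <- pick
      geneSym[sel] <- info$gene[pick]
    }
    pepLen <- nchar(pepSeqs)[pepIdx]
    wlen <- pmin(nc, pepLen)
    wstart <- floor(stats::runif(ncod) * (pepLen - wlen + 1)) + 1L
    strand <- ifelse(stats::runif(ncod) < 0.5, "+", "-")

    aaWindows <- substr(pepSeqs[pepIdx], wstart, wstart + wlen - 1L)
    # vectorized reverse translation
    allAA <- strsplit(paste(aaWindows, collapse = ""), "")[[1]]
    u <- stats::runif(length(allAA))
    pickCod <- 1L + floor(u * nCod[allAA])
    codons <- codMat[cbind(match(allAA, AA20), pickCod)]
    grp <- rep.int(seq_len(ncod), nchar(aaWindows))
    dna <- vapply(split(codons, grp), paste, character(1), collapse = "")
    # pad short reads (windows shorter than the read) with random bases
    short <- which(nchar(dna) < L)
    if (length(short)) {
      pad <- vapply(L - nchar(dna[short]), function(k)
        paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
              collapse = ""), character(1))
      dna[short] <- paste0(dna[short], pad)
    }
    neg <- strand == "-"
    if (any(neg)) {
      dna[neg] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(dna[neg])))
    }
    bg <- vapply(seq_len(nbg), function(i)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1))
    reads <- c(dna, bg)
    # Phred-implied substitution errors
    if (design@errorRate > 0) {
      nerr <- stats::rbinom(length(reads), L, mean(prof$rate))
      for (i in which(nerr > 0)) {
        pos <- sample.int(L, nerr[i], prob = prof$rate)
        v <- strsplit(reads[i], "")[[1]]
        v[pos] <- vapply(v[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        reads[i] <- paste(v, collapse = "")
      }
    }
    ids <- sprintf("%s_r%06d", sampleId, seq_along(reads))
    origins <- data.frame(
      read_id = ids,
      sample = sampleId,
      family = c(famDraw, rep("background", nbg)),
      gene = c(geneSym, rep("background", nbg)),
      peptide = c(info$seq_id[pepIdx], rep(NA_character_, nbg)),
      pep_start = c(wstart, rep(NA_integer_, nbg)),
      pep_end = c(wstart + wlen - 1L, rep(NA_integer_, nbg)),
      strand = c(strand, rep(NA_character_, nbg)),
      stringsAsFactors = FALSE
    )
    list(reads = reads, ids = ids, origins = origins)
  })

  sr <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(out$reads),
    Biostrings::PhredQuality(rep(prof$qualString, length(out$reads))))
  names(sr) <- out$ids
  cod_or <- out$origins[out$origins$gene != "background", ]
  gc <- as.data.frame(table(gene = cod_or$gene), stringsAsFactors = FALSE)
  names(gc)[2] <- "count"
  gc$sample <- sampleId
  list(reads = sr, origins = out$origins,
       geneCounts = gc[, c("sample", "gene", "count")],
       familyFractions = fr)
}

#' Simulate the full study
#'
#' @param design a \linkS4class{CommunityDesign}.
#' @param world optional pre-built synthetic world.
#' @return list(reads = named list of \code{QualityScaledDNAStringSet},
#'   truth = truth table list with \code{origins}, \code{geneCounts},
#'   \code{familyFractions}).
#' @export
simulateStudy <- function(design,
                          world = syntheticWorld(design@decoySimilarity)) {
  sims <- lapply(designSamples(design), simulateSample,
                 design = design, world = world)
  names(sims) <- designSamples(design)
  ff <- do.call(rbind, lapply(sims, function(s) s$familyFractions))
  rownames(ff) <- designSamples(design)
  list(
    reads = lapply(sims, `[[`, "reads"),
    truth = list(
      origins = do.call(rbind, lapply(sims, `[[`, "origins")),
      geneCounts = do.call(rbind, lapply(sims, `[[`, "geneCounts")),
      familyFractions = ff
    )
  )
}

#' Write a truth table to TSV
#'
#' One row per read plus per-sample summary blocks (gene counts and family
#' fractions); the layout round-trips losslessly through
#' \code{\link{readTruthTable}}.
#'
#' @param truth truth table list (see \code{\link{simulateStudy}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##SECTION reads", con)
  utils::write.table(truth$origins, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines("##SECTION summaries", con)
  samples <- unique(truth$origins$sample)
  for (s in samples) {
    writeLines(paste0("##SAMPLE ", s), con)
    gc <- truth$geneCounts[truth$geneCounts$sample == s, ]
    utils::write.table(gc, con, sep = "\t", row.names = FALSE, quote = FALSE)
    ff <- truth$familyFractions[s, , drop = FALSE]
    writeLines(paste0("##FRACTIONS ", s, "\t",
                      paste(colnames(ff), collapse = "\t")), con)
    writeLines(paste0("##VALUES ", s, "\t",
                      paste(format(ff[1, ], digits = 17), collapse = "\t")),
               con)
  }
  invisible(path)
}

#' Read a truth table written by \code{\link{writeTruthTable}}
#' @param path TSV path.
#' @return truth table list (origins, geneCounts, familyFractions).
#' @export
readTruthTable <- function(path) {
  lines <- readLines(path)
  secSum <- which(lines == "##SECTION summaries")
  readLines2df <- function(x) {
    if (length(x) <= 1) return(NULL)
    utils::read.table(text = x, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  }
  origins <- if (secSum > 2) readLines2df(lines[seq.int(2, secSum - 1)])
             else NULL
  if (is.null(origins))
    origins <- utils::read.table(text = lines[2], sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)[0, ]
  rest <- if (secSum < length(lines)) lines[(secSum + 1):length(lines)]
          else character(0)
  sampStarts <- grep("^##SAMPLE ", rest)
  geneCounts <- NULL
  fracRows <- list()
  for (i in seq_along(sampStarts)) {
    s <- sub("^##SAMPLE ", "", rest[sampStarts[i]])
    end <- if (i < length(sampStarts)) sampStarts[i + 1] - 1 else length(rest)
    blk <- rest[(sampStarts[i] + 1):end]
    fr <- grep("^##FRACTIONS ", blk)
    va <- grep("^##VALUES ", blk)
    gcLines <- blk[setdiff(seq_along(blk), c(fr, va))]
    gc <- readLines2df(gcLines)
    if (!is.null(gc) && nrow(gc)) geneCounts <- rbind(geneCounts, gc)
    fams <- strsplit(sub("^##FRACTIONS [^\t]+\t", "", blk[fr[1]]), "\t")[[1]]
    vals <- as.numeric(strsplit(sub("^##VALUES [^\t]+\t", "", blk[va[1]]),
                                "\t")[[1]])
    fracRows[[s]] <- stats::setNames(vals, fams)
  }
  ff <- do.call(rbind, fracRows)
  list(origins = origins, geneCounts = geneCounts, familyFractions = ff)
}
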