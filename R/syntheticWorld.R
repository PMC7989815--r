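# The packaged synthetic protein world: per-gene domain consensus sequences,
# per-family homolog variants, decoy paralogs and housekeeping peptides, and
# the matching profile-HMM library. Everything is generated in code from a
# fixed internal seed, so the "database" is a deterministic constant of the
# package; it is a synthetic stand-in for the unversioned public databases a
# field study would query.

WORLD_SEED <- 104729L
DOMAIN_LEN <- 80L
FLANK_LEN <- 40L
HK_LEN <- 200L
HK_PER_FAMILY <- 3L
DOMAIN_SUB_RATE <- 0.10   # family variant divergence inside the domain
FLANK_SUB_RATE <- 0.25    # family variant divergence in the flanks

.world_cache <- new.env(parent = emptyenv())

#' Bacterial families of the default synthetic community
#'
#' Ten soil families spanning abundant and rare, with a depth-shifted
#' deep-soil guild (Anaerolineaceae, Nitrospiraceae) and surface-enriched
#' families (Chitinophagaceae, Bradyrhizobiaceae). Baselines are fractions
#' before renormalization; multipliers act multiplicatively per depth layer.
#'
#' @return data.frame(family, lineage, baseline, d0_10, d10_20, d20_50,
#'   ct, rt).
#' @export
syntheticFamilies <- function() {
  lin <- function(ph, cl, or, fam)
    paste("Bacteria", ph, cl, or, fam, sep = ";")
  fam <- data.frame(
    family = c("Anaerolineaceae", "Chitinophagaceae", "Bradyrhizobiaceae",
               "Planctomycetaceae", "Nitrospiraceae", "Cytophagaceae",
               "Polyangiaceae", "Acidobacteriaceae", "Flavobacteriaceae",
               "Solibacteraceae"),
    lineage = c(
      lin("Chloroflexi", "Anaerolineae", "Anaerolineales", "Anaerolineaceae"),
      lin("Bacteroidetes", "Chitinophagia", "Chitinophagales", "Chitinophagaceae"),
      lin("Proteobacteria", "Alphaproteobacteria", "Rhizobiales", "Bradyrhizobiaceae"),
      lin("Planctomycetes", "Planctomycetia", "Planctomycetales", "Planctomycetaceae"),
      lin("Nitrospirae", "Nitrospira", "Nitrospirales", "Nitrospiraceae"),
      lin("Bacteroidetes", "Cytophagia", "Cytophagales", "Cytophagaceae"),
      lin("Proteobacteria", "Deltaproteobacteria", "Myxococcales", "Polyangiaceae"),
      lin("Acidobacteria", "Acidobacteriia", "Acidobacteriales", "Acidobacteriaceae"),
      lin("Bacteroidetes", "Flavobacteriia", "Flavobacteriales", "Flavobacteriaceae"),
      lin("Acidobacteria", "Solibacteres", "Solibacterales", "Solibacteraceae")),
    baseline = c(0.14, 0.12, 0.10, 0.09, 0.08, 0.07, 0.06, 0.05, 0.03, 0.02),
    d0_10  = c(0.8, 1.8, 1.4, 1.0, 0.7, 1.3, 1.3, 1.0, 1.0, 1.0),
    d10_20 = c(1.0, 1.2, 1.1, 1.0, 0.9, 1.1, 1.0, 1.0, 1.0, 1.0),
    d20_50 = c(2.2, 0.6, 0.7, 1.0, 1.8, 0.8, 0.8, 1.0, 1.0, 1.0),
    ct = 1, rt = 1,
    stringsAsFactors = FALSE
  )
  fam$baseline <- fam$baseline / sum(fam$baseline)
  fam
}

#' Family repertoires of EPS/LPS target genes
#'
#' Each family carries a proper subset of the 14 target genes; every gene is
#' carried by at least two families.
#'
#' @return named list family -> character vector of gene symbols.
#' @export
syntheticRepertoire <- function() {
  list(
    Anaerolineaceae   = c("kpsE", "epsG", "wzt"),
    Chitinophagaceae  = c("wza", "wcaB", "wcaF", "epsA", "lptF", "lptG"),
    Bradyrhizobiaceae = c("wza", "algE", "algJ", "kpsE", "epsA", "sacB",
                          "lptF", "lptG", "lptC"),
    Planctomycetaceae = c("wza", "wcaK/amsJ", "kpsE", "wzt"),
    Nitrospiraceae    = c("wzt"),
    Cytophagaceae     = c("wza", "wcaB", "wcaF", "lptF", "lptG"),
    Polyangiaceae     = c("algE", "algJ", "lptF", "lptG", "lptC"),
    Acidobacteriaceae = c("wcaK/amsJ", "epsG"),
    Flavobacteriaceae = c("wcaB", "wcaF", "sacB", "lptF", "lptG", "lptC"),
    Solibacteraceae   = c("epsG")
  )
}

randomPeptide <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

substitutePeptide <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(v)) < rate
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(a)
      sample(setdiff(AA20, a), 1), character(1))
  }
  paste(v, collapse = "")
}

# Decoy domain: randomize evenly spaced columns so a paralog preserving a
# fraction `similarity` of the domain columns never carries a long conserved
# run (interspersed conservation, the regime the specificity screen probes).
decoyDomain <- function(consensus, similarity) {
  v <- strsplit(consensus, "")[[1]]
  if (similarity < 1) {
    k <- max(1L, round(1 / (1 - similarity)))
    idx <- seq(k, length(v), by = k)
    v[idx] <- vapply(v[idx], function(a)
      sample(setdiff(AA20, a), 1), character(1))
  }
  paste(v, collapse = "")
}

# Per-gene architecture: flank1 + domain + flank2 consensus strings.
geneArchitecture <- function() {
  man <- table1Manifest()
  withSeed(WORLD_SEED, {
    arch <- lapply(man$gene, function(g) {
      list(flank1 = randomPeptide(FLANK_LEN),
           domain = randomPeptide(DOMAIN_LEN),
           flank2 = randomPeptide(FLANK_LEN))
    })
    names(arch) <- man$gene
    arch
  })
}

#' Build the synthetic protein world
#'
#' Generates, deterministically from the package's internal world seed:
#' per-(family, gene) target peptides (flank + conserved domain + flank,
#' with family-specific divergence), per-family decoy paralogs that preserve
#' \code{decoySimilarity} of the domain columns with shuffled remainder and
#' flanks, per-family housekeeping peptides (taxonomy anchors), and one
#' calibrated \linkS4class{ProfileHMM} per manifest accession.
#'
#' @param decoySimilarity fraction of domain columns decoys preserve.
#' @return list(reference = full \linkS4class{KOReference} (targets +
#'   decoys + housekeeping), koReference = targets only, hmms = named list
#'   of calibrated models, architecture = per-gene consensus parts).
#' @export
syntheticWorld <- function(decoySimilarity = 0.5) {
  key <- sprintf("w%.4f", decoySimilarity)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  man <- table1Manifest()
  fams <- syntheticFamilies()
  repert <- syntheticRepertoire()
  arch <- geneArchitecture()

  ids <- chars <- ko <- gene <- pathway <- lineage <- type <- character(0)
  add <- function(id, aa, k, g, p, lin, ty) {
    ids <<- c(ids, id); chars <<- c(chars, aa); ko <<- c(ko, k)
    gene <<- c(gene, g); pathway <<- c(pathway, p)
    lineage <<- c(lineage, lin); type <<- c(type, ty)
  }

  withSeed(deriveSeed(WORLD_SEED, key), {
    for (fi in seq_len(nrow(fams))) {
      fam <- fams$family[fi]; lin <- fams$lineage[fi]
      genes <- repert[[fam]]
      for (g in genes) {
        row <- man[man$gene == g, ]
        a <- arch[[g]]
        aa <- paste0(substitutePeptide(a$flank1, FLANK_SUB_RATE),
                     substitutePeptide(a$domain, DOMAIN_SUB_RATE),
                     substitutePeptide(a$flank2, FLANK_SUB_RATE))
        add(sprintf("%s|%s", gsub("/", "_", g), fam), aa, row$ko, g,
            row$pathway, lin, "target")
      }
      # two decoy paralogs per family, derived from its first two genes
      for (g in utils::head(genes, 2)) {
        dom <- decoyDomain(arch[[g]]$domain, decoySimilarity)
        aa <- paste0(randomPeptide(FLANK_LEN), dom, randomPeptide(FLANK_LEN))
        add(sprintf("decoy_%s|%s", gsub("/", "_", g), fam), aa,
            "none", paste0(g, "_like"), "decoy", lin, "decoy")
      }
      for (h in seq_len(HK_PER_FAMILY)) {
        add(sprintf("hk%d|%s", h, fam), randomPeptide(HK_LEN),
            "none", sprintf("%s_hk%d", fam, h), "housekeeping", lin,
            "housekeeping")
      }
    }
  })

  seqs <- Biostrings::AAStringSet(chars)
  names(seqs) <- ids
  info <- S4Vectors::DataFrame(seq_id = ids, ko = ko, gene = gene,
                               pathway = pathway, lineage = lineage,
                               type = type)
  reference <- koReferenceFromInfo(seqs, info)
  koRef <- subsetReference(reference, info$type == "target")

  hmms <- list()
  for (i in seq_len(nrow(man))) {
    accs <- strsplit(man$hmm[i], ",")[[1]]
    dom <- arch[[man$gene[i]]]$domain
    for (j in seq_along(accs)) {
      # a second accession models an inner subregion of the same domain
      cons <- if (j == 1) dom else substr(dom, 11, DOMAIN_LEN - 10)
      h <- makeProfileHMM(paste0(gsub("/", "_", man$gene[i]),
                                 if (j > 1) "_inner" else ""),
                          accs[j], cons)
      hmms[[accs[j]]] <- calibrateHMM(h, seed = deriveSeed(WORLD_SEED, accs[j]))
    }
  }

  out <- list(reference = reference, koReference = koRef, hmms = hmms,
              architecture = arch)
  .world_cache[[key]] <- out
  out
}

#' Write the synthetic HMM library to disk
#' @param dir output directory (created if needed).
#' @param decoySimilarity forwarded to \code{\link{syntheticWorld}}.
#' @return invisibly, the written file paths.
#' @export
writeHMMLibrary <- function(dir, decoySimilarity = 0.5) {
  world <- syntheticWorld(decoySimilarity)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(world$hmms), function(acc) {
    p <- file.path(dir, paste0(acc, ".hmm"))
    writeProfileHMM(world$hmms[[acc]], p)
    p
  }, character(1))
  invisible(paths)
}
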