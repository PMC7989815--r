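# Community statistics: relative abundances, dominance filters, diversity,
# ordination, core microbiomes, and tillage x depth split-plot effect tests.

#' Relative abundance in percent of total filtered reads
#'
#' @param count reads assigned to a feature.
#' @param totalFiltered total filtered reads of the sample (> 0).
#' @return \code{100 * count / totalFiltered}.
#' @export
relativeAbundance <- function(count, totalFiltered) {
  if (any(totalFiltered <= 0)) stop("totalFiltered must be positive")
  if (any(count < 0) || any(count > totalFiltered))
    stop("count must lie in [0, totalFiltered]")
  100 * count / totalFiltered
}

#' Build a features x samples abundance SummarizedExperiment
#'
#' @param counts matrix features x samples of read counts.
#' @param meta data.frame with columns sample, tillage, depth, plot and
#'   total_filtered (total filtered reads per sample).
#' @return a \code{SummarizedExperiment} with assays \code{counts} and
#'   \code{relabund} (percent).
#' @export
abundanceTable <- function(counts, meta) {
  meta <- meta[match(colnames(counts), meta$sample), ]
  stopifnot(!anyNA(meta$sample), all(meta$total_filtered > 0))
  rel <- sweep(counts, 2, meta$total_filtered, "/") * 100
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, relabund = rel),
    colData = S4Vectors::DataFrame(meta, row.names = meta$sample))
}

#' Dominant features by mean relative abundance
#'
#' Features whose mean abundance across all samples strictly exceeds the
#' threshold (0.5\% for families, 0.005\% for genes).
#'
#' @param rel matrix features x samples in percent.
#' @param threshold strict lower bound on the mean percent abundance.
#' @return character vector of dominant feature names.
#' @export
dominantFeatures <- function(rel, threshold) {
  rownames(rel)[rowMeans(rel) > threshold]
}

#' Shannon-Wiener diversity index
#'
#' \code{H = -sum p_i ln p_i} over positive proportions (natural log);
#' input is normalized internally.
#'
#' @param x non-negative feature vector (counts or proportions).
#' @return H.
#' @export
shannonIndex <- function(x) {
  if (any(x < 0)) stop("proportions must be non-negative")
  s <- sum(x)
  if (s == 0) stop("all-zero vector: diversity undefined")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity
#'
#' \code{sum |u - v| / sum (u + v)}; 0 for identical vectors, 1 for
#' disjoint supports.
#'
#' @param u,v non-negative vectors of equal length.
#' @return distance in [0, 1].
#' @export
brayCurtis <- function(u, v) {
  stopifnot(length(u) == length(v))
  if (any(u < 0) || any(v < 0)) stop("vectors must be non-negative")
  tot <- sum(u + v)
  if (tot == 0) stop("both vectors all-zero: distance undefined")
  sum(abs(u - v)) / tot
}

#' Bray-Curtis distance matrix over samples
#'
#' @param rel matrix features x samples.
#' @return a \code{dist} over the columns.
#' @export
brayCurtisDist <- function(rel) {
  n <- ncol(rel)
  d <- matrix(0, n, n, dimnames = list(colnames(rel), colnames(rel)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- brayCurtis(rel[, i], rel[, j])
  stats::as.dist(d)
}

#' NMDS ordination of a distance matrix
#'
#' Non-metric multidimensional scaling (Kruskal stress-1) with seeded
#' random starts, via \code{vegan::metaMDS} on a precomputed distance.
#'
#' @param d a \code{dist} (symmetric, zero diagonal).
#' @param k embedding dimension (default 2).
#' @param nStarts random starts (default 20).
#' @param seed integer seed (same seed, same coordinates).
#' @return list(points = n x k coordinates, stress = stress-1 in [0, 1]).
#' @export
nmdsOrdination <- function(d, k = 2L, nStarts = 20L, seed = 1L) {
  n <- attr(d, "Size")
  if (n < k + 1) stop("need at least k + 1 points for a k-dimensional NMDS")
  fit <- withSeed(seed, vegan::metaMDS(d, k = k, try = nStarts,
                                       trymax = nStarts, trace = 0,
                                       wascores = FALSE))
  list(points = fit$points, stress = fit$stress)
}

#' Core / unique membership across tillage treatments
#'
#' A feature is present in a treatment (at a depth) only when detected in
#' at least two of the three plot replicates (strict majority for other
#' replicate counts, with a warning). Per depth, features are partitioned
#' into those present under both tillage systems, only CT, or only RT.
#'
#' @param counts matrix features x samples.
#' @param meta data.frame(sample, tillage, depth, plot).
#' @return data.frame(depth, feature, ct_present, rt_present,
#'   membership in both / CT_only / RT_only / absent).
#' @export
coreMembership <- function(counts, meta) {
  meta <- meta[match(colnames(counts), meta$sample), ]
  out <- list()
  for (dep in unique(meta$depth)) {
    pres <- list()
    for (till in c("CT", "RT")) {
      sel <- meta$depth == dep & meta$tillage == till
      nrep <- sum(sel)
      need <- if (nrep == 3L) 2L else {
        warning("treatment ", till, " at ", dep, " has ", nrep,
                " replicates; using strict majority")
        floor(nrep / 2) + 1L
      }
      pres[[till]] <- rowSums(counts[, sel, drop = FALSE] > 0) >= need
    }
    membership <- ifelse(pres$CT & pres$RT, "both",
                  ifelse(pres$CT, "CT_only",
                  ifelse(pres$RT, "RT_only", "absent")))
    out[[dep]] <- data.frame(depth = dep, feature = rownames(counts),
                             ct_present = pres$CT, rt_present = pres$RT,
                             membership = membership,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# split-plot F statistics (and p-values) via aov with a plot error stratum;
# for the balanced design this is the exact mixed-model ANOVA, identical to
# the unconstrained REML solution
splitPlotF <- function(y, meta, pvalues = FALSE) {
  dat <- data.frame(y = y, tillage = factor(meta$tillage),
                    depth = factor(meta$depth), plot = factor(meta$plot))
  fit <- stats::aov(y ~ tillage * depth + Error(plot), data = dat)
  s <- summary(fit)
  wp <- s[["Error: plot"]][[1]]
  sp <- s[["Error: Within"]][[1]]
  f <- c(tillage = wp["tillage", "F value"],
         depth = sp["depth", "F value"],
         interaction = sp["tillage:depth", "F value"])
  if (!pvalues) return(f)
  list(f = f,
       p = c(tillage = wp["tillage", "Pr(>F)"],
             depth = sp["depth", "Pr(>F)"],
             interaction = sp["tillage:depth", "Pr(>F)"]))
}

#' Tillage x depth split-plot effect tests per feature
#'
#' Per feature, a multilevel model with tillage as whole-plot factor, depth
#' within plot and their interaction, and a random intercept per plot.
#' F tests come from the exact balanced split-plot stratum decomposition by
#' default, from the \code{nlme::lme} REML fit, or from a seeded structured
#' permutation scheme (whole-plot tillage labels permuted across plots;
#' depth labels permuted within plots) on the split-plot F statistics.
#' p-values are BH-adjusted per factor across features; the two depth
#' contrasts (0-20 vs 20-50 cm, 0-10 vs 10-20 cm) are estimated from the
#' REML fit for features whose depth effect survives BH at \code{alpha}.
#'
#' @param rel matrix features x samples (relative abundances), or a
#'   \code{SummarizedExperiment} from \code{\link{abundanceTable}}.
#' @param meta data.frame(sample, tillage, depth, plot); ignored when
#'   \code{rel} is a SummarizedExperiment.
#' @param method "anova" (default: the exact balanced split-plot stratum F
#'   table, identical to the unconstrained REML solution), "reml"
#'   (\code{nlme::lme} Wald F; conservative for the whole-plot factor when
#'   the plot variance estimate hits the zero boundary), or "permutation".
#' @param nPerm permutations (permutation method only).
#' @param seed integer seed (permutation method only).
#' @param alpha BH threshold gating contrast reporting (default 0.05).
#' @param transform "identity" (default) or "log1p".
#' @return list(tests = data.frame(feature, factor, statistic, p, p_bh),
#'   contrasts = data.frame(feature, contrast, estimate, se, p)).
#' @export
testEffects <- function(rel, meta = NULL,
                        method = c("anova", "reml", "permutation"),
                        nPerm = 999L, seed = 1L, alpha = 0.05,
                        transform = c("identity", "log1p")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  if (methods::is(rel, "SummarizedExperiment")) {
    meta <- as.data.frame(SummarizedExperiment::colData(rel))
    rel <- SummarizedExperiment::assay(rel, "relabund")
  }
  meta <- meta[match(colnames(rel), meta$sample), ]
  if (transform == "log1p") rel <- log1p(rel)
  feats <- rownames(rel)
  if (is.null(feats)) feats <- sprintf("feature%d", seq_len(nrow(rel)))
  dat0 <- data.frame(tillage = factor(meta$tillage),
                     depth = factor(meta$depth),
                     plot = factor(meta$plot))
  balanced <- all(table(dat0$tillage, dat0$depth) ==
                  table(dat0$tillage, dat0$depth)[1])
  if (method %in% c("anova", "reml") && !balanced) {
    warning("unbalanced design: falling back to the permutation scheme")
    method <- "permutation"
  }

  tests <- vector("list", nrow(rel))
  lmeFits <- vector("list", nrow(rel))
  if (method == "anova") {
    for (i in seq_len(nrow(rel))) {
      sp <- splitPlotF(rel[i, ], dat0, pvalues = TRUE)
      tests[[i]] <- data.frame(feature = feats[i],
                               factor = c("tillage", "depth", "interaction"),
                               statistic = unname(sp$f),
                               p = unname(sp$p))
    }
  } else if (method == "reml") {
    for (i in seq_len(nrow(rel))) {
      dat <- cbind(dat0, y = rel[i, ])
      fit <- tryCatch(
        nlme::lme(y ~ tillage * depth, random = ~ 1 | plot, data = dat,
                  method = "REML"),
        error = function(e) NULL)
      if (is.null(fit)) {
        tests[[i]] <- data.frame(feature = feats[i],
                                 factor = c("tillage", "depth", "interaction"),
                                 statistic = NA_real_, p = NA_real_)
        next
      }
      lmeFits[[i]] <- fit
      an <- stats::anova(fit)
      rows <- match(c("tillage", "depth", "tillage:depth"), rownames(an))
      tests[[i]] <- data.frame(feature = feats[i],
                               factor = c("tillage", "depth", "interaction"),
                               statistic = an[rows, "F-value"],
                               p = an[rows, "p-value"])
    }
  } else {
    perms <- permutationScheme(dat0, nPerm, seed)
    for (i in seq_len(nrow(rel))) {
      y <- rel[i, ]
      obs <- splitPlotF(y, dat0)
      exceed <- c(tillage = 0L, depth = 0L, interaction = 0L)
      for (p in perms) {
        fTill <- splitPlotF(y, p$metaT)["tillage"]
        fDep <- splitPlotF(y, p$metaW)[c("depth", "interaction")]
        exceed["tillage"] <- exceed["tillage"] +
          (!is.na(fTill) && fTill >= obs["tillage"] - 1e-12)
        exceed["depth"] <- exceed["depth"] +
          (!is.na(fDep[1]) && fDep[1] >= obs["depth"] - 1e-12)
        exceed["interaction"] <- exceed["interaction"] +
          (!is.na(fDep[2]) && fDep[2] >= obs["interaction"] - 1e-12)
      }
      pv <- (1 + exceed) / (1 + length(perms))
      tests[[i]] <- data.frame(feature = feats[i],
                               factor = c("tillage", "depth", "interaction"),
                               statistic = unname(obs), p = unname(pv))
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_bh <- NA_real_
  for (fac in unique(tests$factor)) {
    sel <- tests$factor == fac
    tests$p_bh[sel] <- stats::p.adjust(tests$p[sel], method = "BH")
  }

  # contrasts for features whose depth effect survives BH
  hit <- tests$feature[tests$factor == "depth" &
                       !is.na(tests$p_bh) & tests$p_bh < alpha]
  contrasts <- NULL
  if (length(hit)) {
    lev <- levels(dat0$depth)  # "0-10", "10-20", "20-50"
    cmat <- list("0-20 vs 20-50" = c(0.5, 0.5, -1),
                 "0-10 vs 10-20" = c(1, -1, 0))
    rows <- list()
    for (f in hit) {
      i <- match(f, feats)
      fit <- lmeFits[[i]]
      if (is.null(fit)) {
        dat <- cbind(dat0, y = rel[i, ])
        fit <- tryCatch(
          nlme::lme(y ~ tillage * depth, random = ~ 1 | plot, data = dat,
                    method = "REML"),
          error = function(e) NULL)
        if (is.null(fit)) next
      }
      emm <- suppressMessages(
        emmeans::emmeans(fit, "depth", data = cbind(dat0, y = rel[i, ])))
      ct <- as.data.frame(suppressMessages(emmeans::contrast(emm, cmat)))
      rows[[f]] <- data.frame(feature = f, contrast = ct$contrast,
                              estimate = ct$estimate, se = ct$SE,
                              p = ct$p.value, stringsAsFactors = FALSE)
    }
    contrasts <- do.call(rbind, rows)
    if (!is.null(contrasts)) rownames(contrasts) <- NULL
  }
  if (is.null(contrasts))
    contrasts <- data.frame(feature = character(0), contrast = character(0),
                            estimate = numeric(0), se = numeric(0),
                            p = numeric(0), stringsAsFactors = FALSE)
  list(tests = tests, contrasts = contrasts)
}

# Structured permutations for the strip-split-plot design: tillage is
# permuted at whole-plot level (plots swap tillage labels); depth layers are
# permuted within each plot (also used for the interaction).
permutationScheme <- function(dat0, nPerm, seed) {
  plots <- levels(dat0$plot)
  plotTill <- vapply(plots, function(pl)
    as.character(dat0$tillage[dat0$plot == pl][1]), character(1))
  withSeed(seed, {
    lapply(seq_len(nPerm), function(b) {
      metaT <- dat0
      shuffled <- stats::setNames(plotTill[sample(length(plots))], plots)
      metaT$tillage <- factor(shuffled[as.character(dat0$plot)],
                              levels = levels(dat0$tillage))
      metaW <- dat0
      for (pl in plots) {
        r <- which(dat0$plot == pl)
        metaW$depth[r] <- dat0$depth[r][sample(length(r))]
      }
      list(metaT = metaT, metaW = metaW)
    })
  })
}

#' Simulate a reduced 18-sample feature table
#'
#' Direct simulation of relative-abundance-like responses on the 2 tillage
#' x 3 depth x 3 plot layout: Gaussian within-group noise, a plot-level
#' random intercept, and an optional planted depth effect (a shift of the
#' deepest layer, in units of the within-group sd) on the first
#' \code{effectFeatures} features. Used for power and type-I calibration
#' of the effect tests at desk scale.
#'
#' @param nFeatures number of features.
#' @param depthEffect shift of the 20-50 cm layer in within-group sd units.
#' @param effectFeatures number of features carrying the effect.
#' @param sdWithin within-group sd (default 1).
#' @param sdPlot plot random-intercept sd (default 0.5).
#' @param seed integer seed.
#' @return list(rel = features x samples matrix, meta, effectFeatures).
#' @export
simulateStudyTable <- function(nFeatures = 15L, depthEffect = 0,
                               effectFeatures = 0L, sdWithin = 1,
                               sdPlot = 0.5, seed = 1L) {
  design <- expand.grid(plot = paste0("P", 1:3),
                        depth = c("0-10", "10-20", "20-50"),
                        tillage = c("CT", "RT"), stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_%s_%s", design$tillage, design$depth,
                           design$plot)
  design$plot <- paste(design$tillage, design$plot, sep = "_")
  meta <- design[, c("sample", "tillage", "depth", "plot")]
  withSeed(seed, {
    plotEff <- matrix(stats::rnorm(nFeatures * 6, 0, sdPlot), nFeatures, 6,
                      dimnames = list(NULL, unique(meta$plot)))
    rel <- matrix(10, nFeatures, 18,
                  dimnames = list(sprintf("feature%02d", seq_len(nFeatures)),
                                  meta$sample))
    rel <- rel + plotEff[, meta$plot] +
      matrix(stats::rnorm(nFeatures * 18, 0, sdWithin), nFeatures, 18)
    if (effectFeatures > 0 && depthEffect != 0) {
      sel <- seq_len(effectFeatures)
      rel[sel, meta$depth == "20-50"] <-
        rel[sel, meta$depth == "20-50"] + depthEffect * sdWithin
    }
    list(rel = rel, meta = meta,
         effectFeatures = rownames(rel)[seq_len(effectFeatures)])
  })
}
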