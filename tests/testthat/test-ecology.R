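# Community statistics: abundances, diversity, ordination, core sets,
# split-plot effect tests.

test_that("relative abundance follows the percent formula", {
  expect_identical(relativeAbundance(50, 10000), 0.5)
  expect_identical(relativeAbundance(0, 10000), 0)
  expect_equal(relativeAbundance(21, 120000), 0.0175)
  expect_error(relativeAbundance(1, 0), "positive")
  expect_error(relativeAbundance(-1, 10), "count")
})

test_that("dominance uses mean abundance with a strict threshold", {
  rel <- rbind(fam1 = rep(0.6, 18), fam2 = rep(0.5, 18),
               fam3 = rep(0.4, 18))
  expect_identical(dominantFeatures(rel, 0.5), "fam1")
  gene <- rbind(g1 = rep(0.006, 18), g2 = rep(0.005, 18))
  expect_identical(dominantFeatures(gene, 0.005), "g1")
})

test_that("Shannon index matches closed forms and direct evaluation", {
  expect_equal(shannonIndex(rep(1, 4)), log(4))
  expect_identical(shannonIndex(c(7, 0, 0)), 0)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannonIndex(p), -sum(p * log(p)))
  expect_equal(shannonIndex(p), 1.0397, tolerance = 1e-4)
  # counts normalize internally
  expect_equal(shannonIndex(c(2, 1, 1) * 50), shannonIndex(p))
  expect_error(shannonIndex(c(0, 0)), "all-zero")
  # cross-check against the community-ecology reference implementation
  set.seed(43)
  for (i in 1:5) {
    x <- stats::rpois(12, 20)
    expect_equal(shannonIndex(x), unname(vegan::diversity(x)))
  }
  # the uniform distribution maximizes H for any support size
  for (k in 2:10) {
    u <- shannonIndex(rep(1, k))
    for (i in 1:5) {
      w <- stats::rexp(k) + 1e-3
      expect_gte(u + 1e-12, shannonIndex(w))
    }
  }
})

test_that("Bray-Curtis matches the formula and its metric properties", {
  expect_identical(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(brayCurtis(c(5, 0), c(0, 3)), 1)
  expect_identical(brayCurtis(c(3, 0, 1), c(1, 2, 1)), 0.5)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(47)
  for (i in 1:30) {
    u <- stats::rexp(8); v <- stats::rexp(8)
    d <- brayCurtis(u, v)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_identical(d, brayCurtis(v, u))
    expect_identical(brayCurtis(u, u), 0)
    # agrees with the reference implementation
    expect_equal(d, as.numeric(vegan::vegdist(rbind(u, v))))
  }
})

test_that("NMDS embeds simple geometries with near-zero stress", {
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  fit <- suppressWarnings(nmdsOrdination(d3, k = 2, seed = 3L))
  expect_lt(fit$stress, 0.01)
  # points already Euclidean in 2-D are recovered
  set.seed(53)
  pts <- matrix(stats::rnorm(20), 10, 2)
  fit2 <- suppressWarnings(nmdsOrdination(stats::dist(pts), k = 2, seed = 5L))
  expect_lt(fit2$stress, 0.01)
  fit3 <- suppressWarnings(nmdsOrdination(stats::dist(pts), k = 2, seed = 5L))
  expect_identical(fit2$points, fit3$points)
  expect_error(nmdsOrdination(d3, k = 3), "at least k")
})

test_that("core membership needs two of three replicates", {
  counts <- rbind(
    famA = c(3, 1, 0, 2, 2, 2),   # CT: 2/3 -> present; RT: 3/3 -> present
    famB = c(1, 0, 0, 0, 4, 4),   # CT: 1/3 -> absent;  RT: 2/3 -> present
    famC = c(0, 0, 0, 0, 0, 1))   # CT absent; RT 1/3 absent
  colnames(counts) <- c("CT_0-10_P1", "CT_0-10_P2", "CT_0-10_P3",
                        "RT_0-10_P1", "RT_0-10_P2", "RT_0-10_P3")
  meta <- data.frame(
    sample = colnames(counts),
    tillage = rep(c("CT", "RT"), each = 3),
    depth = "0-10",
    plot = paste0(rep(c("CT", "RT"), each = 3), "_P", 1:3))
  cm <- coreMembership(counts, meta)
  expect_identical(cm$membership[cm$feature == "famA"], "both")
  expect_identical(cm$membership[cm$feature == "famB"], "RT_only")
  expect_identical(cm$membership[cm$feature == "famC"], "absent")
  # replicate counts other than 3 generalize to a strict majority
  expect_warning(cm2 <- coreMembership(counts[, -3], meta[-3, ]),
                 "majority")
  expect_identical(cm2$membership[cm2$feature == "famA"], "both")
})

test_that("BH adjustment matches the hand-computed step-up", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  set.seed(59)
  praw <- stats::runif(40)
  adj <- stats::p.adjust(praw, "BH")
  expect_true(all(adj >= praw))
  ord <- order(praw)
  expect_true(all(diff(adj[ord]) >= -1e-15))
})

test_that("split-plot tests find planted depth effects and report contrasts", {
  sim <- simulateStudyTable(nFeatures = 8, depthEffect = 3,
                            effectFeatures = 3, seed = 11L)
  res <- testEffects(sim$rel, sim$meta)
  tests <- res$tests
  expect_setequal(unique(tests$factor),
                  c("tillage", "depth", "interaction"))
  expect_true(all(tests$p_bh >= tests$p - 1e-12, na.rm = TRUE))
  dep <- tests[tests$factor == "depth", ]
  hit <- dep$feature[dep$p_bh < 0.05]
  expect_true(all(sim$effectFeatures %in% hit))
  # contrasts only for BH-surviving features; deep-layer shift loads the
  # 0-20 vs 20-50 contrast
  expect_setequal(unique(res$contrasts$feature), hit)
  c1 <- res$contrasts[res$contrasts$feature == sim$effectFeatures[1] &
                      res$contrasts$contrast == "0-20 vs 20-50", ]
  expect_lt(c1$estimate, 0)
  expect_lt(c1$p, 0.05)
})

test_that("REML and structured permutation tests agree on rejections", {
  sim <- simulateStudyTable(nFeatures = 24, depthEffect = 3,
                            effectFeatures = 8, seed = 21L)
  r1 <- testEffects(sim$rel, sim$meta, method = "reml")
  r2 <- testEffects(sim$rel, sim$meta, method = "permutation",
                    nPerm = 199L, seed = 31L)
  agree <- 0L; total <- 0L
  for (fac in c("tillage", "depth", "interaction")) {
    a <- r1$tests$p[r1$tests$factor == fac] < 0.05
    b <- r2$tests$p[r2$tests$factor == fac] < 0.05
    agree <- agree + sum(a == b); total <- total + length(a)
  }
  expect_gte(agree / total, 0.9)
})

test_that("unbalanced designs fall back to the permutation scheme", {
  sim <- simulateStudyTable(nFeatures = 3, seed = 41L)
  expect_warning(
    res <- testEffects(sim$rel[, -1], sim$meta[-1, ], nPerm = 49L),
    "unbalanced")
  expect_identical(nrow(res$tests), 9L)
})

test_that("abundance tables wire counts, totals and metadata together", {
  counts <- matrix(c(10, 20, 30, 40), 2, 2,
                   dimnames = list(c("f1", "f2"), c("s1", "s2")))
  meta <- data.frame(sample = c("s1", "s2"), tillage = "CT",
                     depth = "0-10", plot = "p1",
                     total_filtered = c(1000, 2000))
  se <- abundanceTable(counts, meta)
  rel <- SummarizedExperiment::assay(se, "relabund")
  expect_identical(rel["f1", "s1"], 1)
  expect_identical(rel["f2", "s2"], 2)
})
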