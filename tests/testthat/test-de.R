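test_that("the detection filter applies the stated boundary exactly", {
  n <- 300
  m <- rbind(boundary = c(rep(1L, 200), rep(0L, n - 200)),
             under    = c(rep(1L, 199), rep(0L, n - 199)),
             allzero  = rep(0L, n),
             rich     = rep(2L, n))
  colnames(m) <- sprintf("c%03d", 1:n)
  se <- SenescenceExperiment(m, rep("excitatory", n))
  kept <- rownames(filterGenes(se, minCount = 1, minCells = 200))
  expect_identical(kept, c("boundary", "rich"))

  # toy oracle at minCells = 2
  m2 <- toyCounts(5, 6, seed = 9, lambda = 0.8)
  se2 <- SenescenceExperiment(m2, rep("excitatory", 6))
  kept2 <- rownames(filterGenes(se2, minCount = 1, minCells = 2))
  expect_identical(kept2, rownames(m2)[rowSums(m2 >= 1) >= 2])
  expect_error(filterGenes(se2, minCount = 100, minCells = 6), "all genes")
})

test_that("log CPM matches direct arithmetic and rejects empty cells", {
  m <- matrix(c(0L, 1000000L, 10L, 990L), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  lc <- logCPM(m)
  expect_equal(lc["g1", "c1"], 0)                       # log2(0 + 1)
  m2 <- matrix(c(1L, 999999L, 10L, 990L), 2, 2,
               dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_equal(logCPM(m2)["g1", "c1"], 1)               # total 1e6, count 1
  expect_equal(logCPM(m2)["g1", "c2"], log2(10 * 1e6 / 1000 + 1))  # 13.2879
  m3 <- m2; m3[, 2] <- 0L
  expect_error(logCPM(m3), "zero total")
})

test_that("upsampling replicates the minority class by the rounded ratio", {
  lab <- rep(c("senescent", "non_senescent"), c(475, 16871))
  idx <- upsampleIndices(lab)
  expect_identical(max(tabulate(idx)), 36L)             # round(16871/475)
  expect_identical(sum(tabulate(idx) == 36L), 475L)
  expect_identical(upsampleIndices(rep(c("a", "b"), 5)), 1:10)
  idx2 <- upsampleIndices(rep(c("s", "n"), c(3, 10)))
  expect_identical(max(tabulate(idx2)), 3L)             # round(10/3)
  expect_error(upsampleIndices(rep("a", 5)), "two nonempty")
})

test_that("hurdle statistic is null on identical groups and exact on pure separation", {
  x <- matrix(rnorm(40, 5), 2, 20)
  x[x < 0] <- 0
  expr <- cbind(x, x)
  rownames(expr) <- c("g1", "g2")
  lab <- rep(c("senescent", "non_senescent"), each = 20)
  tab <- hurdleTest(expr, lab, upsample = FALSE)
  expect_lt(max(tab$stat), 1e-8)
  expect_true(all(tab$p > 0.999))
  expect_equal(tab$log2fc, c(0, 0), tolerance = 1e-12)

  # 20 all-zero vs 20 all-positive: discrete LRT is -2 * 40 * ln(0.5),
  # continuous part skipped (one group has no positive cells)
  expr2 <- matrix(c(rep(0, 20), rep(5, 20)), 1, 40,
                  dimnames = list("g", NULL))
  lab2 <- rep(c("non_senescent", "senescent"), each = 20)
  tab2 <- hurdleTest(expr2, lab2, upsample = FALSE)
  expect_equal(tab2$stat, -2 * 40 * log(0.5), tolerance = 1e-9)
  expect_identical(tab2$df, 1)
})

test_that("hurdle parts match independent glm/lm likelihood-ratio fits", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 30
    lab <- sample(rep(c("senescent", "non_senescent"), c(12, 18)))
    x <- rpois(n, 1.5) * round(runif(n), 2) * 4
    expr <- matrix(x, 1, n, dimnames = list("g", NULL))
    tab <- hurdleTest(expr, lab, upsample = FALSE)
    det <- as.numeric(x > 0)
    grp <- as.numeric(lab == "senescent")
    g0 <- glm(det ~ 1, family = binomial)
    g1 <- glm(det ~ grp, family = binomial)
    G <- g0$deviance - g1$deviance
    pos <- x > 0
    statC <- 0; dfC <- 0
    if (sum(pos & grp == 1) >= 2 && sum(pos & grp == 0) >= 2) {
      rss1 <- sum(resid(lm(x[pos] ~ grp[pos]))^2)
      rss0 <- sum(resid(lm(x[pos] ~ 1))^2)
      statC <- sum(pos) * log(rss0 / rss1)
      dfC <- 1
    }
    expect_equal(tab$stat, G + statC, tolerance = 1e-6)
    expect_identical(tab$df, 1 + dfC)
    expect_equal(tab$p, pchisq(G + statC, 1 + dfC, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("hurdle type-I error is calibrated on null data", {
  cfg <- syntheticConfig(nCells = 240, senescentFraction = 0.5, nGenes = 900,
                         panelSizes = c(A = 8, B = 10, C = 15), nDeGenes = 30)
  sim <- simulateNullDataset(cfg, seed = 5)
  sef <- filterGenes(sim$experiment, minCount = 1, minCells = 4)
  tab <- hurdleTest(logCPM(sef), sim$truth$status)
  expect_gt(mean(tab$p < 0.05), 0.03)
  expect_lt(mean(tab$p < 0.05), 0.07)
})

test_that("EMD handles degenerate and point-mass cases", {
  lab <- rep(c("senescent", "non_senescent"), each = 30)
  exprConst <- matrix(1, 1, 60, dimnames = list("g", NULL))
  tabC <- emdTest(exprConst, lab, nBins = 5, nPerm = 99, seed = 1)
  expect_equal(tabC$emd, 0)
  expect_equal(tabC$p, 1)

  # group masses in the first and last of 5 bins: transport cost 4 bins
  expr <- matrix(c(rep(0, 30), rep(5, 30)), 1, 60, dimnames = list("g", NULL))
  tab <- emdTest(expr, lab, nBins = 5, nPerm = 99, seed = 1)
  expect_equal(tab$emd, 4)
})

test_that("EMD equals the transport oracle on random binned instances", {
  set.seed(31)
  for (i in 1:60) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    nBins <- sample(3:12, 1)
    x <- c(rnorm(n1, sample(0:2, 1)), rnorm(n0))
    lab <- rep(c("senescent", "non_senescent"), c(n1, n0))
    expr <- matrix(x, 1, n1 + n0, dimnames = list("g", NULL))
    tab <- emdTest(expr, lab, nBins = nBins, nPerm = 99, seed = i)
    breaks <- seq(min(x), max(x), length.out = nBins + 1)
    idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    h1 <- tabulate(idx[seq_len(n1)], nBins)
    h0 <- tabulate(idx[n1 + seq_len(n0)], nBins)
    expect_lt(abs(tab$emd - greedyEmd(h1, h0)), 1e-12)
  }
})

test_that("small-sample permutation p equals exhaustive enumeration", {
  set.seed(41)
  for (i in 1:10) {
    x <- round(rnorm(6), 2)
    lab <- rep(c("senescent", "non_senescent"), each = 3)
    expr <- matrix(x, 1, 6, dimnames = list("g", NULL))
    tab <- emdTest(expr, lab, nBins = 4, nPerm = 999, seed = i)
    breaks <- seq(min(x), max(x), length.out = 5)
    idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    sets <- combn(6, 3)
    stats <- apply(sets, 2, function(ix) {
      h1 <- tabulate(idx[ix], 4); h0 <- tabulate(idx[-ix], 4)
      sum(abs(cumsum(h1 / 3 - h0 / 3)))
    })
    obs <- stats[1]                      # first combination is 1,2,3
    expect_lt(abs(tab$p - mean(stats >= obs - 1e-12)), 1e-12)
  }
})

test_that("planted DE genes come out positive and the intersection test is exact", {
  cfg <- smallConfig(senescentFraction = 0.1)
  sim <- simulateDataset(cfg, seed = 6)
  sef <- filterGenes(sim$experiment, minCount = 1, minCells = 4)
  expr <- logCPM(sef)
  tab <- hurdleTest(expr, sim$truth$status)
  planted <- intersect(sim$truth$deGenes, tab$gene)
  expect_gt(length(planted), 20)
  expect_gte(mean(tab$log2fc[tab$gene %in% planted] > 0), 0.99)

  mk <- function(genes, sig) data.frame(gene = genes, significant = genes %in% sig)
  universe <- letters[1:10]
  res <- intersectDE(mk(universe, c("a", "b", "c")), mk(universe, c("b", "c", "d")))
  expect_setequal(res$genes, c("b", "c"))
  expect_equal(res$p, 22 / 120, tolerance = 1e-12)
  resDisj <- intersectDE(mk(universe, c("a", "b")), mk(universe, c("c", "d")))
  expect_equal(resDisj$p, 1)
  expect_error(intersectDE(mk(universe, "a"), mk(letters[2:11], "b")),
               "same gene universe")
})

test_that("Benjamini-Hochberg adjustment in DE tables is the step-up procedure", {
  expr <- matrix(rep(c(0, 4), each = 6), 3, 4, byrow = TRUE,
                 dimnames = list(paste0("g", 1:3), NULL))
  # check the padj columns follow p.adjust on the worked list via direct call
  p <- c(0.01, 0.02, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.03, 0.03, 0.04), tolerance = 1e-12)
  # and that DE tables expose BH-adjusted p monotone in p rank
  sim <- simulateDataset(smallConfig(), seed = 8)
  sef <- filterGenes(sim$experiment, minCount = 1, minCells = 4)
  tab <- hurdleTest(logCPM(sef)[1:50, ], sim$truth$status)
  o <- order(tab$p)
  expect_true(all(diff(tab$padj[o]) >= -1e-12))
  expect_true(all(tab$padj >= tab$p - 1e-12))
})
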