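test_that("binarization is an idempotent indicator of detection", {
  m <- matrix(c(0L, 1L, 5L, 2L, 0L, 7L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  se <- SenescenceExperiment(m, c("excitatory", "excitatory"))
  b <- binarizeCounts(se)
  bm <- as.matrix(SummarizedExperiment::assay(b))
  expect_equal(unname(bm[, 1]), c(0, 1, 1))
  expect_equal(as.matrix(SummarizedExperiment::assay(binarizeCounts(b))), bm)
  expect_equal(colSums(bm), colSums(m > 0))
})

test_that("a perfectly separating binary gene yields a one-split tree", {
  m <- rbind(marker = c(rep(1L, 10), rep(0L, 30)),
             noise = rep(c(0L, 1L), 20))
  colnames(m) <- sprintf("c%02d", 1:40)
  lab <- rep(c("senescent", "non_senescent"), c(10, 30))
  tree <- fitMarkerTree(m, lab, mode = "binary")
  expect_identical(treeGenes(tree), "marker")
  met <- evaluateMetrics(predictTree(tree, m), lab)
  expect_equal(met$accuracy, 1)
})

test_that("gain ratio, not raw gain, picks the root split", {
  # 8 cases, 4 senescent. geneA splits 4|4 with IG = 0.1887, split info 1,
  # gain ratio 0.1887. geneB isolates one senescent case: IG = 0.1379,
  # split info 0.5436, gain ratio 0.2537. Gain ratio prefers geneB.
  m <- rbind(geneA = c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L),
             geneB = c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  colnames(m) <- paste0("c", 1:8)
  lab <- rep(c("senescent", "non_senescent"), each = 4)
  tree <- fitMarkerTree(m, lab, mode = "binary", minCases = 1, maxDepth = 1)
  expect_identical(tree@nodes$gene[1], "geneB")
})

test_that("deterministic tie-breaking prefers earlier pool genes", {
  m <- rbind(g1 = c(1L, 1L, 0L, 0L), g2 = c(1L, 1L, 0L, 0L))
  colnames(m) <- paste0("c", 1:4)
  lab <- rep(c("senescent", "non_senescent"), each = 2)
  tree <- fitMarkerTree(m, lab, mode = "binary", minCases = 1)
  expect_identical(treeGenes(tree), "g1")
  treeRev <- fitMarkerTree(m, lab, genePool = c("g2", "g1"),
                           mode = "binary", minCases = 1)
  expect_identical(treeGenes(treeRev), "g2")
})

test_that("excessive minCases forces the majority-class leaf", {
  m <- rbind(marker = c(rep(1L, 10), rep(0L, 30)))
  colnames(m) <- sprintf("c%02d", 1:40)
  lab <- rep(c("senescent", "non_senescent"), c(10, 30))
  tree <- fitMarkerTree(m, lab, mode = "binary", minCases = 25,
                        upsample = FALSE)
  expect_length(treeGenes(tree), 0)
  met <- evaluateMetrics(predictTree(tree, m), lab)
  expect_equal(met$sensitivity, 0)
})

test_that("the fitted pair matches the exhaustive best-pair oracle", {
  set.seed(17)
  nSen <- 40; nNon <- 400
  lab <- rep(c("senescent", "non_senescent"), c(nSen, nNon))
  n <- nSen + nNon
  mkGene <- function(pOn, pOff) {
    c(rbinom(nSen, 1, pOn), rbinom(nNon, 1, pOff))
  }
  # background positivity of 5% makes a single marker insufficient, so the
  # conjunction of the two planted genes is genuinely needed
  m <- rbind(a1 = mkGene(0.9, 0.05), a2 = mkGene(0.85, 0.05),
             w1 = mkGene(0.5, 0.2), w2 = mkGene(0.4, 0.25),
             n1 = mkGene(0.05, 0.05), n2 = mkGene(0.1, 0.1))
  m <- matrix(as.integer(m), nrow(m), dimnames = list(rownames(m), paste0("c", 1:n)))
  tree <- fitMarkerTree(m, lab, mode = "binary")
  # oracle: exhaustive search over all gene pairs and conjunctive rules
  pairs <- combn(rownames(m), 2)
  accs <- apply(pairs, 2, function(pr) {
    pred <- ifelse(m[pr[1], ] > 0 & m[pr[2], ] > 0, "senescent", "non_senescent")
    mean(pred == lab)
  })
  bestPair <- pairs[, which.max(accs)]
  expect_setequal(treeGenes(tree), bestPair)
})

test_that("predictions are routed deterministically and replay training exactly", {
  sim <- simulateDataset(smallConfig(senescentFraction = 0.05), seed = 12)
  pool <- c(unlist(sim$truth$panels), sim$truth$markerGenes)
  tree <- fitMarkerTree(sim$experiment, sim$truth$status, genePool = pool,
                        mode = "binary")
  pred <- predictTree(tree, sim$experiment)
  predAgain <- predictTree(tree, sim$experiment)
  expect_identical(pred, predAgain)
  # invariant to adding unrelated genes: predictions depend only on tree genes
  sub <- sim$experiment[c(treeGenes(tree), sample(rownames(sim$experiment), 5)), ]
  expect_identical(unname(predictTree(tree, sub)), unname(pred))
  expect_error(predictTree(tree, sim$experiment[setdiff(rownames(sim$experiment),
                                                        treeGenes(tree)[1]), ]),
               "missing")
  # simple threshold semantics: count above 0 routes to the right branch
  m <- rbind(geneX = c(3L, 0L))
  colnames(m) <- c("cA", "cB")
  tr2 <- fitMarkerTree(rbind(geneX = c(rep(1L, 5), rep(0L, 5))),
                       rep(c("senescent", "non_senescent"), each = 5),
                       mode = "binary", minCases = 1)
  expect_identical(unname(predictTree(tr2, m)), c("senescent", "non_senescent"))
})

test_that("metric arithmetic and degenerate truth handling are correct", {
  pred <- rep(c("senescent", "non_senescent"), c(83, 917))
  truth <- rep(c("senescent", "non_senescent"), c(100, 900))
  met <- evaluateMetrics(pred, truth)
  expect_equal(met$tp, 83); expect_equal(met$fn, 17)
  expect_equal(met$tn, 900); expect_equal(met$fp, 0)
  expect_equal(met$sensitivity, 0.83)
  expect_equal(met$specificity, 1.0)
  expect_equal(met$accuracy, 0.983)
  expect_warning(m2 <- evaluateMetrics(rep("non_senescent", 5),
                                       rep("non_senescent", 5)),
                 "sensitivity undefined")
  expect_true(is.na(m2$sensitivity))
  # borderline cells never enter the denominators
  met3 <- evaluateMetrics(c(pred, "senescent"), c(truth, "borderline"))
  expect_equal(met3$accuracy, 0.983)
})

test_that("random predictions on balanced labels sit near 50% accuracy", {
  set.seed(23)
  truth <- rep(c("senescent", "non_senescent"), each = 500)
  acc <- mean(vapply(1:10, function(i) {
    evaluateMetrics(sample(truth), truth)$accuracy
  }, 1))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("raising minCases never increases the number of distinct genes", {
  sim <- simulateDataset(smallConfig(senescentFraction = 0.05), seed = 13)
  pool <- c(unlist(sim$truth$panels), sim$truth$markerGenes)
  sizes <- vapply(c(1, 4, 16, 64, 256), function(mc) {
    length(treeGenes(fitMarkerTree(sim$experiment, sim$truth$status,
                                   genePool = pool, minCases = mc,
                                   mode = "binary")))
  }, 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("elimination rounds pick planted pairs in decreasing quality order", {
  set.seed(19)
  nSen <- 50; nNon <- 450
  lab <- rep(c("senescent", "non_senescent"), c(nSen, nNon))
  mkGene <- function(pOn, pOff) {
    as.integer(c(rbinom(nSen, 1, pOn), rbinom(nNon, 1, pOff)))
  }
  m <- rbind(s1 = mkGene(0.97, 0.04), s2 = mkGene(0.96, 0.04),
             w1 = mkGene(0.75, 0.06), w2 = mkGene(0.7, 0.06),
             b1 = mkGene(0.1, 0.08))
  colnames(m) <- paste0("c", 1:500)
  mv <- rbind(s1 = mkGene(0.97, 0.04), s2 = mkGene(0.96, 0.04),
              w1 = mkGene(0.75, 0.06), w2 = mkGene(0.7, 0.06),
              b1 = mkGene(0.1, 0.08))
  colnames(mv) <- paste0("v", 1:500)
  ledger <- eliminationAnalysis(m, lab, genePool = rownames(m),
                                validationSets = list(val = list(
                                  features = mv, labels = lab)),
                                maxRounds = 3, mode = "binary")
  expect_setequal(strsplit(ledger$selected[1], ",")[[1]], c("s1", "s2"))
  expect_setequal(strsplit(ledger$selected[2], ",")[[1]], c("w1", "w2"))
  expect_true(all(ledger$sensitivity_val[-1] <= ledger$sensitivity_val[1]))
  # round 1 with no exclusions is identical to a plain fit on the full pool
  tree1 <- fitMarkerTree(m, lab, genePool = rownames(m), mode = "binary")
  expect_setequal(strsplit(ledger$selected[1], ",")[[1]], treeGenes(tree1))
})
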