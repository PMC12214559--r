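#' Filter genes by minimum detection
#'
#' Keeps gene g iff its count is at least \code{minCount} in at least
#' \code{minCells} cells, preserving gene order. The defaults (expression
#' of at least 1 in at least 200 neurons) match the pre-filter of the
#' differential-expression analysis at discovery scale.
#'
#' @param x a \linkS4class{SenescenceExperiment}.
#' @param minCount minimum count for a cell to count as detected.
#' @param minCells minimum number of detected cells.
#' @return The filtered \linkS4class{SenescenceExperiment}.
#' @export
filterGenes <- function(x, minCount = 1, minCells = 200) {
  stopifnot(minCount >= 0, minCells >= 0)
  m <- SummarizedExperiment::assay(x, "counts")
  nDetected <- Matrix::rowSums(m >= minCount)
  keep <- nDetected >= minCells
  if (!any(keep)) stop("all genes removed by the detection filter")
  x[keep, ]
}

#' Upsampling index multiset for imbalanced groups
#'
#' Replicates each cell of the minority class r times, where
#' r = round(n_majority / n_minority) (at least 1), and keeps majority
#' cells once, so the two classes appear roughly equal downstream. At the
#' discovery scale of 475 senescent vs 16,871 non-senescent neurons this
#' gives r = 36.
#'
#' @param labels two-class vector (character/factor/logical).
#' @return Integer vector of cell indices, with minority indices repeated.
#' @export
upsampleIndices <- function(labels) {
  tab <- table(as.character(labels))
  if (length(tab) != 2 || any(tab == 0)) {
    stop("labels must contain exactly two nonempty classes")
  }
  minority <- names(tab)[which.min(tab)]
  r <- max(1, round(max(tab) / min(tab)))
  reps <- ifelse(as.character(labels) == minority, r, 1L)
  rep(seq_along(labels), reps)
}

# replication weight per original cell implied by upsampleIndices
.upsampleWeights <- function(labels, upsample) {
  if (!upsample) return(rep(1, length(labels)))
  tabulate(upsampleIndices(labels), nbins = length(labels))
}

.xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

#' Two-part hurdle differential-expression test
#'
#' For each gene, jointly models the rate of expression (discrete part: a
#' 1-df binomial likelihood-ratio G-test comparing group detection
#' proportions against the pooled proportion) and the positive mean
#' expression (continuous part: a 1-df Gaussian likelihood-ratio statistic
#' n * ln(RSS0/RSS1) over cells with positive expression, computed only
#' when each group has at least 2 positive cells). The two statistics are
#' summed and referred to a chi-square with the summed degrees of freedom.
#' log2 fold change is the difference of group means over all cells
#' (positive = higher in the \code{positiveClass} group). With
#' \code{upsample = TRUE} (default) the minority class is weighted by the
#' replication factor of \code{\link{upsampleIndices}} before testing.
#'
#' @param expr genes x cells matrix of log2 CPM values on filtered genes
#'   (see \code{\link{logCPM}}, \code{\link{filterGenes}}).
#' @param labels two-class vector over cells.
#' @param positiveClass label treated as the senescent/"high" group.
#' @param fdr adjusted-p cut for significance (default 0.01).
#' @param lfcMin minimum |log2 fold change| for significance (default 6).
#' @param upsample replicate the minority class as in
#'   \code{\link{upsampleIndices}}.
#' @return data.frame with columns \code{gene}, \code{log2fc},
#'   \code{stat}, \code{df}, \code{p}, \code{padj}, \code{significant},
#'   \code{degenerate} (no detected cells), \code{method}.
#' @export
hurdleTest <- function(expr, labels, positiveClass = "senescent",
                       fdr = 0.01, lfcMin = 6, upsample = TRUE) {
  labels <- as.character(labels)
  if (ncol(expr) != length(labels)) stop("labels must match expr columns")
  if (!positiveClass %in% labels) {
    stop("positiveClass '", positiveClass, "' not present in labels")
  }
  w <- .upsampleWeights(labels, upsample)
  g1 <- labels == positiveClass
  w1 <- w * g1
  w0 <- w * !g1
  n1 <- sum(w1); n0 <- sum(w0)

  D <- expr > 0
  k1 <- as.numeric(D %*% w1)
  k0 <- as.numeric(D %*% w0)

  llBin <- function(k, n) .xlogy(k, k / n) + .xlogy(n - k, 1 - k / n)
  G <- 2 * (llBin(k1, n1) + llBin(k0, n0) - llBin(k1 + k0, n1 + n0))

  # continuous part on positive-expression cells, weighted
  EP <- expr * D
  S1 <- as.numeric(EP %*% w1); S0 <- as.numeric(EP %*% w0)
  Q1 <- as.numeric((EP * expr) %*% w1); Q0 <- as.numeric((EP * expr) %*% w0)
  rssPart <- function(Q, S, m) ifelse(m > 0, Q - S^2 / m, 0)
  RSS1 <- rssPart(Q1, S1, k1) + rssPart(Q0, S0, k0)
  RSS0 <- rssPart(Q1 + Q0, S1 + S0, k1 + k0)
  c1 <- as.numeric(D[, g1, drop = FALSE] %*% rep(1, sum(g1)))
  c0 <- as.numeric(D[, !g1, drop = FALSE] %*% rep(1, sum(!g1)))
  contOK <- c1 >= 2 & c0 >= 2 & RSS0 > 1e-12
  statC <- ifelse(contOK,
                  (k1 + k0) * log(RSS0 / pmax(RSS1, 1e-12)), 0)
  statC <- pmax(statC, 0)

  stat <- G + statC
  df <- 1 + as.numeric(contOK)
  degenerate <- (k1 + k0) == 0
  p <- pchisq(stat, df, lower.tail = FALSE)
  p[degenerate] <- 1
  stat[degenerate] <- 0

  lfc <- as.numeric(expr %*% w1) / n1 - as.numeric(expr %*% w0) / n0
  lfc[degenerate] <- 0
  padj <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(expr), log2fc = lfc, stat = stat, df = df,
             p = p, padj = padj,
             significant = padj < fdr & abs(lfc) > lfcMin,
             degenerate = degenerate,
             method = "hurdle", row.names = NULL, stringsAsFactors = FALSE)
}

# EMD between two groups of binned values: L1 distance between the
# normalized histogram CDFs, in bin units.
.emdBinned <- function(binIdx, inG1, nBins) {
  c1 <- tabulate(binIdx[inG1], nBins)
  c0 <- tabulate(binIdx[!inG1], nBins)
  sum(abs(cumsum(c1 / sum(c1) - c0 / sum(c0))))
}

#' Earth Mover's Distance permutation test
#'
#' For each gene, the two group distributions are histogrammed on
#' \code{nBins} equal-width bins spanning the pooled range, and the EMD is
#' the L1 distance between the two histogram CDFs in bin units (the 1-D
#' equal-mass optimal-transport cost). Significance comes from permuting
#' group labels at the level of original cells: exhaustively when the
#' number of distinct assignments is at most \code{nPerm} (the p-value is
#' then the exact enumeration fraction), otherwise by \code{nPerm} Monte
#' Carlo draws with p = (b + 1) / (nPerm + 1). Class upsampling by
#' replication leaves each group's empirical distribution (hence the EMD)
#' unchanged, so the statistic is computed directly on the original cells.
#'
#' @inheritParams hurdleTest
#' @param nBins number of histogram bins (default 100).
#' @param nPerm number of permutations (at least 99; default 999).
#' @param seed integer seed for the permutation draws.
#' @param emdMin minimum EMD for significance (default 30).
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{emd},
#'   \code{p}, \code{padj}, \code{significant}, \code{method}.
#' @export
emdTest <- function(expr, labels, positiveClass = "senescent",
                    nBins = 100, nPerm = 999, seed = 1,
                    fdr = 0.01, emdMin = 30) {
  labels <- as.character(labels)
  if (ncol(expr) != length(labels)) stop("labels must match expr columns")
  if (nPerm < 99) stop("nPerm must be at least 99")
  g1 <- labels == positiveClass
  if (!any(g1) || all(g1)) stop("both groups must be nonempty")
  n <- length(labels)
  n1 <- sum(g1)
  exact <- choose(n, n1) <= nPerm
  if (exact) {
    assignments <- combn(n, n1)
  }
  set.seed(seed)
  permSets <- if (exact) {
    lapply(seq_len(ncol(assignments)), function(j) assignments[, j])
  } else {
    lapply(seq_len(nPerm), function(j) sample.int(n, n1))
  }

  emd <- numeric(nrow(expr))
  p <- numeric(nrow(expr))
  for (g in seq_len(nrow(expr))) {
    x <- expr[g, ]
    rng <- range(x)
    if (rng[1] == rng[2]) {
      emd[g] <- 0; p[g] <- 1
      next
    }
    breaks <- seq(rng[1], rng[2], length.out = nBins + 1)
    idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    obs <- .emdBinned(idx, g1, nBins)
    permStats <- vapply(permSets, function(ix) {
      sel <- logical(n); sel[ix] <- TRUE
      .emdBinned(idx, sel, nBins)
    }, 1)
    b <- sum(permStats >= obs - 1e-12)
    emd[g] <- obs
    p[g] <- if (exact) b / length(permStats) else (b + 1) / (nPerm + 1)
  }
  lfc <- rowMeans(expr[, g1, drop = FALSE]) -
    rowMeans(expr[, !g1, drop = FALSE])
  padj <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(expr), log2fc = lfc, emd = emd, p = p,
             padj = padj, significant = padj < fdr & emd > emdMin,
             method = "emd", row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect the significant genes of the two DE methods
#'
#' Returns the genes called significant by both tests and the upper-tail
#' hypergeometric probability of an overlap at least this large when two
#' sets of the observed sizes are drawn at random from the shared gene
#' universe (computed in log space, so extreme significance is resolved).
#'
#' @param hurdleTable,emdTable outputs of \code{\link{hurdleTest}} and
#'   \code{\link{emdTest}} over the same gene universe.
#' @param universeSize background size; defaults to the number of tested
#'   genes.
#' @return List with \code{genes}, \code{overlap}, \code{nHurdle},
#'   \code{nEmd}, \code{universeSize}, \code{p}, \code{log10p}.
#' @export
intersectDE <- function(hurdleTable, emdTable, universeSize = NULL) {
  if (!setequal(hurdleTable$gene, emdTable$gene) ||
      nrow(hurdleTable) != nrow(emdTable)) {
    stop("the two DE tables must cover the same gene universe")
  }
  if (is.null(universeSize)) universeSize <- nrow(hurdleTable)
  sigH <- hurdleTable$gene[hurdleTable$significant]
  sigE <- emdTable$gene[emdTable$significant]
  inter <- intersect(sigH, sigE)
  ht <- hypergeomUpperTail(length(inter), length(sigH), length(sigE),
                           universeSize)
  list(genes = inter, overlap = length(inter),
       nHurdle = length(sigH), nEmd = length(sigE),
       universeSize = universeSize, p = ht$p, log10p = ht$log10p)
}
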