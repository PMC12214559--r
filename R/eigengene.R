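#' Cell-type balancing weights
#'
#' Each cell is weighted by the total number of cells divided by the count
#' of its cell type, so rarer types receive larger weights and every type
#' contributes equitably to the weighted PCA. The minimum weight is 1
#' (attained only when all cells share one type).
#'
#' @param cellTypes character/factor vector of cell-type labels.
#' @return Named numeric vector of per-cell weights.
#' @examples
#' balanceWeights(rep(c("excitatory", "inhibitory"), c(8, 2)))
#' @export
balanceWeights <- function(cellTypes) {
  if (!length(cellTypes)) stop("cellTypes must be nonempty")
  cellTypes <- as.character(cellTypes)
  tab <- table(cellTypes)
  w <- length(cellTypes) / as.numeric(tab[cellTypes])
  names(w) <- names(cellTypes)
  w
}

#' Log2 counts-per-million expression
#'
#' Normalizes each cell's counts to a library size of one million and
#' transforms to log2 with a pseudocount of 1:
#' \code{log2(1e6 * count / cellTotal + 1)}.
#'
#' @param x a \linkS4class{SenescenceExperiment} or a genes x cells count
#'   matrix.
#' @param genes optional gene ids to return (totals are always computed
#'   from all genes).
#' @return Dense numeric matrix of log2 CPM values (rows \code{genes} if
#'   given, else all genes).
#' @export
logCPM <- function(x, genes = NULL) {
  m <- if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else x
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    bad <- colnames(m)[totals == 0]
    stop("cell(s) with zero total count: ", paste(head(bad, 5), collapse = ", "))
  }
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  d <- as.matrix(m)
  log2(sweep(d, 2, totals / 1e6, "/") + 1)
}

.expressionMatrix <- function(x, genes, scale) {
  if (scale == "log_cpm") {
    logCPM(x, genes)
  } else {
    m <- if (methods::is(x, "SummarizedExperiment")) {
      SummarizedExperiment::assay(x, "counts")
    } else x
    as.matrix(m[genes, , drop = FALSE])
  }
}

#' Fit a cell-type-balanced weighted-PCA eigengene
#'
#' The eigengene of a gene panel is the first principal component of the
#' panel's expression: a weighted average of member-gene expression whose
#' gene weights (loadings) are learned by PCA. To keep abundant cell types
#' from dominating, each gene is standardized with weighted mean/sd using
#' \code{\link{balanceWeights}}, each cell's standardized profile is scaled
#' by the square root of its weight, and the leading right-singular vector
#' of that matrix gives the loadings (equivalently, the leading eigenvector
#' of the weighted covariance matrix). The reported per-cell discovery
#' scores are projections of the \emph{unweighted} standardized data on the
#' loadings; the weights shape the component, not the scores. The score
#' orientation is chosen so that scores correlate non-negatively with
#' member-gene expression on average. The model records the score mean,
#' s.d., and the \code{mu + 3 sd} overexpression threshold used by
#' \code{\link{panelStatus}}.
#'
#' @param x a \linkS4class{SenescenceExperiment}.
#' @param panel character vector of panel gene ids (genes absent from
#'   \code{x} are dropped with a message).
#' @param panelName name stored on the model.
#' @param weights per-cell weights; defaults to
#'   \code{balanceWeights(cellType(x))}.
#' @param expressionScale \code{"log_cpm"} (default) or \code{"raw"}.
#' @param thresholdMultiplier multiplier of sigma in the overexpression
#'   threshold (default 3).
#' @return An \linkS4class{EigengeneModel}.
#' @export
fitEigengene <- function(x, panel, panelName = "panel",
                         weights = NULL,
                         expressionScale = c("log_cpm", "raw"),
                         thresholdMultiplier = 3) {
  expressionScale <- match.arg(expressionScale)
  if (is.null(weights)) weights <- unname(balanceWeights(cellType(x)))
  present <- intersect(panel, rownames(x))
  if (length(present) < length(panel)) {
    message(length(panel) - length(present), " of ", length(panel),
            " panel genes absent from '", datasetTag(x), "' and dropped")
  }
  if (length(present) < 2) {
    stop("fewer than 2 panel genes present; missing: ",
         paste(setdiff(panel, rownames(x)), collapse = ", "))
  }
  if (ncol(x) < 3) stop("need at least 3 cells")
  E <- .expressionMatrix(x, present, expressionScale)   # genes x cells
  X <- t(E)                                             # cells x genes
  w <- as.numeric(weights)
  if (length(w) != nrow(X)) stop("weights must have one entry per cell")
  sw <- sum(w)
  ctr <- colSums(X * w) / sw
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(colSums(Xc^2 * w) / sw)
  zero <- scl <= 1e-12
  if (any(zero)) {
    warning("dropping zero-variance gene(s): ",
            paste(present[zero], collapse = ", "))
    present <- present[!zero]
    if (length(present) < 2) stop("fewer than 2 usable panel genes remain")
    Xc <- Xc[, !zero, drop = FALSE]
    ctr <- ctr[!zero]
    scl <- scl[!zero]
  }
  Xs <- sweep(Xc, 2, scl, "/")
  v <- svd(Xs * sqrt(w), nu = 0, nv = 1)$v[, 1]
  rawScores <- as.numeric(Xs %*% v)
  orient <- mean(suppressWarnings(cor(rawScores, t(E[present, , drop = FALSE]))),
                 na.rm = TRUE)
  s <- if (orient < 0) -1 else 1
  scores <- s * rawScores
  names(scores) <- colnames(x)
  mu <- mean(scores)
  sigma <- sd(scores)
  methods::new("EigengeneModel",
    panelName = panelName,
    memberGenes = present,
    loadings = v / sqrt(sum(v^2)),
    geneCenters = setNames(ctr, present),
    geneScales = setNames(scl, present),
    orientationSign = s,
    discoveryScores = scores,
    scoreNorm = sqrt(sum(scores^2)),
    mu = mu,
    sigma = sigma,
    thresholdHigh = mu + thresholdMultiplier * sigma,
    thresholdMultiplier = thresholdMultiplier,
    expressionScale = expressionScale)
}

#' Project a fitted eigengene onto another dataset
#'
#' Validation expression is standardized with the \emph{discovery} centers
#' and scales, projected on the learned loadings over the genes available
#' in the validation data (missing genes are reported), and the resulting
#' score vector is rescaled to have the same Euclidean norm as the
#' discovery eigengene. Projecting a model onto its own discovery data
#' reproduces the discovery scores.
#'
#' @param model an \linkS4class{EigengeneModel}.
#' @param x a \linkS4class{SenescenceExperiment}.
#' @return Named numeric vector of per-cell eigengene scores.
#' @export
projectEigengene <- function(model, x) {
  avail <- intersect(model@memberGenes, rownames(x))
  if (!length(avail)) stop("none of the model genes are present in '",
                           datasetTag(x), "'")
  if (length(avail) < length(model@memberGenes)) {
    warning(length(model@memberGenes) - length(avail),
            " model gene(s) missing from '", datasetTag(x),
            "'; projecting on the remaining ", length(avail))
  }
  E <- .expressionMatrix(x, avail, model@expressionScale)
  X <- t(E)
  Xs <- sweep(sweep(X, 2, model@geneCenters[avail]), 2,
              pmax(model@geneScales[avail], 1e-12), "/")
  lv <- geneLoadings(model)[avail]
  raw <- as.numeric(Xs %*% lv)
  nrm <- sqrt(sum(raw^2))
  if (nrm == 0) stop("projected scores have zero norm; cannot normalize")
  scores <- raw * (model@scoreNorm / nrm)
  names(scores) <- colnames(x)
  scores
}

#' Correlation between the gene weights of two eigengene models
#'
#' Pearson correlation of the oriented loadings over the genes shared by
#' the two models; each model's own orientation sign is applied first, so
#' a model refitted with globally negated loadings still correlates +1.
#'
#' @param modelA,modelB \linkS4class{EigengeneModel} objects sharing at
#'   least 3 genes.
#' @return Correlation in [-1, 1].
#' @export
weightCorrelation <- function(modelA, modelB) {
  shared <- intersect(modelA@memberGenes, modelB@memberGenes)
  if (length(shared) < 3) {
    stop("models share only ", length(shared), " genes; need at least 3")
  }
  as.numeric(cor(geneLoadings(modelA)[shared], geneLoadings(modelB)[shared]))
}
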