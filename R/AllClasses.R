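#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor sd p.adjust pchisq phyper dhyper rnbinom rpois rbinom
#'   rlnorm runif quantile setNames predict
#' @importFrom utils read.delim write.table combn head
NULL

#' SenescenceExperiment: annotated single-nucleus count matrix
#'
#' The universal input container of the pipeline: a genes x cells matrix of
#' non-negative integer counts with one cell-type label per cell, carried as
#' a \linkS4class{SingleCellExperiment} with a mandatory \code{"counts"}
#' assay and a \code{cell_type} column in \code{colData}.
#'
#' Validity requires: a \code{"counts"} assay of non-negative integral
#' values; unique, non-empty gene and cell identifiers; exactly one
#' \code{cell_type} label per cell.
#'
#' @slot datasetTag free-text tag identifying the dataset (e.g. "discovery").
#'
#' @seealso \code{\link{SenescenceExperiment}} (constructor),
#'   \code{\link{readCountMatrix}}, \code{\link{simulateDataset}}
#' @name SenescenceExperiment-class
#' @rdname SenescenceExperiment-class
#' @exportClass SenescenceExperiment
setClass("SenescenceExperiment",
  contains = "SingleCellExperiment",
  slots = c(datasetTag = "character")
)

.validSenescenceExperiment <- function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'counts' is missing")
  }
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(object)) || is.null(colnames(object))) {
    msg <- c(msg, "gene and cell identifiers (dimnames) are required")
  } else {
    if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicated gene ids")
    if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicated cell ids")
  }
  x <- if (methods::is(m, "sparseMatrix")) m@x else m
  if (length(x)) {
    if (anyNA(x)) {
      msg <- c(msg, "counts must not contain NA")
    } else if (min(x) < 0) {
      msg <- c(msg, "counts must be non-negative")
    } else if (!is.integer(x) && any(x != floor(x))) {
      msg <- c(msg, "counts must be integral")
    }
  }
  if (!"cell_type" %in% colnames(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData must contain a 'cell_type' column")
  } else if (anyNA(object$cell_type)) {
    msg <- c(msg, "every cell needs exactly one cell_type label")
  }
  if (length(object@datasetTag) != 1L) {
    msg <- c(msg, "datasetTag must be a single string")
  }
  if (length(msg)) msg else TRUE
}

setValidity("SenescenceExperiment", .validSenescenceExperiment)

#' Construct a SenescenceExperiment
#'
#' @param counts genes x cells matrix (dense or \pkg{Matrix} sparse) of
#'   non-negative integer counts, with rownames (gene ids) and colnames
#'   (cell ids).
#' @param cellType character/factor vector of cell-type labels, one per cell.
#' @param datasetTag single string naming the dataset.
#' @return A validated \linkS4class{SenescenceExperiment}.
#' @examples
#' m <- matrix(rpois(12, 1), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' se <- SenescenceExperiment(m, rep(c("excitatory", "inhibitory"), 2))
#' @export
SenescenceExperiment <- function(counts, cellType, datasetTag = "unnamed") {
  if (length(cellType) != ncol(counts)) {
    stop("cellType must have one label per cell (", ncol(counts),
         " cells, ", length(cellType), " labels)")
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cell_type = as.character(cellType),
                                   row.names = colnames(counts))
  )
  methods::new("SenescenceExperiment", sce, datasetTag = datasetTag)
}

#' EigengeneModel: a fitted weighted-PCA panel eigengene
#'
#' Stores everything needed to score new cells against a senescence panel:
#' the per-gene loadings (the panel "weights"), the centering/scaling
#' constants of the discovery fit, the orientation sign, the discovery
#' scores with their Euclidean norm, and the labelling thresholds
#' (mean, s.d., mean + 3 s.d. of the discovery scores).
#'
#' @slot panelName panel identifier.
#' @slot memberGenes genes of the panel present in the discovery data, in
#'   fitting order.
#' @slot loadings raw unit-norm first-PC gene loadings (apply
#'   \code{orientationSign} to obtain the oriented weights returned by
#'   \code{\link{geneLoadings}}).
#' @slot geneCenters,geneScales weighted mean and s.d. used to standardize
#'   each gene at fit time.
#' @slot orientationSign +1/-1 such that oriented scores correlate
#'   non-negatively with member-gene expression on average.
#' @slot discoveryScores oriented per-cell eigengene values in the
#'   discovery dataset.
#' @slot scoreNorm Euclidean norm of \code{discoveryScores}.
#' @slot mu,sigma mean and s.d. of \code{discoveryScores}.
#' @slot thresholdHigh \code{mu + multiplier * sigma} (multiplier 3 by
#'   default), the overexpression cut.
#' @slot thresholdMultiplier the multiplier used for \code{thresholdHigh}.
#' @slot expressionScale \code{"log_cpm"} or \code{"raw"}; the expression
#'   transform the model was fitted on (projection reuses it).
#' @name EigengeneModel-class
#' @rdname EigengeneModel-class
#' @exportClass EigengeneModel
setClass("EigengeneModel", slots = c(
  panelName = "character",
  memberGenes = "character",
  loadings = "numeric",
  geneCenters = "numeric",
  geneScales = "numeric",
  orientationSign = "numeric",
  discoveryScores = "numeric",
  scoreNorm = "numeric",
  mu = "numeric",
  sigma = "numeric",
  thresholdHigh = "numeric",
  thresholdMultiplier = "numeric",
  expressionScale = "character"
))

setValidity("EigengeneModel", function(object) {
  msg <- character()
  p <- length(object@memberGenes)
  if (length(object@loadings) != p || length(object@geneCenters) != p ||
      length(object@geneScales) != p) {
    msg <- c(msg, "loadings/centers/scales must match memberGenes length")
  }
  if (abs(sqrt(sum(object@loadings^2)) - 1) > 1e-9) {
    msg <- c(msg, "loadings must have unit Euclidean norm")
  }
  if (any(object@geneScales <= 0)) msg <- c(msg, "geneScales must be > 0")
  if (!object@orientationSign %in% c(-1, 1)) {
    msg <- c(msg, "orientationSign must be +1 or -1")
  }
  if (abs(object@thresholdHigh -
          (object@mu + object@thresholdMultiplier * object@sigma)) > 1e-12) {
    msg <- c(msg, "thresholdHigh must equal mu + multiplier * sigma")
  }
  if (length(msg)) msg else TRUE
})

#' CellLabeling: per-panel and consensus senescence calls
#'
#' @slot cellIds cell identifiers.
#' @slot panelStatus cells x panels character matrix with entries
#'   \code{"pos"}, \code{"neg"}, \code{"borderline"}.
#' @slot consensus per-cell consensus label: \code{"senescent"} iff all
#'   panels pos, \code{"non_senescent"} iff all panels neg, otherwise
#'   \code{"borderline"} (excluded downstream).
#' @name CellLabeling-class
#' @rdname CellLabeling-class
#' @exportClass CellLabeling
setClass("CellLabeling", slots = c(
  cellIds = "character",
  panelStatus = "matrix",
  consensus = "character"
))

setValidity("CellLabeling", function(object) {
  msg <- character()
  n <- length(object@cellIds)
  if (nrow(object@panelStatus) != n || length(object@consensus) != n) {
    msg <- c(msg, "panelStatus rows and consensus must match cellIds")
  }
  if (!all(object@panelStatus %in% c("pos", "neg", "borderline"))) {
    msg <- c(msg, "panelStatus entries must be pos/neg/borderline")
  }
  if (!all(object@consensus %in% c("senescent", "non_senescent", "borderline"))) {
    msg <- c(msg, "consensus entries must be senescent/non_senescent/borderline")
  }
  allpos <- rowSums(object@panelStatus == "pos") == ncol(object@panelStatus)
  allneg <- rowSums(object@panelStatus == "neg") == ncol(object@panelStatus)
  want <- ifelse(allpos, "senescent",
                 ifelse(allneg, "non_senescent", "borderline"))
  if (n && !identical(unname(want), unname(object@consensus))) {
    msg <- c(msg, "consensus inconsistent with panel statuses")
  }
  if (length(msg)) msg else TRUE
})

#' MarkerTree: a depth-limited two-gene decision tree
#'
#' A greedy gain-ratio tree of depth at most 2 over at most 2 distinct
#' genes, with integer split thresholds (tests are \code{<= t} vs
#' \code{> t}; in binary mode every threshold is 0). Nodes are stored as a
#' data.frame with columns \code{id}, \code{gene}, \code{threshold},
#' \code{left}, \code{right}, \code{leafClass} (split rows have
#' \code{gene != NA}; leaf rows carry \code{leafClass}).
#'
#' @slot inputMode \code{"counts"} or \code{"binary"}.
#' @slot nodes node table (see Description); node 1 is the root; children
#'   \code{left}/\code{right} index into the table; the left child receives
#'   cases with \code{feature <= threshold}.
#' @slot minCases minimum cases required in each branch of a split
#'   (after the automatic doubling search, if it ran).
#' @slot genePool genes the tree was allowed to use.
#' @name MarkerTree-class
#' @rdname MarkerTree-class
#' @exportClass MarkerTree
setClass("MarkerTree", slots = c(
  inputMode = "character",
  nodes = "data.frame",
  minCases = "numeric",
  genePool = "character"
))

setValidity("MarkerTree", function(object) {
  msg <- character()
  g <- unique(object@nodes$gene[!is.na(object@nodes$gene)])
  if (length(g) > 2) msg <- c(msg, "tree may use at most 2 distinct genes")
  if (!object@inputMode %in% c("counts", "binary")) {
    msg <- c(msg, "inputMode must be 'counts' or 'binary'")
  }
  if (object@inputMode == "binary") {
    thr <- object@nodes$threshold[!is.na(object@nodes$gene)]
    if (length(thr) && any(thr != 0)) {
      msg <- c(msg, "binary-mode thresholds must all be 0")
    }
  }
  leaves <- object@nodes$leafClass[is.na(object@nodes$gene)]
  if (!all(leaves %in% c("senescent", "non_senescent"))) {
    msg <- c(msg, "leaf classes must be senescent/non_senescent")
  }
  if (length(msg)) msg else TRUE
})
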