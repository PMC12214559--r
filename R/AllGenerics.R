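#' @rdname SenescenceExperiment-class
#' @param x,object a package object.
#' @export
setGeneric("datasetTag", function(x) standardGeneric("datasetTag"))

#' @rdname SenescenceExperiment-class
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))

#' Oriented unit-norm gene loadings of a panel eigengene
#' @rdname EigengeneModel-class
#' @export
setGeneric("geneLoadings", function(x) standardGeneric("geneLoadings"))

#' @rdname EigengeneModel-class
#' @export
setGeneric("discoveryScores", function(x) standardGeneric("discoveryScores"))

#' @rdname EigengeneModel-class
#' @export
setGeneric("scoreNorm", function(x) standardGeneric("scoreNorm"))

#' @rdname EigengeneModel-class
#' @export
setGeneric("thresholdHigh", function(x) standardGeneric("thresholdHigh"))

#' @rdname EigengeneModel-class
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))

#' @rdname EigengeneModel-class
#' @export
setGeneric("memberGenes", function(x) standardGeneric("memberGenes"))

#' Per-cell consensus senescence labels
#' @rdname CellLabeling-class
#' @export
setGeneric("consensusLabels", function(x) standardGeneric("consensusLabels"))

#' @rdname CellLabeling-class
#' @export
setGeneric("panelStatuses", function(x) standardGeneric("panelStatuses"))

#' Distinct genes used by a fitted marker tree
#' @rdname MarkerTree-class
#' @export
setGeneric("treeGenes", function(x) standardGeneric("treeGenes"))

#' @rdname MarkerTree-class
#' @export
setGeneric("minCases", function(x) standardGeneric("minCases"))

## ---- methods ----

#' @rdname SenescenceExperiment-class
#' @export
setMethod("datasetTag", "SenescenceExperiment", function(x) x@datasetTag)

#' @rdname SenescenceExperiment-class
#' @export
setMethod("cellType", "SenescenceExperiment",
          function(x) setNames(x$cell_type, colnames(x)))

#' @rdname SenescenceExperiment-class
#' @export
setMethod("show", "SenescenceExperiment", function(object) {
  cat("SenescenceExperiment '", object@datasetTag, "': ",
      nrow(object), " genes x ", ncol(object), " cells\n", sep = "")
  tab <- table(object$cell_type)
  cat("cell types:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

#' @rdname EigengeneModel-class
#' @export
setMethod("geneLoadings", "EigengeneModel", function(x) {
  setNames(x@orientationSign * x@loadings, x@memberGenes)
})

#' @rdname EigengeneModel-class
#' @export
setMethod("discoveryScores", "EigengeneModel", function(x) x@discoveryScores)

#' @rdname EigengeneModel-class
#' @export
setMethod("scoreNorm", "EigengeneModel", function(x) x@scoreNorm)

#' @rdname EigengeneModel-class
#' @export
setMethod("thresholdHigh", "EigengeneModel", function(x) x@thresholdHigh)

#' @rdname EigengeneModel-class
#' @export
setMethod("panelName", "EigengeneModel", function(x) x@panelName)

#' @rdname EigengeneModel-class
#' @export
setMethod("memberGenes", "EigengeneModel", function(x) x@memberGenes)

#' @rdname EigengeneModel-class
#' @export
setMethod("show", "EigengeneModel", function(object) {
  cat("EigengeneModel '", object@panelName, "': ",
      length(object@memberGenes), " genes, ",
      length(object@discoveryScores), " discovery cells\n",
      "  mu = ", format(object@mu), ", sigma = ", format(object@sigma),
      ", threshold (mu + ", object@thresholdMultiplier, " sd) = ",
      format(object@thresholdHigh), "\n", sep = "")
  invisible(NULL)
})

#' @rdname CellLabeling-class
#' @export
setMethod("consensusLabels", "CellLabeling",
          function(x) setNames(x@consensus, x@cellIds))

#' @rdname CellLabeling-class
#' @export
setMethod("panelStatuses", "CellLabeling", function(x) {
  m <- x@panelStatus
  rownames(m) <- x@cellIds
  m
})

#' @rdname CellLabeling-class
#' @export
setMethod("show", "CellLabeling", function(object) {
  tab <- table(factor(object@consensus,
                      c("senescent", "non_senescent", "borderline")))
  cat("CellLabeling over", length(object@cellIds), "cells (",
      ncol(object@panelStatus), "panels ):\n")
  print(tab)
  invisible(NULL)
})

#' @rdname MarkerTree-class
#' @export
setMethod("treeGenes", "MarkerTree", function(x) {
  unique(x@nodes$gene[!is.na(x@nodes$gene)])
})

#' @rdname MarkerTree-class
#' @export
setMethod("minCases", "MarkerTree", function(x) x@minCases)

#' @rdname MarkerTree-class
#' @export
setMethod("show", "MarkerTree", function(object) {
  cat("MarkerTree (", object@inputMode, " mode, minCases = ",
      object@minCases, ")\n", sep = "")
  .printNode <- function(id, indent) {
    nd <- object@nodes[id, ]
    pad <- strrep("  ", indent)
    if (is.na(nd$gene)) {
      cat(pad, "-> ", nd$leafClass, "\n", sep = "")
    } else {
      cat(pad, nd$gene, " <= ", nd$threshold, ":\n", sep = "")
      .printNode(nd$left, indent + 1)
      cat(pad, nd$gene, " > ", nd$threshold, ":\n", sep = "")
      .printNode(nd$right, indent + 1)
    }
  }
  .printNode(1L, 1)
  invisible(NULL)
})
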