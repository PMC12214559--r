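#' Binarize a count matrix
#'
#' Converts every count above zero to 1, the transform used to search for
#' presence/absence markers usable in histology.
#'
#' @param x a \linkS4class{SenescenceExperiment}.
#' @return A \linkS4class{SenescenceExperiment} with 0/1 counts.
#' @export
binarizeCounts <- function(x) {
  m <- SummarizedExperiment::assay(x, "counts")
  b <- (m > 0) * 1
  dimnames(b) <- dimnames(m)
  SenescenceExperiment(b, x$cell_type, datasetTag = datasetTag(x))
}

.asCountsMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else x
}

# weighted entropy (bits) of a binary class split
.entropy <- function(wPos, wNeg) {
  n <- wPos + wNeg
  h <- 0
  for (q in c(wPos, wNeg) / n) if (q > 0) h <- h - q * log2(q)
  h
}

# Best admissible "<= t" split for one gene: maximizes gain ratio among
# thresholds leaving at least minCases (weighted) in both branches.
.bestSplitForGene <- function(xv, wPos, wNeg, minCases, parentH) {
  o <- order(xv)
  xs <- xv[o]
  cumP <- cumsum(wPos[o])
  cumN <- cumsum(wNeg[o])
  last <- which(diff(xs) > 0)            # positions where value changes
  if (!length(last)) return(NULL)
  lp <- cumP[last]; ln <- cumN[last]
  totP <- cumP[length(cumP)]; totN <- cumN[length(cumN)]
  rp <- totP - lp; rn <- totN - ln
  nl <- lp + ln; nr <- rp + rn
  ok <- nl >= minCases & nr >= minCases
  if (!any(ok)) return(NULL)
  n <- totP + totN
  hl <- vapply(seq_along(lp), function(i) .entropy(lp[i], ln[i]), 1)
  hr <- vapply(seq_along(rp), function(i) .entropy(rp[i], rn[i]), 1)
  ig <- parentH - (nl / n) * hl - (nr / n) * hr
  si <- -(nl / n) * log2(nl / n) - (nr / n) * log2(nr / n)
  gr <- ifelse(ok & ig > 1e-12 & si > 0, ig / si, -Inf)
  if (all(gr == -Inf)) return(NULL)
  best <- which.max(gr)                   # earliest max -> smallest threshold
  list(threshold = xs[last[best]], gainRatio = gr[best])
}

.majorityClass <- function(wPos, wNeg) {
  if (sum(wPos) > sum(wNeg)) "senescent" else "non_senescent"
}

# recursive greedy induction; returns a nested list tree
.growTree <- function(feat, wPos, wNeg, minCases, depth, maxDepth, pool) {
  leaf <- list(leaf = TRUE, class = .majorityClass(wPos, wNeg))
  if (depth > maxDepth) return(leaf)
  active <- wPos + wNeg > 0
  parentH <- .entropy(sum(wPos), sum(wNeg))
  if (parentH == 0) return(leaf)
  best <- NULL
  for (g in pool) {
    sp <- .bestSplitForGene(feat[g, active], wPos[active], wNeg[active],
                            minCases, parentH)
    if (!is.null(sp) && (is.null(best) || sp$gainRatio > best$gainRatio + 1e-12)) {
      best <- c(sp, gene = g)
    }
  }
  if (is.null(best)) return(leaf)
  goLeft <- feat[best$gene, ] <= best$threshold
  lw <- active & goLeft; rw <- active & !goLeft
  list(leaf = FALSE, gene = best$gene, threshold = best$threshold,
       left = .growTree(feat, wPos * lw, wNeg * lw, minCases,
                        depth + 1, maxDepth, pool),
       right = .growTree(feat, wPos * rw, wNeg * rw, minCases,
                         depth + 1, maxDepth, pool))
}

.flattenTree <- function(node) {
  nodes <- data.frame(id = integer(), gene = character(),
                      threshold = numeric(), left = integer(),
                      right = integer(), leafClass = character(),
                      stringsAsFactors = FALSE)
  addNode <- function(nd) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, NA_character_, NA_real_, NA_integer_,
                         NA_integer_, NA_character_)
    if (nd$leaf) {
      nodes$leafClass[id] <<- nd$class
    } else {
      nodes$gene[id] <<- nd$gene
      nodes$threshold[id] <<- nd$threshold
      nodes$left[id] <<- addNode(nd$left)
      nodes$right[id] <<- addNode(nd$right)
    }
    id
  }
  addNode(node)
  nodes
}

# drop splits whose two children are leaves of the same class: they never
# change a prediction but would count against the distinct-gene limit
.collapseTree <- function(node) {
  if (node$leaf) return(node)
  node$left <- .collapseTree(node$left)
  node$right <- .collapseTree(node$right)
  if (node$left$leaf && node$right$leaf &&
      identical(node$left$class, node$right$class)) {
    return(list(leaf = TRUE, class = node$left$class))
  }
  node
}

.treeDistinctGenes <- function(node) {
  if (node$leaf) return(character())
  unique(c(node$gene, .treeDistinctGenes(node$left),
           .treeDistinctGenes(node$right)))
}

#' Fit a depth-limited two-gene marker tree
#'
#' Greedy top-down induction maximizing the information gain ratio
#' (C4.5-style), with integer split thresholds taken from the observed
#' values (tests are \code{<= t} vs \code{> t}; in binary mode the only
#' threshold is 0). A split is admissible only if at least \code{minCases}
#' (weighted) cases fall in each branch; growth stops at depth 2 or when
#' no admissible split exists. If the fitted tree would use more than two
#' distinct genes, \code{minCases} is doubled and the fit repeated until
#' at most two genes are used. Ties between equally good splits go to the
#' earlier gene in \code{genePool} order, then to the smaller threshold.
#' Optionally the minority class is upsampled (replication weights from
#' \code{\link{upsampleIndices}}); the default trains at natural
#' prevalence.
#'
#' @param x a \linkS4class{SenescenceExperiment} or genes x cells matrix.
#' @param labels per-cell labels; \code{"borderline"} cells are dropped,
#'   the rest must be \code{"senescent"}/\code{"non_senescent"}.
#' @param genePool genes the tree may use (default: all rows of \code{x}).
#' @param minCases minimum (weighted) cases per branch; the starting value
#'   of the doubling search.
#' @param mode \code{"binary"} (counts are binarized first) or
#'   \code{"counts"}.
#' @param upsample weight minority cells by the replication factor of
#'   \code{\link{upsampleIndices}} so minority leaves can satisfy
#'   \code{minCases}. Off by default: training under the natural class
#'   prevalence is what makes a single low-specificity marker insufficient
#'   evidence on its own and yields the conjunctive two-marker trees with
#'   perfect specificity.
#' @param maxDepth,maxGenes structural limits (defaults 2 and 2).
#' @return A \linkS4class{MarkerTree}.
#' @export
fitMarkerTree <- function(x, labels, genePool = NULL, minCases = 2,
                          mode = c("binary", "counts"), upsample = FALSE,
                          maxDepth = 2, maxGenes = 2) {
  mode <- match.arg(mode)
  m <- .asCountsMatrix(x)
  labels <- as.character(labels)
  if (ncol(m) != length(labels)) stop("labels must match cells")
  keep <- labels != "borderline"
  if (!all(keep)) {
    message("excluding ", sum(!keep), " borderline cells from training")
    m <- m[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  if (is.null(genePool)) genePool <- rownames(m)
  missingPool <- setdiff(genePool, rownames(m))
  if (length(missingPool)) {
    stop("gene pool members absent from the data: ",
         paste(head(missingPool, 5), collapse = ", "))
  }
  feat <- as.matrix(m[genePool, , drop = FALSE])
  if (mode == "binary") feat <- (feat > 0) * 1
  isPos <- labels == "senescent"
  if (all(isPos) || all(!isPos)) {
    warning("single-class labels; returning a one-leaf tree")
    nodes <- data.frame(id = 1L, gene = NA_character_, threshold = NA_real_,
                        left = NA_integer_, right = NA_integer_,
                        leafClass = if (all(isPos)) "senescent" else
                          "non_senescent", stringsAsFactors = FALSE)
    return(methods::new("MarkerTree", inputMode = mode, nodes = nodes,
                        minCases = minCases, genePool = genePool))
  }
  w <- .upsampleWeights(labels, upsample)
  wPos <- w * isPos
  wNeg <- w * !isPos
  mc <- minCases
  repeat {
    tr <- .collapseTree(.growTree(feat, wPos, wNeg, mc, 1, maxDepth, genePool))
    if (length(.treeDistinctGenes(tr)) <= maxGenes) break
    mc <- mc * 2
  }
  methods::new("MarkerTree", inputMode = mode, nodes = .flattenTree(tr),
               minCases = mc, genePool = genePool)
}

#' Predict senescence classes with a fitted marker tree
#'
#' Routes each cell through the stored splits; thresholds learned on the
#' discovery data are never refit. Binary-mode thresholds (0) apply
#' directly to raw counts, since \code{count <= 0} and
#' \code{binary <= 0} coincide.
#'
#' @param tree a \linkS4class{MarkerTree}.
#' @param x a \linkS4class{SenescenceExperiment} or genes x cells matrix
#'   containing every gene the tree uses.
#' @return Named character vector of per-cell predicted classes.
#' @export
predictTree <- function(tree, x) {
  m <- .asCountsMatrix(x)
  need <- treeGenes(tree)
  absent <- setdiff(need, rownames(m))
  if (length(absent)) {
    stop("tree gene(s) missing from the data: ", paste(absent, collapse = ", "))
  }
  feat <- as.matrix(m[need, , drop = FALSE])
  nodes <- tree@nodes
  out <- character(ncol(feat))
  route <- function(id, mask) {
    nd <- nodes[id, ]
    if (is.na(nd$gene)) {
      out[mask] <<- nd$leafClass
    } else {
      goLeft <- feat[nd$gene, ] <= nd$threshold
      route(nd$left, mask & goLeft)
      route(nd$right, mask & !goLeft)
    }
  }
  route(1L, rep(TRUE, ncol(feat)))
  setNames(out, colnames(feat))
}

#' @rdname predictTree
#' @param object a \linkS4class{MarkerTree}.
#' @param newdata data to predict on.
#' @param ... ignored.
#' @export
setMethod("predict", "MarkerTree", function(object, newdata, ...) {
  predictTree(object, newdata)
})

#' Confusion-matrix metrics against eigengene-derived truth
#'
#' True positives are cells called senescent by both the tree and the
#' eigengene consensus. Cells with truth \code{"borderline"} are excluded
#' from every denominator. Accuracy is (tp + tn) / total by default; the
#' literal variant tp / total is available via \code{literalAccuracy}.
#' With no truth positives, sensitivity is undefined and reported as NA
#' with a warning.
#'
#' @param predicted per-cell predicted classes (from
#'   \code{\link{predictTree}}).
#' @param truth per-cell consensus labels (may include borderline).
#' @param literalAccuracy report tp / total instead of (tp + tn) / total.
#' @return One-row data.frame: \code{tp}, \code{tn}, \code{fp}, \code{fn},
#'   \code{accuracy}, \code{sensitivity}, \code{specificity}.
#' @export
evaluateMetrics <- function(predicted, truth, literalAccuracy = FALSE) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  keep <- truth != "borderline"
  predicted <- as.character(predicted)[keep]
  truth <- as.character(truth)[keep]
  tp <- sum(predicted == "senescent" & truth == "senescent")
  tn <- sum(predicted != "senescent" & truth != "senescent")
  fp <- sum(predicted == "senescent" & truth != "senescent")
  fn <- sum(predicted != "senescent" & truth == "senescent")
  sens <- if (tp + fn == 0) {
    warning("no truth positives; sensitivity undefined")
    NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  acc <- if (literalAccuracy) tp / (tp + tn + fp + fn) else
    (tp + tn) / (tp + tn + fp + fn)
  data.frame(tp = tp, tn = tn, fp = fp, fn = fn, accuracy = acc,
             sensitivity = sens, specificity = spec)
}

#' Iterative marker elimination ledger
#'
#' Round r fits a tree on the gene pool minus all genes selected in earlier
#' rounds (plus any user exclusions), evaluates it on the discovery data
#' and on every validation set, and appends a ledger row. Stops after
#' \code{maxRounds}, when the pool is exhausted, or when no admissible
#' split remains.
#'
#' @inheritParams fitMarkerTree
#' @param validationSets named list; each element is a list with
#'   \code{features} (matrix or \linkS4class{SenescenceExperiment}) and
#'   \code{labels} (consensus labels of those cells).
#' @param exclude genes excluded from every round.
#' @param maxRounds maximum number of elimination rounds.
#' @return data.frame ledger: \code{round}, \code{removed},
#'   \code{selected}, then accuracy/specificity/sensitivity per dataset.
#' @export
eliminationAnalysis <- function(x, labels, genePool, validationSets = list(),
                                maxRounds = 5, minCases = 2,
                                mode = c("binary", "counts"),
                                exclude = character(), upsample = FALSE) {
  mode <- match.arg(mode)
  if (length(validationSets) && is.null(names(validationSets))) {
    names(validationSets) <- sprintf("validation%d", seq_along(validationSets))
  }
  selectedSoFar <- character()
  rows <- list()
  for (r in seq_len(maxRounds)) {
    pool <- setdiff(genePool, c(exclude, selectedSoFar))
    if (length(pool) == 0) break
    tree <- fitMarkerTree(x, labels, genePool = pool, minCases = minCases,
                          mode = mode, upsample = upsample)
    sel <- treeGenes(tree)
    if (!length(sel)) break
    evalSets <- c(list(discovery = list(features = x, labels = labels)),
                  validationSets)
    met <- lapply(evalSets, function(vs) {
      evaluateMetrics(predictTree(tree, vs$features), vs$labels)
    })
    row <- data.frame(round = r,
                      removed = paste(c(exclude, selectedSoFar),
                                      collapse = ","),
                      selected = paste(sel, collapse = ","),
                      stringsAsFactors = FALSE)
    for (nm in names(met)) {
      row[[paste0("accuracy_", nm)]] <- met[[nm]]$accuracy
      row[[paste0("specificity_", nm)]] <- met[[nm]]$specificity
      row[[paste0("sensitivity_", nm)]] <- met[[nm]]$sensitivity
    }
    rows[[r]] <- row
    selectedSoFar <- union(selectedSoFar, sel)
  }
  if (!length(rows)) {
    return(data.frame(round = integer(), removed = character(),
                      selected = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
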