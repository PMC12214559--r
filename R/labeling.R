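#' Per-panel overexpression status of each cell
#'
#' A cell is \code{"pos"} when its eigengene score is strictly above the
#' model's \code{mu + 3 sd} threshold, \code{"neg"} when strictly below the
#' mean \code{mu}, and \code{"borderline"} otherwise (ties fall in
#' borderline because the cuts are strict inequalities).
#'
#' @param scores named numeric vector of per-cell eigengene scores.
#' @param model the \linkS4class{EigengeneModel} supplying \code{mu} and
#'   the threshold.
#' @return Named character vector with entries pos/neg/borderline.
#' @export
panelStatus <- function(scores, model) {
  if (any(!is.finite(scores))) {
    bad <- names(scores)[!is.finite(scores)]
    if (is.null(bad)) bad <- which(!is.finite(scores))
    stop("non-finite score for cell(s): ", paste(head(bad, 5), collapse = ", "))
  }
  st <- rep("borderline", length(scores))
  st[scores > model@thresholdHigh] <- "pos"
  st[scores < model@mu] <- "neg"
  setNames(st, names(scores))
}

#' Three-panel consensus senescence labels
#'
#' A cell is \code{"senescent"} only when every panel calls it pos
#' (overexpressing all eigengenes), \code{"non_senescent"} only when every
#' panel calls it neg (below all means), and \code{"borderline"} otherwise.
#' Borderline cells are excluded from downstream differential expression
#' and tree training.
#'
#' @param ... two or more equal-length per-panel status vectors (from
#'   \code{\link{panelStatus}}), or a single named list of them.
#' @param cellIds cell identifiers; defaults to the names of the first
#'   status vector.
#' @return A \linkS4class{CellLabeling}.
#' @export
consensusLabel <- function(..., cellIds = NULL) {
  statuses <- list(...)
  if (length(statuses) == 1 && is.list(statuses[[1]])) statuses <- statuses[[1]]
  if (length(statuses) < 2) stop("need at least two panel status vectors")
  n <- unique(vapply(statuses, length, 1L))
  if (length(n) != 1) stop("panel status vectors have mismatched lengths: ",
                           paste(vapply(statuses, length, 1L), collapse = ", "))
  if (is.null(cellIds)) cellIds <- names(statuses[[1]])
  if (is.null(cellIds)) cellIds <- sprintf("cell%d", seq_len(n))
  m <- do.call(cbind, statuses)
  if (is.null(colnames(m))) colnames(m) <- sprintf("panel%d", seq_along(statuses))
  allpos <- rowSums(m == "pos") == ncol(m)
  allneg <- rowSums(m == "neg") == ncol(m)
  consensus <- ifelse(allpos, "senescent",
                      ifelse(allneg, "non_senescent", "borderline"))
  methods::new("CellLabeling", cellIds = as.character(cellIds),
               panelStatus = m, consensus = unname(consensus))
}

#' Cell-type enrichment of senescent cells
#'
#' For each cell type, tests whether it contains more consensus-senescent
#' cells than expected at random with an upper-tail hypergeometric test:
#' \code{P(X >= k)} where the population is all labeled cells, successes
#' are the senescent cells, and the draw is the cell type.
#'
#' @param labeling a \linkS4class{CellLabeling}.
#' @param cellTypes cell-type label per labeled cell.
#' @return data.frame with columns \code{cell_type}, \code{n_cells},
#'   \code{n_senescent}, \code{p}, \code{log10p}.
#' @export
cellTypeEnrichment <- function(labeling, cellTypes) {
  lab <- consensusLabels(labeling)
  if (length(cellTypes) != length(lab)) {
    stop("cellTypes must have one label per labeled cell")
  }
  sen <- lab == "senescent"
  N <- length(lab)
  K <- sum(sen)
  if (K == 0) warning("no senescent cells; all enrichment p-values are 1")
  types <- sort(unique(as.character(cellTypes)))
  rows <- lapply(types, function(ty) {
    inTy <- cellTypes == ty
    k <- sum(sen & inTy)
    ht <- if (K == 0) list(p = 1, log10p = 0) else
      hypergeomUpperTail(k, K, sum(inTy), N)
    data.frame(cell_type = ty, n_cells = sum(inTy), n_senescent = k,
               p = ht$p, log10p = ht$log10p)
  })
  do.call(rbind, rows)
}
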