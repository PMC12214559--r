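#' Configuration for the synthetic snRNA-seq generator
#'
#' Bundles and validates the parameters of \code{\link{simulateDataset}}.
#' Defaults emulate a discovery-scale neuronal snRNA-seq experiment: an
#' imbalanced excitatory/inhibitory mix (79/21), a 1\% planted senescent
#' subpopulation, three senescence panels of 22/44/116 genes coordinately
#' up-shifted by 2 log2 units in senescent cells, a block of 324 strongly
#' overexpressed genes (7 log2 units), and one pair of near-binary marker
#' genes detected with probability 0.95 in senescent and 0.01 in other
#' cells.
#'
#' @param nCells number of cells.
#' @param cellTypeProportions named fractions per cell type; must sum to 1.
#' @param senescentFraction fraction of cells planted as senescent.
#' @param nGenes number of genes; must exceed the planted structure
#'   (\code{sum(panelSizes) + nDeGenes + 2}).
#' @param panelSizes named integer sizes of the three senescence panels.
#' @param baselineLogMean,baselineLogSd natural-log mean/sd of the
#'   log-normal draw of per-gene baseline negative-binomial means.
#' @param dispersion negative-binomial dispersion (NB size = 1/dispersion).
#' @param panelLog2Shift log2 up-shift of panel genes in senescent cells.
#' @param nDeGenes number of planted differentially expressed genes.
#' @param deLog2Shift log2 up-shift of planted DE genes in senescent cells.
#' @param markerPOn,markerPOff detection probability of each planted marker
#'   gene in senescent / non-senescent cells.
#' @param librarySizeSd log-normal sd of per-cell library size factors.
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nCells = 20000,
                            cellTypeProportions = c(excitatory = 0.79,
                                                    inhibitory = 0.21),
                            senescentFraction = 0.01,
                            nGenes = 6000,
                            panelSizes = c(CSP = 22, SIP = 44, SenMayo = 116),
                            baselineLogMean = 0,
                            baselineLogSd = 0.4,
                            dispersion = 0.2,
                            panelLog2Shift = 2.0,
                            nDeGenes = 324,
                            deLog2Shift = 7.0,
                            markerPOn = 0.95,
                            markerPOff = 0.01,
                            librarySizeSd = 0.2) {
  cfg <- list(nCells = as.integer(nCells),
              cellTypeProportions = cellTypeProportions,
              senescentFraction = senescentFraction,
              nGenes = as.integer(nGenes),
              panelSizes = panelSizes,
              baselineLogMean = baselineLogMean,
              baselineLogSd = baselineLogSd,
              dispersion = dispersion,
              panelLog2Shift = panelLog2Shift,
              nDeGenes = as.integer(nDeGenes),
              deLog2Shift = deLog2Shift,
              markerPOn = markerPOn,
              markerPOff = markerPOff,
              librarySizeSd = librarySizeSd)
  class(cfg) <- "SyntheticConfig"
  validateSyntheticConfig(cfg)
  cfg
}

#' Validate a SyntheticConfig
#'
#' Errors (before any sampling) on violated invariants: fractions outside
#' [0,1], proportions not summing to 1, negative shifts, or planted
#' structure exceeding \code{nGenes}.
#'
#' @param cfg a \code{"SyntheticConfig"} list.
#' @return \code{cfg}, invisibly.
#' @export
validateSyntheticConfig <- function(cfg) {
  stopifnot(cfg$nCells >= 1, cfg$nGenes >= 1)
  fr <- c(cfg$senescentFraction, cfg$cellTypeProportions,
          cfg$markerPOn, cfg$markerPOff)
  if (any(fr < 0 | fr > 1)) stop("fractions/probabilities must lie in [0, 1]")
  if (abs(sum(cfg$cellTypeProportions) - 1) > 1e-9) {
    stop("cellTypeProportions must sum to 1 (got ",
         sum(cfg$cellTypeProportions), ")")
  }
  if (cfg$panelLog2Shift < 0 || cfg$deLog2Shift < 0) {
    stop("log2 shifts must be >= 0")
  }
  if (is.null(names(cfg$cellTypeProportions)) ||
      is.null(names(cfg$panelSizes))) {
    stop("cellTypeProportions and panelSizes must be named")
  }
  if (sum(cfg$panelSizes) + cfg$nDeGenes + 2 > cfg$nGenes) {
    stop("nGenes must be at least sum(panelSizes) + nDeGenes + 2 = ",
         sum(cfg$panelSizes) + cfg$nDeGenes + 2)
  }
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  invisible(cfg)
}

# deterministic sub-stream seed for a generation stage, kept < 2^31
.stageSeed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

#' Generate a synthetic snRNA-seq dataset with planted ground truth
#'
#' Counts are negative binomial with log-normal per-gene baseline means and
#' multiplicative log-normal cell size factors (dropout arises from low
#' means). Panel genes and planted DE genes receive their log2 up-shift
#' only in senescent cells. Each planted marker gene is 0 with probability
#' \code{1 - p} and \code{1 + Poisson(1)} otherwise, with
#' \code{p = markerPOn} in senescent cells and \code{markerPOff} elsewhere,
#' so binary markers are detectable at threshold > 0 but low-expressed.
#' Identical \code{(config, seed)} pairs reproduce identical output.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param seed integer seed; all randomness derives from it.
#' @param datasetTag tag for the returned experiment.
#' @return A list with elements:
#'   \describe{
#'     \item{experiment}{a \linkS4class{SenescenceExperiment};}
#'     \item{truth}{a list with \code{status} (named per-cell
#'       "senescent"/"non_senescent"), \code{markerGenes} (2 ids),
#'       \code{deGenes}, and \code{panels} (named list of member gene ids).}
#'   }
#' @examples
#' sim <- simulateDataset(syntheticConfig(nCells = 200, nGenes = 600,
#'                                        nDeGenes = 50), seed = 1)
#' table(sim$truth$status)
#' @export
simulateDataset <- function(config, seed, datasetTag = "synthetic") {
  validateSyntheticConfig(config)
  cfg <- config
  nG <- cfg$nGenes; nC <- cfg$nCells

  geneIds <- sprintf("gene%05d", seq_len(nG))
  cellIds <- sprintf("cell%05d", seq_len(nC))

  # planted structure occupies the head of the gene list (ids are arbitrary)
  ends <- cumsum(cfg$panelSizes)
  starts <- c(1, head(ends, -1) + 1)
  panels <- Map(function(s, e) geneIds[s:e], starts, ends)
  names(panels) <- names(cfg$panelSizes)
  deGenes <- geneIds[(sum(cfg$panelSizes) + 1):(sum(cfg$panelSizes) + cfg$nDeGenes)]
  markerGenes <- geneIds[sum(cfg$panelSizes) + cfg$nDeGenes + 1:2]

  # cell types by largest remainder, then planted senescent cells
  tgt <- cfg$cellTypeProportions * nC
  cnt <- floor(tgt)
  rem <- nC - sum(cnt)
  if (rem > 0) {
    ord <- order(tgt - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  cellTypes <- rep(names(cnt), cnt)

  nSen <- round(nC * cfg$senescentFraction)
  set.seed(.stageSeed(seed, 1))
  senIdx <- sort(sample.int(nC, nSen))
  status <- rep("non_senescent", nC)
  status[senIdx] <- "senescent"

  set.seed(.stageSeed(seed, 2))
  baseline <- rlnorm(nG, cfg$baselineLogMean, cfg$baselineLogSd)
  sizeFactor <- rlnorm(nC, 0, cfg$librarySizeSd)

  shift <- numeric(nG)
  names(shift) <- geneIds
  shift[unlist(panels)] <- cfg$panelLog2Shift
  shift[deGenes] <- cfg$deLog2Shift
  # genes with a several-log2 fold change are near-silent at baseline in
  # real sparse data; anchor the shifted block there so planted DE genes
  # do not dominate senescent cells' library sizes
  baseline[match(deGenes, geneIds)] <-
    baseline[match(deGenes, geneIds)] / 2^cfg$deLog2Shift

  isSen <- status == "senescent"
  set.seed(.stageSeed(seed, 3))
  counts <- matrix(0L, nG, nC, dimnames = list(geneIds, cellIds))
  size <- 1 / cfg$dispersion
  shiftFactor <- 2^shift          # applied only in senescent cells
  for (c in seq_len(nC)) {        # column-wise: contiguous writes
    mu <- baseline * sizeFactor[c]
    if (isSen[c]) mu <- mu * shiftFactor
    counts[, c] <- as.integer(rnbinom(nG, size = size, mu = mu))
  }

  set.seed(.stageSeed(seed, 4))
  for (mg in markerGenes) {
    p <- ifelse(isSen, cfg$markerPOn, cfg$markerPOff)
    on <- runif(nC) < p
    v <- integer(nC)
    v[on] <- 1L + rpois(sum(on), 1)
    counts[mg, ] <- v
  }

  # simulated counts are only ~30-50% zeros, so dense integer storage is
  # more compact than a sparse double matrix
  exper <- SenescenceExperiment(counts, cellTypes, datasetTag = datasetTag)
  truth <- list(status = setNames(status, cellIds),
                markerGenes = markerGenes,
                deGenes = deGenes,
                panels = panels)
  list(experiment = exper, truth = truth)
}

#' Generate a null dataset (no planted effects)
#'
#' Identical to \code{\link{simulateDataset}} with every effect parameter
#' forced to zero (panel and DE shifts 0, marker detection probability
#' equal in both groups); the truth labels are retained so type-I-error
#' studies can still split cells by status.
#'
#' @inheritParams simulateDataset
#' @return As \code{\link{simulateDataset}}.
#' @export
simulateNullDataset <- function(config, seed, datasetTag = "synthetic_null") {
  validateSyntheticConfig(config)
  cfg <- config
  cfg$panelLog2Shift <- 0
  cfg$deLog2Shift <- 0
  cfg$markerPOn <- cfg$markerPOff
  simulateDataset(cfg, seed, datasetTag = datasetTag)
}
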