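.logSumExp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Upper-tail hypergeometric probability
#'
#' \code{P(X >= k)} for \code{X ~ Hypergeometric(N, K, n)} (population
#' \code{N}, successes \code{K}, draws \code{n}), accumulated in log space
#' from log-gamma mass terms so that probabilities far below the smallest
#' normal double (e.g. 1e-300) are still resolved; the log10 probability is
#' always returned alongside.
#'
#' @param k observed overlap (successes drawn).
#' @param K successes in the population.
#' @param n draws.
#' @param N population size.
#' @return List with \code{p} (may underflow to 0 for extreme tails) and
#'   \code{log10p} (always finite for valid input).
#' @examples
#' hypergeomUpperTail(2, 3, 3, 10)$p  # 22/120
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
  if (length(k) != 1 || length(K) != 1 || length(n) != 1 || length(N) != 1 ||
      anyNA(c(k, K, n, N)) || k < 0 || K < 0 || n < 0 ||
      k > min(K, n) || K > N || n > N) {
    stop("need 0 <= k <= min(K, n) <= N; got k=", k, " K=", K,
         " n=", n, " N=", N)
  }
  if (k == 0) return(list(p = 1, log10p = 0))
  j <- k:min(K, n)
  lp <- .logSumExp(dhyper(j, K, N - K, n, log = TRUE))
  lp <- min(lp, 0)
  list(p = exp(lp), log10p = lp / log(10))
}

#' Hypergeometric pathway over-representation
#'
#' Tests each pathway for over-representation of the query genes against a
#' gene universe: pathways are intersected with the universe, the overlap
#' with the query is scored by \code{\link{hypergeomUpperTail}}, and
#' p-values are Benjamini-Hochberg adjusted across pathways. A typical
#' universe is the post-filter gene set of the differential-expression
#' analysis.
#'
#' @param queryGenes character vector, a subset of \code{universe}.
#' @param pathways named list of gene sets (e.g. from
#'   \code{\link{readGeneSets}}).
#' @param universe character vector of background gene ids.
#' @param alpha adjusted-p significance cut (default 0.05).
#' @return data.frame with one row per pathway: \code{pathway},
#'   \code{set_size} (within universe), \code{overlap}, \code{p},
#'   \code{padj}, \code{significant}, \code{overlapping_genes}
#'   (comma-separated).
#' @export
enrichPathways <- function(queryGenes, pathways, universe, alpha = 0.05) {
  if (!length(universe)) stop("universe must be nonempty")
  universe <- unique(universe)
  bad <- setdiff(queryGenes, universe)
  if (length(bad)) {
    stop("query genes outside the universe: ", paste(head(bad, 5), collapse = ", "))
  }
  queryGenes <- unique(queryGenes)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]], universe)
    ov <- intersect(pw, queryGenes)
    ht <- hypergeomUpperTail(length(ov), length(pw), length(queryGenes),
                             length(universe))
    data.frame(pathway = nm, set_size = length(pw), overlap = length(ov),
               p = ht$p,
               overlapping_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out$significant <- out$padj < alpha
  out[order(out$p), c("pathway", "set_size", "overlap", "p", "padj",
                      "significant", "overlapping_genes")]
}

#' Exact multi-set intersection test
#'
#' Under the null that each set is placed uniformly at random in a universe
#' of size \code{N}, the size of the running intersection of k sets evolves
#' by conditional hypergeometric draws: given a current intersection of
#' size m, its overlap with the next set of size s is
#' Hypergeometric(N, m, s). Convolving these distributions yields the exact
#' law of the k-set intersection size; the reported p is
#' \code{P(intersection >= observed)}. For k = 2 this reduces exactly to
#' \code{\link{hypergeomUpperTail}}. The expected intersection size is
#' \code{N * prod(|set_i| / N)}.
#'
#' @param sets named list of at least two character vectors, each a subset
#'   of the universe.
#' @param N universe size; must be at least the size of every set and of
#'   their union.
#' @return List with \code{observed}, \code{expected}, \code{p},
#'   \code{log10p}.
#' @export
multisetIntersectionTest <- function(sets, N) {
  if (length(sets) < 2) stop("need at least 2 sets")
  sizes <- vapply(sets, function(s) length(unique(s)), 1L)
  if (any(sizes > N) || length(unique(unlist(sets))) > N) {
    stop("every set (and their union) must fit in a universe of size N")
  }
  observed <- length(Reduce(intersect, sets))
  expected <- N * prod(sizes / N)

  # distribution of the running intersection size, in log space
  lp <- rep(-Inf, sizes[1] + 1)          # support 0..m
  lp[sizes[1] + 1] <- 0                  # first set intersects itself
  for (s in sizes[-1]) {
    mMax <- length(lp) - 1L
    newMax <- min(mMax, s)
    lnew <- rep(-Inf, newMax + 1)
    for (m in 0:mMax) {
      if (lp[m + 1] == -Inf) next
      j <- 0:min(m, s)
      contrib <- lp[m + 1] + dhyper(j, m, N - m, s, log = TRUE)
      for (i in seq_along(j)) {
        lnew[j[i] + 1] <- .logSumExp(c(lnew[j[i] + 1], contrib[i]))
      }
    }
    lp <- lnew
  }
  if (observed > length(lp) - 1L) {
    stop("observed intersection exceeds the support of the null")
  }
  tail <- lp[(observed + 1):length(lp)]
  lpv <- min(.logSumExp(tail), 0)
  list(observed = observed, expected = expected,
       p = exp(lpv), log10p = lpv / log(10))
}
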