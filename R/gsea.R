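## Preranked gene-set enrichment: classic weighted Kolmogorov-Smirnov
## running sum with a gene-permutation null, signed-null NES, and BH
## correction. This stands in for adaptive multilevel p-value estimators:
## enrichment scores agree exactly with the standard definition, p-values
## are plain permutation estimates.

#' Build a ranked gene list
#'
#' Sorts statistics in decreasing order (stable: ties keep input order,
#' with a warning).
#'
#' @param stats Named numeric vector (names = gene identifiers, no
#'   duplicates, finite values).
#' @return The sorted named vector.
#' @export
makeRankedList <- function(stats) {
  if (is.null(names(stats)) || anyDuplicated(names(stats)))
    stop("makeRankedList: stats must be named with unique gene ids",
         call. = FALSE)
  if (any(!is.finite(stats)))
    stop("makeRankedList: statistics must be finite", call. = FALSE)
  if (anyDuplicated(stats))
    warning("makeRankedList: tied statistics broken by stable input order")
  stats[order(-stats)]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walking down the ranked list, a gene in the set increments the running
#' sum by its |statistic|^weight share of the in-set total; a gene outside
#' the set decrements by 1/(N - Nh). The enrichment score is the running
#' sum value of maximum absolute magnitude.
#'
#' @param ranked Named numeric vector sorted decreasing
#'   ([makeRankedList()]).
#' @param geneSet Character vector of set members.
#' @param weight Statistic weight exponent (default 1; 0 gives the
#'   unweighted KS statistic).
#' @return A list with `es`, the `running` sum profile, and the logical
#'   `hits` vector along the ranking.
#' @export
enrichmentScore <- function(ranked, geneSet, weight = 1) {
  N <- length(ranked)
  hits <- names(ranked) %in% geneSet
  Nh <- sum(hits)
  if (Nh == 0L)
    stop("enrichmentScore: gene set does not intersect the ranked universe",
         call. = FALSE)
  if (Nh == N)
    stop("enrichmentScore: gene set equals the entire universe (miss decrement undefined)",
         call. = FALSE)
  running <- .runningSum(abs(ranked)^weight, hits, N, Nh)
  list(es = running[which.max(abs(running))], running = running, hits = hits)
}

.runningSum <- function(w, hits, N, Nh) {
  steps <- rep(-1 / (N - Nh), N)
  nr <- sum(w[hits])
  steps[hits] <- if (nr > 0) w[hits] / nr else 1 / Nh
  cumsum(steps)
}

.esOnly <- function(w, hits, N, Nh) {
  running <- .runningSum(w, hits, N, Nh)
  running[which.max(abs(running))]
}

#' Preranked GSEA over a gene-set collection
#'
#' Sets are intersected with the ranked universe and filtered by size
#' (sets with fewer than `minSize` or more than `maxSize` surviving genes
#' are excluded). The null distribution for each set size is `nPerm`
#' random same-size gene draws; NES is the enrichment score divided by the
#' mean |null score| of matching sign, and the permutation p-value is
#' `(1 + # same-sign nulls at least as extreme) / (1 + # same-sign
#' nulls)`, never zero. BH adjustment is applied across retained sets.
#'
#' @param ranked Named numeric vector sorted decreasing
#'   ([makeRankedList()]).
#' @param sets Named list of gene sets ([readGmt()]).
#' @param minSize,maxSize Inclusive size bounds after universe
#'   intersection (defaults 10 and 500).
#' @param nPerm Number of permutations (default 1000, minimum 100).
#' @param weight Statistic weight exponent (default 1).
#' @param seed Integer seed for the permutation draws (the global RNG
#'   state is restored afterwards).
#' @return A `data.frame` with `set`, `size`, `es`, `nes`, `p_value`,
#'   `p_adjusted`, ordered by `p_value`; empty (with a warning) when no
#'   set survives filtering.
#' @export
gseaPreranked <- function(ranked, sets, minSize = 10L, maxSize = 500L,
                          nPerm = 1000L, weight = 1, seed = 1L) {
  stopifnot(nPerm >= 100L)
  inset <- lapply(sets, function(s) unique(s[s %in% names(ranked)]))
  sizes <- lengths(inset)
  keep <- sizes >= minSize & sizes <= maxSize & sizes < length(ranked)
  if (!any(keep)) {
    warning("gseaPreranked: no gene set survives size filtering")
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_value = numeric(0),
                      p_adjusted = numeric(0)))
  }
  inset <- inset[keep]
  sizes <- sizes[keep]
  N <- length(ranked)
  w <- abs(ranked)^weight
  old <- .saveRng()
  on.exit(.restoreRng(old))
  set.seed(seed)
  nullBySize <- list()
  for (sz in unique(sizes)) {
    null <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
      hits <- logical(N)
      hits[sample.int(N, sz)] <- TRUE
      null[b] <- .esOnly(w, hits, N, sz)
    }
    nullBySize[[as.character(sz)]] <- null
  }
  es <- vapply(inset, function(s)
    enrichmentScore(ranked, s, weight)$es, 0)
  nes <- p <- numeric(length(es))
  for (i in seq_along(es)) {
    null <- nullBySize[[as.character(sizes[i])]]
    same <- null[sign(null) == sign(es[i])]
    if (!length(same)) {
      nes[i] <- NA_real_
      p[i] <- 1 / (1 + 0)
    } else {
      nes[i] <- es[i] / mean(abs(same))
      p[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
    }
  }
  out <- data.frame(set = names(inset), size = as.integer(sizes), es = es,
                    nes = nes, p_value = p,
                    p_adjusted = stats::p.adjust(p, method = "BH"))
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.saveRng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restoreRng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
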