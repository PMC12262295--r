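## Cross-tissue / cross-method overlap analytics and the genotype
## correlation check.

#' Fraction of a focal tissue's genes shared with at least one other tissue
#'
#' @param sets Named list of gene-identifier character vectors, one per
#'   tissue.
#' @param focal Name of the focal tissue (must be in `names(sets)`).
#' @return A list with `numerator`, `denominator` and `fraction` (NA
#'   sentinel when the focal set is empty).
#' @examples
#' sharedFraction(list(SG = c("a", "b", "c", "d"), tr = "a", fb = "e"), "SG")
#' @export
sharedFraction <- function(sets, focal) {
  if (!focal %in% names(sets))
    stop("sharedFraction: focal tissue not in sets", call. = FALSE)
  fset <- unique(sets[[focal]])
  others <- unique(unlist(sets[setdiff(names(sets), focal)], use.names = FALSE))
  num <- length(intersect(fset, others))
  list(numerator = num, denominator = length(fset),
       fraction = if (length(fset) == 0L) NA_real_ else num / length(fset))
}

#' Exclusive Venn region counts for up to three gene sets
#'
#' Each gene of the union is counted in exactly one region, keyed by the
#' membership pattern over the input sets (e.g. `"A"`, `"A&B"`, `"A&B&C"`).
#' Region counts therefore sum to the union size.
#'
#' @param sets Named list of 1-3 character vectors.
#' @return Named integer vector over all 2^k - 1 non-empty membership
#'   patterns (zero counts included).
#' @export
vennCounts <- function(sets) {
  k <- length(sets)
  if (k < 1L || k > 3L)
    stop("vennCounts: supply 1-3 sets (use pairwise mode beyond 3)",
         call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- LETTERS[seq_len(k)]
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  out <- integer(nrow(patterns))
  labs <- character(nrow(patterns))
  for (i in seq_len(nrow(patterns))) {
    pat <- as.logical(patterns[i, ])
    labs[i] <- paste(names(sets)[pat], collapse = "&")
    if (length(universe))
      out[i] <- sum(apply(member, 1L, function(r) all(r == pat)))
  }
  stats::setNames(out, labs)
}

#' Average expression per cell type
#'
#' @param expr Numeric matrix, genes in rows, cells in columns.
#' @param labels Character vector of cell-type labels, one per column.
#' @return Gene-by-type matrix of arithmetic means; types with zero cells
#'   cannot occur (every label present has at least one cell), but a label
#'   level with no cells after factoring is dropped with a warning.
#' @export
avgExpressionByType <- function(expr, labels) {
  if (ncol(expr) != length(labels))
    stop("avgExpressionByType: one label per cell required", call. = FALSE)
  types <- unique(labels)
  out <- vapply(types, function(t)
    rowMeans(expr[, labels == t, drop = FALSE]), numeric(nrow(expr)))
  if (nrow(expr) == 1L) out <- matrix(out, nrow = 1L,
                                      dimnames = list(rownames(expr), types))
  colnames(out) <- types
  rownames(out) <- rownames(expr)
  out
}

#' Spearman correlation of matched cell-type expression profiles
#'
#' For each matched type, the profiles are restricted to the shared gene
#' universe (genes present in both matrices and with mean expression > 0 in
#' at least one genotype for that type) and rank-correlated with
#' average-rank tie handling.
#'
#' @param avgWt,avgMut Gene-by-type matrices ([avgExpressionByType()]),
#'   rownames = gene identifiers.
#' @param typePairs Character vector of type labels present in both
#'   matrices (default: their common columns).
#' @return A `data.frame` with `type`, `rho` (NA sentinel when fewer than 3
#'   shared genes) and `n_genes`.
#' @export
celltypeSpearman <- function(avgWt, avgMut,
                             typePairs = intersect(colnames(avgWt),
                                                   colnames(avgMut))) {
  shared <- intersect(rownames(avgWt), rownames(avgMut))
  out <- data.frame(type = typePairs, rho = NA_real_,
                    n_genes = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(typePairs)) {
    t <- typePairs[i]
    wt <- avgWt[shared, t]; mut <- avgMut[shared, t]
    keep <- wt > 0 | mut > 0
    out$n_genes[i] <- sum(keep)
    if (sum(keep) >= 3L)
      out$rho[i] <- stats::cor(wt[keep], mut[keep], method = "spearman")
  }
  out
}
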