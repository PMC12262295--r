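## Target classification: the three-evidence activation rule, the
## scRNA-only repression rule, the 150-least-changed "unchanged" class, and
## the bound-by-regulated network summary.

#' Classification thresholds
#'
#' All inequalities downstream are strict, exactly as the rules are written:
#' activated needs `log_fc < lfcDown` and `p_value < pMax`; repressed needs
#' `log_fc > lfcUp` and `p_value < pMax`; the microarray route needs
#' `fold_change < microarrayFc`, microarray `p < microarrayP`, wild-type
#' percent expressing `> pctWtMin` and focal `log_fc < 0`.
#'
#' @param lfcDown Down-regulation logFC threshold (default -0.15).
#' @param lfcUp Up-regulation logFC threshold (default +0.15).
#' @param pMax p-value threshold (default 0.05).
#' @param microarrayFc Microarray linear fold-change threshold (default -1.25).
#' @param microarrayP Microarray p-value threshold (default 0.05).
#' @param pctWtMin Minimum percent of wild-type focal-tissue cells expressing
#'   the gene for the microarray route (default 10, strict `>`).
#' @param unchangedN Size of the least-changed "unchanged" class (default 150).
#' @param adjustP Apply Benjamini-Hochberg to the focal DE p-values before
#'   thresholding (default `FALSE`: raw p-values, as the rules state them).
#' @return A named list of thresholds with class `"ClassificationThresholds"`.
#' @export
classificationThresholds <- function(lfcDown = -0.15, lfcUp = 0.15,
                                     pMax = 0.05, microarrayFc = -1.25,
                                     microarrayP = 0.05, pctWtMin = 10,
                                     unchangedN = 150L, adjustP = FALSE) {
  stopifnot(lfcDown < 0, lfcUp > 0, pMax > 0, pMax < 1,
            microarrayFc < 0, unchangedN > 0)
  structure(list(lfcDown = lfcDown, lfcUp = lfcUp, pMax = pMax,
                 microarrayFc = microarrayFc, microarrayP = microarrayP,
                 pctWtMin = pctWtMin, unchangedN = as.integer(unchangedN),
                 adjustP = isTRUE(adjustP)),
            class = "ClassificationThresholds")
}

.focalP <- function(de, thr) {
  if (thr$adjustP) stats::p.adjust(de$p_value, method = "BH") else de$p_value
}

#' Classify activated genes by the three-evidence union rule
#'
#' A gene is activated iff it satisfies any route:
#' \enumerate{
#'   \item scRNA: focal `log_fc < lfcDown` and `p_value < pMax`;
#'   \item in-situ: membership in the curated in-situ-validated list;
#'   \item microarray: `fold_change < microarrayFc` and microarray
#'     `p_value < microarrayP`, and in the focal DE table
#'     `pct_wt > pctWtMin` and `log_fc < 0`. A microarray gene absent from
#'     the focal DE table fails this route closed.
#' }
#' Every satisfied route is recorded as an evidence flag.
#'
#' @param deFocal Focal-tissue DE `data.frame` ([readDETable()] columns).
#' @param insitu Character vector of in-situ-validated activated genes.
#' @param microarray Microarray `data.frame` ([readMicroarrayTable()]
#'   columns), or `NULL`.
#' @param thr [classificationThresholds()].
#' @return A `data.frame` with columns `gene_id`, `scrna`, `insitu`,
#'   `microarray` (logical evidence flags), one row per activated gene.
#' @export
classifyActivated <- function(deFocal, insitu = character(0),
                              microarray = NULL,
                              thr = classificationThresholds()) {
  p <- .focalP(deFocal, thr)
  scrna_genes <- deFocal$gene_id[deFocal$log_fc < thr$lfcDown & p < thr$pMax]
  ma_genes <- character(0)
  if (!is.null(microarray) && nrow(microarray)) {
    ma_hit <- microarray$gene_id[microarray$fold_change < thr$microarrayFc &
                                 microarray$p_value < thr$microarrayP]
    present <- ma_hit %in% deFocal$gene_id
    if (any(!present))
      message(sprintf(
        "classifyActivated: %d microarray gene(s) absent from focal DE table; microarray route fails closed for them",
        sum(!present)))
    ma_hit <- ma_hit[present]
    idx <- match(ma_hit, deFocal$gene_id)
    keep <- deFocal$pct_wt[idx] > thr$pctWtMin & deFocal$log_fc[idx] < 0
    ma_genes <- ma_hit[keep]
  }
  genes <- sort(unique(c(scrna_genes, insitu, ma_genes)))
  data.frame(gene_id = genes,
             scrna = genes %in% scrna_genes,
             insitu = genes %in% insitu,
             microarray = genes %in% ma_genes)
}

#' Classify repressed genes (scRNA evidence only)
#'
#' @inheritParams classifyActivated
#' @return Sorted character vector of repressed gene identifiers.
#' @export
classifyRepressed <- function(deFocal, thr = classificationThresholds()) {
  p <- .focalP(deFocal, thr)
  sort(unique(deFocal$gene_id[deFocal$log_fc > thr$lfcUp & p < thr$pMax]))
}

#' Resolve activated/repressed conflicts
#'
#' A gene can reach the activated set through the in-situ or microarray
#' route while also meeting the scRNA repression rule. Such genes are
#' called conflicts, removed from both sets, and reported; silent
#' precedence would bias the network fractions.
#'
#' @param activated Output of [classifyActivated()].
#' @param repressed Output of [classifyRepressed()].
#' @return A list with elements `activated` (data.frame), `repressed`
#'   (character) and `conflict` (character).
#' @export
resolveCallConflicts <- function(activated, repressed) {
  conflict <- intersect(activated$gene_id, repressed)
  if (length(conflict))
    warning(sprintf("conflicting activated/repressed calls excluded: %s",
                    paste(conflict, collapse = ", ")))
  list(activated = activated[!activated$gene_id %in% conflict, , drop = FALSE],
       repressed = setdiff(repressed, conflict),
       conflict = conflict)
}

#' Select the n least differentially expressed ("unchanged") genes
#'
#' The `n` genes with smallest absolute focal logFC. Ties at the cutoff are
#' broken by larger p-value first (the less significant gene is the more
#' plausibly unchanged one), then by `gene_id`.
#'
#' @inheritParams classifyActivated
#' @param n Number of genes to select (default `thr$unchangedN`).
#' @param exclude Genes removed from the pool before selection (pass the
#'   activated and repressed calls to guarantee the unchanged class is
#'   disjoint from both).
#' @return Character vector of `n` gene identifiers (all genes, with a
#'   warning, if the table is smaller than `n`).
#' @export
selectUnchanged <- function(deFocal, thr = classificationThresholds(),
                            n = thr$unchangedN, exclude = character(0)) {
  deFocal <- deFocal[!deFocal$gene_id %in% exclude, , drop = FALSE]
  ord <- order(abs(deFocal$log_fc), -deFocal$p_value, deFocal$gene_id)
  if (nrow(deFocal) < n) {
    warning(sprintf("selectUnchanged: only %d genes available (requested %d)",
                    nrow(deFocal), n))
    n <- nrow(deFocal)
  }
  deFocal$gene_id[ord[seq_len(n)]]
}

#' RegulatoryNetwork: bound-by-regulated network with summary fractions
#'
#' Container for the direct regulatory network: the bound, activated and
#' repressed gene sets, their intersections, the conflict set, and the
#' headline fractions (each kept with its numerator and denominator).
#'
#' @slot bound Character vector of bound genes.
#' @slot activated Character vector of activated genes (post conflict
#'   resolution).
#' @slot repressed Character vector of repressed genes.
#' @slot conflict Genes excluded for conflicting activation/repression calls.
#' @slot evidence data.frame of per-activated-gene evidence flags.
#' @slot spcg Curated secretory-pathway component gene list (may be empty).
#' @slot fractions Named list of numerator/denominator/value triples.
#' @export
setClass("RegulatoryNetwork",
         representation(bound = "character", activated = "character",
                        repressed = "character", conflict = "character",
                        evidence = "data.frame", spcg = "character",
                        fractions = "list"),
         validity = function(object) {
           msg <- character(0)
           if (length(intersect(object@activated, object@repressed)))
             msg <- c(msg, "activated and repressed sets must be disjoint")
           for (f in object@fractions) {
             if (!is.na(f$value) && (f$value < 0 || f$value > 1))
               msg <- c(msg, "fractions must lie in [0, 1] (or NA sentinel)")
           }
           if (length(msg)) msg else TRUE
         })

.fraction <- function(num, den) {
  list(numerator = num, denominator = den,
       value = if (den == 0) NA_real_ else num / den)
}

#' Build the regulatory network from bound and regulated gene sets
#'
#' Computes `bound_activated = bound intersect activated`,
#' `bound_repressed = bound intersect repressed`, and the summary fractions:
#' fraction of bound genes that are regulated, fraction of activated (and of
#' repressed) genes that are bound, plus the SPCG bound and bound-and-down
#' counts. An empty bound set yields `NA` fraction sentinels, never 0.
#'
#' @param bound Character vector of bound genes ([boundGenes()]).
#' @param activated Output of [classifyActivated()] (or a data.frame with at
#'   least `gene_id`).
#' @param repressed Character vector from [classifyRepressed()].
#' @param spcg Curated SPCG gene list (character, may be empty).
#' @return A [RegulatoryNetwork-class] object.
#' @export
buildNetwork <- function(bound, activated, repressed,
                         spcg = character(0)) {
  if (is.character(activated))
    activated <- data.frame(gene_id = activated,
                            scrna = TRUE, insitu = FALSE, microarray = FALSE)
  res <- resolveCallConflicts(activated, repressed)
  act <- sort(unique(res$activated$gene_id))
  rep_ <- sort(unique(res$repressed))
  bound <- sort(unique(bound))
  regulated <- union(act, rep_)
  fr <- list(
    fraction_bound_regulated =
      .fraction(length(intersect(bound, regulated)), length(bound)),
    fraction_activated_bound =
      .fraction(length(intersect(bound, act)), length(act)),
    fraction_repressed_bound =
      .fraction(length(intersect(bound, rep_)), length(rep_)),
    spcg_bound_count =
      list(numerator = length(intersect(spcg, bound)),
           denominator = length(spcg),
           value = NA_real_),
    spcg_bound_down_count =
      list(numerator = length(Reduce(intersect, list(spcg, bound, act))),
           denominator = length(spcg),
           value = NA_real_))
  fr$spcg_bound_count$value <-
    if (length(spcg)) fr$spcg_bound_count$numerator / length(spcg) else NA_real_
  fr$spcg_bound_down_count$value <-
    if (length(spcg)) fr$spcg_bound_down_count$numerator / length(spcg) else NA_real_
  methods::new("RegulatoryNetwork", bound = bound, activated = act,
               repressed = rep_, conflict = res$conflict,
               evidence = res$activated, spcg = sort(unique(spcg)),
               fractions = fr)
}

#' @describeIn RegulatoryNetwork-class Bound gene set.
#' @param x,object A `RegulatoryNetwork`.
#' @export
setGeneric("networkBound", function(x) standardGeneric("networkBound"))
#' @rdname RegulatoryNetwork-class
#' @export
setMethod("networkBound", "RegulatoryNetwork", function(x) x@bound)

#' @describeIn RegulatoryNetwork-class Activated gene set.
#' @export
setGeneric("networkActivated", function(x) standardGeneric("networkActivated"))
#' @rdname RegulatoryNetwork-class
#' @export
setMethod("networkActivated", "RegulatoryNetwork", function(x) x@activated)

#' @describeIn RegulatoryNetwork-class Repressed gene set.
#' @export
setGeneric("networkRepressed", function(x) standardGeneric("networkRepressed"))
#' @rdname RegulatoryNetwork-class
#' @export
setMethod("networkRepressed", "RegulatoryNetwork", function(x) x@repressed)

#' @describeIn RegulatoryNetwork-class Bound-and-activated gene set.
#' @export
setGeneric("boundActivated", function(x) standardGeneric("boundActivated"))
#' @rdname RegulatoryNetwork-class
#' @export
setMethod("boundActivated", "RegulatoryNetwork",
          function(x) intersect(x@bound, x@activated))

#' @describeIn RegulatoryNetwork-class Bound-and-repressed gene set.
#' @export
setGeneric("boundRepressed", function(x) standardGeneric("boundRepressed"))
#' @rdname RegulatoryNetwork-class
#' @export
setMethod("boundRepressed", "RegulatoryNetwork",
          function(x) intersect(x@bound, x@repressed))

#' @describeIn RegulatoryNetwork-class Summary fractions, each a
#'   numerator/denominator/value triple.
#' @export
setGeneric("networkFractions", function(x) standardGeneric("networkFractions"))
#' @rdname RegulatoryNetwork-class
#' @export
setMethod("networkFractions", "RegulatoryNetwork", function(x) x@fractions)

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("show", "RegulatoryNetwork", function(object) {
  fr <- object@fractions
  cat("RegulatoryNetwork\n")
  cat(sprintf("  bound genes:      %d\n", length(object@bound)))
  cat(sprintf("  activated:        %d (bound: %d)\n",
              length(object@activated),
              fr$fraction_activated_bound$numerator))
  cat(sprintf("  repressed:        %d (bound: %d)\n",
              length(object@repressed),
              fr$fraction_repressed_bound$numerator))
  if (length(object@conflict))
    cat(sprintf("  conflicts:        %d\n", length(object@conflict)))
  v <- fr$fraction_bound_regulated$value
  cat(sprintf("  bound regulated:  %s (%d/%d)\n",
              ifelse(is.na(v), "NA", sprintf("%.1f%%", 100 * v)),
              fr$fraction_bound_regulated$numerator,
              fr$fraction_bound_regulated$denominator))
  if (length(object@spcg))
    cat(sprintf("  SPCGs bound:      %d/%d (bound & down: %d)\n",
                fr$spcg_bound_count$numerator, length(object@spcg),
                fr$spcg_bound_down_count$numerator))
  invisible(object)
})
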