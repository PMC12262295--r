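## Peak intersection and peak-to-gene assignment.
##
## The peak "center" follows the 0-based rule floor((start0 + end0) / 2);
## on the internal 1-based closed GRanges frame that is
## floor((start1 - 1 + end1) / 2) + 1, and all TSS distances are identical
## in either frame.

#' Intersect two peak sets, keeping the original entries of the first
#'
#' A peak from `setA` is retained (unmodified, at most once, in input
#' order) iff it shares at least one base with any peak of `setB`. This is
#' the "keep original entry" intersection used to restrict binding to the
#' tissue where both drivers are active.
#'
#' @param setA,setB Peak `GRanges` (as from [readNarrowPeak()]).
#' @return The retained subset of `setA`.
#' @examples
#' a <- GenomicRanges::GRanges("chrX", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chrX", IRanges::IRanges(151, 250))
#' intersectKeepA(a, b)
#' @export
intersectKeepA <- function(setA, setB) {
  if (length(setA) == 0L || length(setB) == 0L) return(setA[integer(0)])
  hits <- GenomicRanges::findOverlaps(setA, setB, minoverlap = 1L,
                                      ignore.strand = TRUE)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  setA[keep]
}

#' Peak centers
#'
#' Center of a peak interval, defined as floor((start + end) / 2) on the
#' 0-based half-open frame, returned as a 1-based position. The narrowPeak
#' summit offset is deliberately ignored: assignment is center-based.
#'
#' @param peaks A peak `GRanges`.
#' @return Integer vector of 1-based center positions, one per peak.
#' @export
peakCenters <- function(peaks) {
  s0 <- GenomicRanges::start(peaks) - 1L
  e0 <- GenomicRanges::end(peaks)
  as.integer(floor((s0 + e0) / 2) + 1L)
}

#' Assign intersected peaks to genes by nearest 5'-most TSS per side
#'
#' For every peak center, at most one gene whose TSS lies at or left of the
#' center (the closest such) and at most one gene whose TSS lies right of
#' the center (the closest such) are assigned, each only if strictly closer
#' than `maxDistance` bases. A TSS exactly at the center is the left-side
#' candidate at distance 0. "Left/right" is genomic position around the
#' center, not gene strand (strand is consumed only when the TSS itself is
#' derived). Ties on a side are broken by lexicographically smaller
#' `gene_id`, with a warning.
#'
#' @param peaks Intersected peak `GRanges`.
#' @param tss TSS `GRanges` from [geneTssTable()].
#' @param maxDistance Strict distance cutoff in bases (default 1000).
#' @return A `data.frame` with columns `peak` (index into `peaks`), `name`,
#'   `chrom`, `center` (1-based), `gene_id`, `distance`, `side`
#'   (`"left"`/`"right"` of the center).
#' @export
assignPeaks <- function(peaks, tss, maxDistance = 1000L) {
  stopifnot(maxDistance >= 0)
  empty <- data.frame(peak = integer(0), name = character(0),
                      chrom = character(0), center = integer(0),
                      gene_id = character(0), distance = integer(0),
                      side = character(0))
  if (length(tss) == 0L) {
    warning("assignPeaks: empty TSS table; no assignments")
    return(empty)
  }
  if (length(peaks) == 0L) return(empty)
  centers <- peakCenters(peaks)
  pchrom <- as.character(GenomicRanges::seqnames(peaks))
  tchrom <- as.character(GenomicRanges::seqnames(tss))
  tpos <- GenomicRanges::start(tss)
  tgene <- tss$gene_id
  pname <- if (!is.null(peaks$name)) peaks$name else
    paste0("peak", seq_along(peaks))
  rows <- vector("list", length(peaks))
  tied <- FALSE
  for (i in seq_along(peaks)) {
    onchrom <- which(tchrom == pchrom[i])
    if (!length(onchrom)) next
    d <- tpos[onchrom] - centers[i]
    picks <- list()
    for (side in c("left", "right")) {
      cand <- if (side == "left") onchrom[d <= 0] else onchrom[d > 0]
      if (!length(cand)) next
      dist <- abs(tpos[cand] - centers[i])
      best <- dist == min(dist)
      if (sum(best) > 1L) tied <- TRUE
      pick <- cand[best][order(tgene[cand[best]])][1L]
      pdist <- abs(tpos[pick] - centers[i])
      if (pdist < maxDistance)
        picks[[side]] <- data.frame(
          peak = i, name = pname[i], chrom = pchrom[i], center = centers[i],
          gene_id = tgene[pick], distance = pdist, side = side)
    }
    if (length(picks)) rows[[i]] <- do.call(rbind, picks)
  }
  if (tied)
    warning("assignPeaks: equidistant TSS tie broken by smaller gene_id")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) empty else {
    rownames(out) <- NULL
    out
  }
}

#' Bound genes: distinct genes across all peak assignments
#'
#' @param assignments Output of [assignPeaks()].
#' @return Sorted character vector of distinct `gene_id`s; a gene hit by
#'   several peaks is counted once.
#' @export
boundGenes <- function(assignments) {
  sort(unique(assignments$gene_id))
}

#' Histogram of signed center-to-TSS distances
#'
#' Signed distance is `center - tss` in bases (negative: TSS right of the
#' center). Bins are left-closed, right-open, anchored at 0.
#'
#' @param assignments Output of [assignPeaks()], joined back to signed
#'   distances via the `side` column (`left` means TSS at or left of the
#'   center, i.e. signed distance `>= 0`).
#' @param binWidth Bin width in bases (> 0).
#' @param maxDistance The assignment cutoff; support is
#'   (-maxDistance, +maxDistance).
#' @return A `data.frame` with `bin_start`, `bin_end` and `count`; counts
#'   sum to `nrow(assignments)`.
#' @export
tssDistanceHistogram <- function(assignments, binWidth = 100L,
                                 maxDistance = 1000L) {
  stopifnot(binWidth > 0)
  edges <- seq(-ceiling(maxDistance / binWidth) * binWidth,
               ceiling(maxDistance / binWidth) * binWidth, by = binWidth)
  signed <- ifelse(assignments$side == "left",
                   assignments$distance, -assignments$distance)
  idx <- findInterval(signed, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1L],
             count = counts)
}
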