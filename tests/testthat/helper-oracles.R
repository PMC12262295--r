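# Independent brute-force oracles and small random-input builders.
# Oracles deliberately avoid the package's code paths (plain data frames,
# all-pairs loops) so the tests are dual-route checks.

randomPeaks <- function(n, chroms = c("chr1", "chr2"), maxPos = 10000L,
                        width = c(20L, 400L)) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(maxPos, n, replace = TRUE)
  w <- sample(width[1]:width[2], n, replace = TRUE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + w - 1L))
  gr$name <- sprintf("p%04d", seq_len(n))
  gr$score <- 0L
  gr$signalValue <- round(stats::runif(n, 0, 50), 3)
  gr$pValueLog <- round(stats::runif(n, 0, 10), 3)
  gr$qValueLog <- rep(-1, n)
  gr$summitOffset <- as.integer(floor(w / 2))
  gr
}

randomTss <- function(n, chroms = c("chr1", "chr2"), maxPos = 10000L) {
  gr <- GenomicRanges::GRanges(
    sample(chroms, n, replace = TRUE),
    IRanges::IRanges(sample.int(maxPos, n), width = 1L),
    sample(c("+", "-"), n, replace = TRUE))
  gr$gene_id <- sprintf("g%04d", seq_len(n))
  names(gr) <- gr$gene_id
  gr
}

# all-pairs overlap scan on plain vectors
bruteIntersectKeepA <- function(a, b) {
  ac <- as.character(GenomicRanges::seqnames(a))
  bc <- as.character(GenomicRanges::seqnames(b))
  as_ <- GenomicRanges::start(a); ae <- GenomicRanges::end(a)
  bs <- GenomicRanges::start(b); be <- GenomicRanges::end(b)
  keep <- vapply(seq_along(a), function(i)
    any(bc == ac[i] & bs <= ae[i] & be >= as_[i]), TRUE)
  a[keep]
}

# exhaustive nearest-per-side scan
bruteAssign <- function(peaks, tss, maxDistance) {
  centers <- peakCenters(peaks)
  pc <- as.character(GenomicRanges::seqnames(peaks))
  tc <- as.character(GenomicRanges::seqnames(tss))
  tp <- GenomicRanges::start(tss)
  out <- list()
  for (i in seq_along(peaks)) {
    for (side in c("left", "right")) {
      idx <- if (side == "left") which(tc == pc[i] & tp <= centers[i])
             else which(tc == pc[i] & tp > centers[i])
      if (!length(idx)) next
      d <- abs(tp[idx] - centers[i])
      cand <- idx[d == min(d)]
      pick <- cand[order(tss$gene_id[cand])][1]
      if (abs(tp[pick] - centers[i]) < maxDistance)
        out[[length(out) + 1L]] <- data.frame(
          peak = i, gene_id = tss$gene_id[pick],
          distance = abs(tp[pick] - centers[i]), side = side)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(peak = integer(0), gene_id = character(0),
               distance = integer(0), side = character(0))
}

# inclusion-exclusion region counts
bruteVenn <- function(sets) {
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  k <- length(sets)
  pats <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  counts <- integer(nrow(pats))
  labs <- character(nrow(pats))
  for (r in seq_len(nrow(pats))) {
    pat <- as.logical(pats[r, ])
    labs[r] <- paste(names(sets)[pat], collapse = "&")
    counts[r] <- sum(vapply(universe, function(g) {
      all(vapply(seq_len(k), function(j)
        (g %in% sets[[j]]) == pat[j], TRUE))
    }, TRUE))
  }
  stats::setNames(counts, labs)
}

# per-gene boolean evaluation of the three-route activation rule
bruteActivated <- function(de, insitu, ma, thr) {
  hits <- character(0)
  for (i in seq_len(nrow(de))) {
    g <- de$gene_id[i]
    act <- (de$log_fc[i] < thr$lfcDown && de$p_value[i] < thr$pMax) ||
      (g %in% insitu)
    if (!act && !is.null(ma) && g %in% ma$gene_id) {
      j <- which(ma$gene_id == g)[1]
      act <- ma$fold_change[j] < thr$microarrayFc &&
        ma$p_value[j] < thr$microarrayP &&
        de$pct_wt[i] > thr$pctWtMin && de$log_fc[i] < 0
    }
    if (act) hits <- c(hits, g)
  }
  # genes only in the microarray table and absent from DE never qualify
  sort(unique(hits))
}

# full-sort selection of the n least-changed genes
bruteUnchanged <- function(de, n) {
  df <- de[order(abs(de$log_fc), -de$p_value, de$gene_id), ]
  df$gene_id[seq_len(min(n, nrow(df)))]
}

# per-sequence word containment by raw string scanning (both strands)
bruteWordCounts <- function(word, seqs) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(word, "")[[1]]),
                                     collapse = ""))
  sum(vapply(as.character(seqs), function(s)
    grepl(word, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE), TRUE))
}

# step-by-step running sum written independently of .runningSum
bruteES <- function(stats, geneSet, weight = 1) {
  stats <- stats[order(-stats)]
  N <- length(stats)
  hit <- names(stats) %in% geneSet
  nr <- sum(abs(stats[hit])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (nr > 0) abs(stats[i])^weight / nr else 1 / sum(hit)
    } else -1 / (N - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# exhaustive offset/orientation PWM scan, written directly from the score
# definition (query column i aligned to target column i + offset)
brutePwmScore <- function(query, target, minOverlap = 4L) {
  rcq <- query[4:1, rev(seq_len(ncol(query))), drop = FALSE]
  best <- -Inf
  for (q in list(query, rcq)) {
    for (off in -(ncol(q)):ncol(target)) {
      pairs <- list()
      for (i in seq_len(ncol(q))) {
        j <- i + off
        if (j >= 1 && j <= ncol(target)) pairs[[length(pairs) + 1L]] <- c(i, j)
      }
      if (length(pairs) < minOverlap) next
      cors <- vapply(pairs, function(pr) {
        x <- q[, pr[1]]; y <- target[, pr[2]]
        if (stats::sd(x) == 0 || stats::sd(y) == 0)
          return(if (isTRUE(all.equal(x, y))) 1 else 0)
        stats::cor(x, y)
      }, 0)
      best <- max(best, mean(cors))
    }
  }
  best
}

randomPwm <- function(w) {
  m <- matrix(stats::runif(4 * w), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  m
}

randomSeqs <- function(n, len) {
  Biostrings::DNAStringSet(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), ""))
}

# small, fast bundle configuration reused across tests
smallBundleConfig <- function(seed = 1L, ...) {
  args <- list(seed = seed, nChroms = 2L, chromLength = 200000L,
               nGenes = 50L, nTrueTargets = 20L, nDecoyBound = 10L,
               nSpcg = 12L, nUnsharedPeaks = 5L)
  over <- list(...)
  args[names(over)] <- over
  do.call(syntheticConfig, args)
}

smallThresholds <- function(...) classificationThresholds(unchangedN = 15L, ...)

# binding + classification only (no motif/GSEA), for recovery measurements
classifyBundle <- function(bundle, thr = classificationThresholds()) {
  p <- bundle$paths
  peaksA <- readNarrowPeak(p$peaks_a)
  peaksB <- readNarrowPeak(p$peaks_b)
  tss <- geneTssTable(readTranscriptsGTF(p$annotation))
  assignments <- suppressWarnings(
    assignPeaks(intersectKeepA(peaksA, peaksB), tss))
  de <- readDETable(p$de)
  deFocal <- de[de$tissue == bundle$truth$focal_tissue, ]
  activated <- classifyActivated(deFocal, readGeneList(p$insitu),
                                 readMicroarrayTable(p$microarray), thr)
  repressed <- classifyRepressed(deFocal, thr)
  suppressWarnings(buildNetwork(boundGenes(assignments), activated,
                                repressed, readGeneList(p$spcg)))
}
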