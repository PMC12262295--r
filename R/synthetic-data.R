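## Seeded synthetic input bundle with planted ground truth: a small
## multi-chromosome genome, stranded multi-transcript gene models, two
## partially overlapping driver peak sets concentrated at the promoters of
## planted target genes, per-tissue DE tables, a whole-embryo microarray
## table, in-situ/SPCG side lists, a gene-set collection and a truth file.
## Every downstream stage of the pipeline is exercisable on the bundle with
## no external data.

#' Synthetic bundle configuration
#'
#' Defaults define the package's reference simulation conditions (see the
#' methods vignette for rationale). The planted motif is a CRE-like
#' placeholder word, not any experimentally determined consensus.
#'
#' @param seed Integer seed; the bundle is a deterministic function of the
#'   full configuration.
#' @param nChroms,chromLength Genome shape (default 3 x 500 kb).
#' @param nGenes Number of genes (default 200).
#' @param transcriptsPerGeneMax Max transcripts per gene (default 3).
#' @param nTrueTargets Genes both bound and regulated (default 30).
#' @param fractionActivated Fraction of true targets that are activated
#'   (default 0.7; the rest are repressed).
#' @param nDecoyBound Bound-but-unregulated genes (default 40).
#' @param peakWidth Peak width in bases (default 200).
#' @param peakJitterSd SD of the peak-center jitter around the TSS
#'   (default 150), truncated so the planted <1 kb rule always holds.
#' @param motif IUPAC word planted in activated-gene promoter windows
#'   (default `"TGACGTCA"`, length >= 4).
#' @param effectSizeLfc Magnitude of the planted log fold change (default
#'   0.5; must exceed the 0.15 classification threshold).
#' @param noiseLfcSd SD of Gaussian noise added to every logFC (default 0).
#' @param nTissues Number of tissues in the DE table (default 5; the first,
#'   `"SG"`, is the focal tissue).
#' @param tissueShare Probability that a true target is also regulated in
#'   at least one non-focal tissue (default 0.79).
#' @param fracInsituOnly,fracMicroarrayOnly Fractions of activated targets
#'   recoverable only through the in-situ or microarray evidence route
#'   (default 0.1 each); their focal logFC stays above the scRNA threshold.
#' @param maFraction Fraction of fully activated targets that also carry
#'   microarray evidence (default 0.6).
#' @param insituExtraFraction Fraction of fully activated targets also put
#'   on the in-situ list (default 0.3).
#' @param bgMotifFraction Fraction of non-activated peak windows that also
#'   receive a planted motif instance (default 0).
#' @param gcBias Shift of the G+C probability away from uniform, in
#'   [0, 0.25) (default 0).
#' @param nSpcg Size of the synthetic SPCG-role list (default 30).
#' @param nUnsharedPeaks Driver-specific peaks per set, placed away from
#'   genes so they drop out at intersection (default 15).
#' @return A validated list with class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(seed = 1L, nChroms = 3L, chromLength = 500000L,
                            nGenes = 200L, transcriptsPerGeneMax = 3L,
                            nTrueTargets = 30L, fractionActivated = 0.7,
                            nDecoyBound = 40L, peakWidth = 200L,
                            peakJitterSd = 150, motif = "TGACGTCA",
                            effectSizeLfc = 0.5, noiseLfcSd = 0,
                            nTissues = 5L, tissueShare = 0.79,
                            fracInsituOnly = 0.1, fracMicroarrayOnly = 0.1,
                            maFraction = 0.6, insituExtraFraction = 0.3,
                            bgMotifFraction = 0, gcBias = 0,
                            nSpcg = 30L, nUnsharedPeaks = 15L) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLength = as.integer(chromLength),
              nGenes = as.integer(nGenes),
              transcriptsPerGeneMax = as.integer(transcriptsPerGeneMax),
              nTrueTargets = as.integer(nTrueTargets),
              fractionActivated = fractionActivated,
              nDecoyBound = as.integer(nDecoyBound),
              peakWidth = as.integer(peakWidth),
              peakJitterSd = peakJitterSd, motif = toupper(motif),
              effectSizeLfc = effectSizeLfc, noiseLfcSd = noiseLfcSd,
              nTissues = as.integer(nTissues), tissueShare = tissueShare,
              fracInsituOnly = fracInsituOnly,
              fracMicroarrayOnly = fracMicroarrayOnly,
              maFraction = maFraction,
              insituExtraFraction = insituExtraFraction,
              bgMotifFraction = bgMotifFraction, gcBias = gcBias,
              nSpcg = as.integer(nSpcg),
              nUnsharedPeaks = as.integer(nUnsharedPeaks))
  if (cfg$nTrueTargets + cfg$nDecoyBound > cfg$nGenes)
    stop("syntheticConfig: nTrueTargets + nDecoyBound must not exceed nGenes",
         call. = FALSE)
  if (nchar(cfg$motif) < 4L)
    stop("syntheticConfig: motif length must be >= 4", call. = FALSE)
  if (!all(strsplit(cfg$motif, "")[[1]] %in% names(.IUPAC)))
    stop("syntheticConfig: motif must be an IUPAC word", call. = FALSE)
  if (cfg$effectSizeLfc <= 0.15)
    stop("syntheticConfig: effectSizeLfc must exceed the 0.15 threshold",
         call. = FALSE)
  if (cfg$fractionActivated < 0 || cfg$fractionActivated > 1 ||
      cfg$gcBias < 0 || cfg$gcBias >= 0.25)
    stop("syntheticConfig: fractionActivated in [0,1], gcBias in [0,0.25)",
         call. = FALSE)
  structure(cfg, class = "SyntheticConfig")
}

.rtruncnorm1 <- function(mean, sd, bound) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (abs(x - mean) <= bound) return(x)
  }
}

#' Plant one concrete motif instance in a promoter window
#'
#' Samples a concrete realisation of the IUPAC word and writes it at a
#' random offset such that the instance lies fully inside
#' `[windowCenter - flank, windowCenter + flank]`. Only the planted
#' positions differ from the input. Uses the current RNG state.
#'
#' @param sequence Chromosome sequence (character or `DNAString`).
#' @param windowCenter 1-based center position.
#' @param motif IUPAC word.
#' @param flank Window half-width (default 250).
#' @return The modified sequence as a character string, with attribute
#'   `"planted_at"` (1-based start of the instance).
#' @export
plantMotif <- function(sequence, windowCenter, motif, flank = 250L) {
  s <- as.character(sequence)
  len <- nchar(motif)
  lo <- windowCenter - flank
  hi <- windowCenter + flank - len + 1L
  if (lo < 1L || windowCenter + flank > nchar(s))
    stop("plantMotif: window out of chromosome bounds", call. = FALSE)
  at <- sample(lo:hi, 1L)
  inst <- paste(vapply(strsplit(toupper(motif), "")[[1]], function(ch) {
    opts <- .IUPAC[[ch]]
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
  substr(s, at, at + len - 1L) <- inst
  attr(s, "planted_at") <- at
  s
}

#' Generate a complete synthetic input bundle
#'
#' Writes, under `dir`: `genome.fa`, `annotation.gtf`,
#' `peaks_driver_a.narrowPeak`, `peaks_driver_b.narrowPeak`,
#' `de_tissues.tsv`, `microarray.tsv`, `insitu.txt`, `spcg.txt`,
#' `genesets.gmt` and `truth.json`. Output is a deterministic function of
#' the configuration (the global RNG state is restored afterwards).
#'
#' For every planted bound gene both peak sets carry a peak whose
#' intersected center lies strictly within 1 kb of the gene's 5'-most TSS;
#' activated targets get focal logFC at or below `-effectSizeLfc` with
#' p < 0.05 (except the configured in-situ-only / microarray-only
#' fractions, which are recoverable only through those evidence routes);
#' repressed targets mirror this with positive logFC; decoy bound genes
#' stay inside (-0.15, 0.15); the motif is planted in the promoter window
#' of every activated target.
#'
#' @param config A [syntheticConfig()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth` (the
#'   planted ground truth, as also serialised to `truth.json`) and
#'   `config`.
#' @export
generateBundle <- function(config = syntheticConfig(), dir = tempfile("bundle")) {
  stopifnot(inherits(config, "SyntheticConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old <- .saveRng()
  on.exit(.restoreRng(old))
  set.seed(config$seed)

  geneSpanMax <- 2000L
  jitterTrunc <- min(700, 1000 - ceiling(config$peakWidth / 2) - 60)
  if (jitterTrunc <= 0)
    stop("generateBundle: peakWidth too large for the <1 kb placement rule",
         call. = FALSE)
  perChrom <- diff(round(seq(0, config$nGenes, length.out = config$nChroms + 1L)))
  geneRegion <- floor(0.80 * config$chromLength)
  spacing <- floor(geneRegion / max(perChrom))
  if (spacing < geneSpanMax + 2L * (1000L + jitterTrunc))
    stop("generateBundle: genome too small to place the requested genes without assignment interference",
         call. = FALSE)

  chroms <- paste0("chr", seq_len(config$nChroms))
  pACGT <- c(A = 0.5 - config$gcBias, C = config$gcBias + 0.25,
             G = config$gcBias + 0.25, T = 0.25 - config$gcBias) /
    (1 + config$gcBias)
  pACGT <- pACGT / sum(pACGT)
  genome <- lapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), config$chromLength,
                 replace = TRUE, prob = pACGT), collapse = ""))
  names(genome) <- chroms

  ## gene models -----------------------------------------------------------
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(config$nGenes)),
                      chrom = rep(chroms, perChrom),
                      slot = unlist(lapply(perChrom, seq_len)),
                      strand = sample(c("+", "-"), config$nGenes,
                                      replace = TRUE))
  genes$tss <- 2000L + (genes$slot - 1L) * spacing +
    sample(0:500, config$nGenes, replace = TRUE)
  gtf <- list()
  for (i in seq_len(config$nGenes)) {
    nTx <- sample.int(config$transcriptsPerGeneMax, 1L)
    span <- sample(1000:geneSpanMax, 1L)
    for (j in seq_len(nTx)) {
      if (genes$strand[i] == "+") {
        s <- genes$tss[i] + if (j == 1L) 0L else sample(1:300, 1L)
        e <- genes$tss[i] + span - sample(0:200, 1L)
      } else {
        e <- genes$tss[i] - if (j == 1L) 0L else sample(1:300, 1L)
        s <- genes$tss[i] - span + sample(0:200, 1L)
      }
      if (s >= e) e <- s + 200L
      gtf[[length(gtf) + 1L]] <- sprintf(
        '%s\tsynth\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t%d";',
        genes$chrom[i], s, e, genes$strand[i], genes$gene_id[i],
        genes$gene_id[i], j)
    }
  }

  ## roles -----------------------------------------------------------------
  shuffled <- sample(genes$gene_id)
  nAct <- round(config$fractionActivated * config$nTrueTargets)
  nRep <- config$nTrueTargets - nAct
  activated <- sort(shuffled[seq_len(nAct)])
  repressed <- sort(shuffled[nAct + seq_len(nRep)])
  decoys <- sort(shuffled[config$nTrueTargets + seq_len(config$nDecoyBound)])
  background <- sort(setdiff(genes$gene_id, c(activated, repressed, decoys)))
  bound <- sort(c(activated, repressed, decoys))
  nInsituOnly <- floor(config$fracInsituOnly * nAct)
  nMaOnly <- floor(config$fracMicroarrayOnly * nAct)
  insituOnly <- activated[seq_len(nInsituOnly)]
  maOnly <- setdiff(activated, insituOnly)[seq_len(nMaOnly)]
  fullAct <- setdiff(activated, c(insituOnly, maOnly))

  ## peaks -----------------------------------------------------------------
  gidx <- match(bound, genes$gene_id)
  peakA <- peakB <- list()
  peakToGene <- list()
  halfW <- floor(config$peakWidth / 2)
  centerA <- integer(length(bound))
  for (k in seq_along(bound)) {
    i <- gidx[k]
    cA <- genes$tss[i] +
      round(.rtruncnorm1(0, config$peakJitterSd, jitterTrunc))
    cB <- cA + round(.rtruncnorm1(0, 30, max(1, halfW - 10L)))
    centerA[k] <- cA
    nameA <- sprintf("peakA_%03d", k)
    peakA[[k]] <- .npLine(genes$chrom[i], cA, config$peakWidth, nameA)
    peakB[[k]] <- .npLine(genes$chrom[i], cB, config$peakWidth,
                          sprintf("peakB_%03d", k))
    peakToGene[[nameA]] <- bound[k]
  }
  ## driver-specific peaks in gene-free territory; they never intersect
  desertA <- floor(0.84 * config$chromLength) + seq(0, by = 2000,
                                                    length.out = config$nUnsharedPeaks)
  desertB <- floor(0.92 * config$chromLength) + seq(0, by = 2000,
                                                    length.out = config$nUnsharedPeaks)
  if (max(desertB) + config$peakWidth >= config$chromLength ||
      max(desertA) >= floor(0.92 * config$chromLength))
    stop("generateBundle: too many driver-specific peaks for the chromosome length",
         call. = FALSE)
  for (k in seq_len(config$nUnsharedPeaks)) {
    ch <- chroms[1L + (k - 1L) %% config$nChroms]
    peakA[[length(peakA) + 1L]] <-
      .npLine(ch, desertA[k], config$peakWidth, sprintf("peakAonly_%03d", k))
    peakB[[length(peakB) + 1L]] <-
      .npLine(ch, desertB[k], config$peakWidth, sprintf("peakBonly_%03d", k))
  }

  ## motif planting --------------------------------------------------------
  motifCenters <- centerA[bound %in% activated]
  motifChroms <- genes$chrom[gidx][bound %in% activated]
  for (k in seq_along(motifCenters))
    genome[[motifChroms[k]]] <-
      as.character(plantMotif(genome[[motifChroms[k]]], motifCenters[k],
                              config$motif))
  if (config$bgMotifFraction > 0) {
    others <- which(!bound %in% activated)
    nBg <- floor(config$bgMotifFraction * length(others))
    for (k in others[seq_len(nBg)])
      genome[[genes$chrom[gidx[k]]]] <-
        as.character(plantMotif(genome[[genes$chrom[gidx[k]]]], centerA[k],
                                config$motif))
  }

  ## DE tables -------------------------------------------------------------
  tissueNames <- c("SG", "trachea", "amnioserosa", "fat_body",
                   "plasmatocytes", paste0("tissue", seq_len(max(0, config$nTissues - 5L))))
  tissueNames <- tissueNames[seq_len(config$nTissues)]
  noise <- function(n) stats::rnorm(n, 0, config$noiseLfcSd)
  eff <- function(n) config$effectSizeLfc * stats::runif(n, 1, 1.8)
  de <- list()
  sharedWith <- list()   # target gene -> non-focal tissues carrying effect
  for (g in c(fullAct, repressed)) {
    if (config$nTissues > 1L && stats::runif(1) < config$tissueShare) {
      m <- sample.int(config$nTissues - 1L, 1L)
      sharedWith[[g]] <- sample(tissueNames[-1L], m)
    } else sharedWith[[g]] <- character(0)
  }
  for (t in tissueNames) {
    lfc <- stats::rnorm(config$nGenes, 0, max(config$noiseLfcSd, 1e-12)) *
      (config$noiseLfcSd > 0)
    p <- stats::runif(config$nGenes)
    pctWt <- stats::runif(config$nGenes, 0, 60)
    focal <- t == tissueNames[1L]
    for (set in list(list(g = fullAct, sgn = -1), list(g = repressed, sgn = 1))) {
      carry <- if (focal) set$g else
        set$g[vapply(set$g, function(g) t %in% sharedWith[[g]], TRUE)]
      idx <- match(carry, genes$gene_id)
      lfc[idx] <- set$sgn * eff(length(idx)) + noise(length(idx))
      p[idx] <- stats::runif(length(idx), 1e-6, 0.04)
      pctWt[idx] <- stats::runif(length(idx), 30, 90)
    }
    if (focal) {
      iIdx <- match(insituOnly, genes$gene_id)
      lfc[iIdx] <- stats::runif(length(iIdx), -0.12, -0.03)
      mIdx <- match(maOnly, genes$gene_id)
      lfc[mIdx] <- stats::runif(length(mIdx), -0.14, -0.04)
      pctWt[mIdx] <- stats::runif(length(mIdx), 25, 85)
      dIdx <- match(decoys, genes$gene_id)
      lfc[dIdx] <- pmax(-0.149, pmin(0.149, noise(length(dIdx))))
    }
    pctMut <- pmax(0, pmin(100, pctWt * stats::runif(config$nGenes, 0.3, 1.4)))
    de[[t]] <- data.frame(gene_id = genes$gene_id, tissue = t,
                          log_fc = round(lfc, 6), p_value = round(p, 8),
                          pct_wt = round(pctWt, 3),
                          pct_mut = round(pctMut, 3))
  }
  deAll <- do.call(rbind, de)

  ## microarray, in-situ, SPCG, gene sets ----------------------------------
  maEvidence <- sort(c(maOnly,
                       fullAct[stats::runif(length(fullAct)) < config$maFraction]))
  maBg <- sample(background, min(30L, max(0L, length(background) - 2L)))
  # pass the fc/p filters but are blocked by the focal logFC < 0 requirement
  blocked <- sample(setdiff(background, maBg),
                    min(2L, length(setdiff(background, maBg))))
  microarray <- rbind(
    data.frame(gene_id = maEvidence,
               fold_change = round(stats::runif(length(maEvidence), -3, -1.5), 4),
               p_value = round(stats::runif(length(maEvidence), 1e-4, 0.01), 8)),
    data.frame(gene_id = blocked,
               fold_change = round(stats::runif(length(blocked), -3, -1.5), 4),
               p_value = round(stats::runif(length(blocked), 1e-4, 0.01), 8)),
    data.frame(gene_id = maBg,
               fold_change = round(sample(c(-1, 1), length(maBg), TRUE) *
                                     stats::runif(length(maBg), 1.01, 1.2), 4),
               p_value = round(stats::runif(length(maBg)), 8)))
  microarray <- microarray[order(microarray$gene_id), ]
  insitu <- sort(unique(c(insituOnly,
                          fullAct[stats::runif(length(fullAct)) <
                                    config$insituExtraFraction])))
  nSpcgAct <- min(length(activated), round(0.6 * config$nSpcg))
  nSpcgDecoy <- min(length(decoys), round(0.25 * config$nSpcg))
  spcg <- sort(c(sample(activated, nSpcgAct), sample(decoys, nSpcgDecoy),
                 sample(background,
                        max(0, config$nSpcg - nSpcgAct - nSpcgDecoy))))
  sets <- list(PLANTED_ACTIVATED = activated, PLANTED_REPRESSED = repressed,
               SPCG_SET = spcg, TINY_SET = sample(genes$gene_id, 5L))
  for (j in seq_len(8L))
    sets[[sprintf("RANDOM_SET_%02d", j)]] <-
      sort(sample(genes$gene_id, sample(10:40, 1L)))

  ## write -----------------------------------------------------------------
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gtf"),
    peaks_a = file.path(dir, "peaks_driver_a.narrowPeak"),
    peaks_b = file.path(dir, "peaks_driver_b.narrowPeak"),
    de = file.path(dir, "de_tissues.tsv"),
    microarray = file.path(dir, "microarray.tsv"),
    insitu = file.path(dir, "insitu.txt"),
    spcg = file.path(dir, "spcg.txt"),
    gmt = file.path(dir, "genesets.gmt"),
    truth = file.path(dir, "truth.json"))
  gseq <- Biostrings::DNAStringSet(unlist(genome))
  names(gseq) <- chroms
  Biostrings::writeXStringSet(gseq, paths$genome, width = 80L)
  writeLines(unlist(gtf), paths$annotation)
  writeLines(unlist(peakA), paths$peaks_a)
  writeLines(unlist(peakB), paths$peaks_b)
  writeDETable(deAll, paths$de)
  utils::write.table(microarray, paths$microarray, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(insitu, paths$insitu)
  writeLines(spcg, paths$spcg)
  writeGmt(sets, paths$gmt)
  truth <- list(bound_genes = bound, activated_genes = activated,
                repressed_genes = repressed, decoy_genes = decoys,
                insitu_only = insituOnly, microarray_only = maOnly,
                peak_to_gene = peakToGene, motif = config$motif,
                focal_tissue = tissueNames[1L])
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, truth = truth, config = config))
}

.npLine <- function(chrom, center, width, name) {
  start0 <- center - 1L - floor(width / 2)   # 0-based start; floor center rule
  sprintf("%s\t%d\t%d\t%s\t0\t.\t%.3f\t%.3f\t-1\t%d",
          chrom, start0, start0 + width, name,
          stats::runif(1, 1, 20), stats::runif(1, 2, 10), floor(width / 2))
}

#' Read a bundle truth file
#' @param path Path to `truth.json`.
#' @return The truth list with character-vector gene sets.
#' @export
readTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
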