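## Full-pipeline orchestration: simulate/load -> intersect -> assign ->
## classify -> network -> overlap -> motif -> gsea, with a provenance
## -stamped report. Every reported fraction carries its numerator and
## denominator, and every number is recomputable from the stage outputs.

#' Build a run configuration
#'
#' @param paths Named list of input paths: `peaks_a`, `peaks_b`,
#'   `annotation` (GTF), `genome` (FASTA), `de` (per-tissue DE TSV),
#'   optional `microarray`, `insitu`, `spcg`, `gmt` (as produced by
#'   [generateBundle()]).
#' @param focalTissue Label of the focal tissue in the DE table (default
#'   `"SG"`).
#' @param maxDistance Peak-to-TSS assignment cutoff in bases (default 1000).
#' @param thresholds [classificationThresholds()].
#' @param motifFlank Window half-width for motif extraction (default 250).
#' @param kMin,kMax Motif word-length range (default 3..8).
#' @param eThreshold Motif class-uniqueness E-value threshold (default 0.05).
#' @param gseaMinSize,gseaMaxSize,nPerm GSEA set-size filter and
#'   permutation count.
#' @param seed Seed for the GSEA permutation null.
#' @param outDir Optional directory for stage outputs and the JSON report.
#' @return A list with class `"RunConfig"`.
#' @export
runConfig <- function(paths, focalTissue = "SG", maxDistance = 1000L,
                      thresholds = classificationThresholds(),
                      motifFlank = 250L, kMin = 3L, kMax = 8L,
                      eThreshold = 0.05, gseaMinSize = 10L,
                      gseaMaxSize = 500L, nPerm = 1000L, seed = 1L,
                      outDir = NULL) {
  need <- c("peaks_a", "peaks_b", "annotation", "de")
  missing <- setdiff(need, names(paths))
  if (length(missing))
    stop("runConfig: missing required paths: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(paths = paths, focalTissue = focalTissue,
                 maxDistance = as.integer(maxDistance),
                 thresholds = thresholds, motifFlank = as.integer(motifFlank),
                 kMin = as.integer(kMin), kMax = as.integer(kMax),
                 eThreshold = eThreshold,
                 gseaMinSize = as.integer(gseaMinSize),
                 gseaMaxSize = as.integer(gseaMaxSize),
                 nPerm = as.integer(nPerm), seed = as.integer(seed),
                 outDir = outDir),
            class = "RunConfig")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the [runConfig()] arguments; `paths` is a mapping
#' of input-file paths, `thresholds` a mapping of
#' [classificationThresholds()] arguments. Explicit function arguments
#' override file keys.
#'
#' @param path Path to the YAML file.
#' @param ... Overrides passed on to [runConfig()].
#' @return A `"RunConfig"`.
#' @export
readRunConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  thr <- do.call(classificationThresholds,
                 if (is.null(y$thresholds)) list() else y$thresholds)
  args <- y[setdiff(names(y), "thresholds")]
  args$thresholds <- thr
  over <- list(...)
  args[names(over)] <- over
  do.call(runConfig, args)
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: read inputs, intersect the driver peak
#' sets (keeping the first driver's entries), derive per-gene 5'-most
#' TSSs, assign intersected peaks to genes, classify
#' activated/repressed/unchanged genes in the focal tissue, build the
#' regulatory network, compute cross-tissue/cross-method overlaps,
#' class-wise motif enrichment, and preranked GSEA on the focal logFC
#' ranking. Missing inputs abort before any stage runs. Identical config
#' and inputs yield an identical report (the `timestamp` field aside).
#'
#' @param config A [runConfig()] (or [readRunConfig()]) object.
#' @return A `RunReport` list: `config` echo, per-input md5 `hashes`,
#'   `counts`, `fractions`, per-stage results (`network`, `overlap`,
#'   `motif`, `gsea`) and accumulated `warnings`. If `config$outDir` is
#'   set, stage outputs (`intersected.narrowPeak`, `assignments.tsv`,
#'   `calls.tsv`, `network.json`, `motif_candidates.tsv`, `gsea.tsv`) and
#'   `report.json` are written there.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  p <- config$paths
  for (key in c("peaks_a", "peaks_b", "annotation", "de")) {
    if (!file.exists(p[[key]]))
      stop("runPipeline: missing input before any stage ran: ", p[[key]],
           call. = FALSE)
  }
  warnings <- character(0)
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  hashes <- vapply(p[vapply(p, function(f) is.character(f) && file.exists(f),
                            TRUE)], function(f) unname(tools::md5sum(f)), "")

  ## binding map
  peaksA <- readNarrowPeak(p$peaks_a)
  peaksB <- readNarrowPeak(p$peaks_b)
  transcripts <- readTranscriptsGTF(p$annotation)
  tss <- geneTssTable(transcripts)
  intersected <- intersectKeepA(peaksA, peaksB)
  assignments <- wcollect(assignPeaks(intersected, tss, config$maxDistance))
  bound <- boundGenes(assignments)

  ## classification
  de <- readDETable(p$de)
  deFocal <- de[de$tissue == config$focalTissue, , drop = FALSE]
  if (nrow(deFocal) == 0L)
    stop("runPipeline: focal tissue absent from DE table: ",
         config$focalTissue, call. = FALSE)
  insitu <- if (!is.null(p$insitu)) readGeneList(p$insitu) else character(0)
  microarray <- if (!is.null(p$microarray)) readMicroarrayTable(p$microarray)
                else NULL
  spcg <- if (!is.null(p$spcg)) readGeneList(p$spcg) else character(0)
  thr <- config$thresholds
  activated <- classifyActivated(deFocal, insitu, microarray, thr)
  repressed <- classifyRepressed(deFocal, thr)
  unchanged <- wcollect(selectUnchanged(
    deFocal, thr, exclude = union(activated$gene_id, repressed)))
  network <- wcollect(buildNetwork(bound, activated, repressed, spcg))

  ## overlap analytics: per-tissue down/up sets and cross-method Venn
  downSets <- lapply(split(de, de$tissue), function(tab)
    tab$gene_id[tab$log_fc < thr$lfcDown & tab$p_value < thr$pMax])
  upSets <- lapply(split(de, de$tissue), function(tab)
    tab$gene_id[tab$log_fc > thr$lfcUp & tab$p_value < thr$pMax])
  overlap <- list(
    shared_down = sharedFraction(downSets, config$focalTissue),
    shared_up = sharedFraction(upSets, config$focalTissue))
  if (!is.null(microarray)) {
    maDown <- microarray$gene_id[microarray$fold_change < thr$microarrayFc &
                                   microarray$p_value < thr$microarrayP]
    overlap$venn_methods <- as.list(vennCounts(list(
      scrna = downSets[[config$focalTissue]], microarray = maDown,
      spcg = spcg)))
  }

  ## motif stage: class windows against the bound-unchanged control
  motif <- NULL
  if (!is.null(p$genome) && file.exists(p$genome)) {
    genome <- readGenomeFasta(p$genome)
    classOf <- function(genes) {
      idx <- unique(assignments$peak[assignments$gene_id %in% genes])
      intersected[idx]
    }
    winAct <- extractWindows(classOf(networkActivated(network)), genome,
                             config$motifFlank)
    winRep <- extractWindows(classOf(networkRepressed(network)), genome,
                             config$motifFlank)
    winUnch <- extractWindows(classOf(unchanged), genome, config$motifFlank)
    if (length(winAct) && length(winRep) && length(winUnch)) {
      candAct <- wcollect(wordEnrichment(winAct, winUnch, config$kMin,
                                         config$kMax))
      candRep <- wcollect(wordEnrichment(winRep, winUnch, config$kMin,
                                         config$kMax))
      unique_ <- classUniqueMotifs(list(activated = candAct,
                                        repressed = candRep),
                                   config$eThreshold)
      topSeed <- candAct$word[1L]
      general <- generalizeWord(topSeed, winAct, winUnch)
      motif <- list(candidates_activated = utils::head(candAct, 25L),
                    candidates_repressed = utils::head(candRep, 25L),
                    top_activated = general,
                    class_unique = unique_,
                    n_windows = c(activated = length(winAct),
                                  repressed = length(winRep),
                                  unchanged = length(winUnch)))
    } else {
      warnings <- c(warnings,
                    "motif stage skipped: a window class is empty")
    }
  }

  ## GSEA on the focal ranking (statistic: -logFC, activated genes top)
  gsea <- NULL
  if (!is.null(p$gmt) && file.exists(p$gmt)) {
    stats <- stats::setNames(-deFocal$log_fc, deFocal$gene_id)
    ranked <- wcollect(makeRankedList(stats))
    sets <- readGmt(p$gmt)
    gsea <- wcollect(gseaPreranked(ranked, sets, config$gseaMinSize,
                                   config$gseaMaxSize, config$nPerm,
                                   seed = config$seed))
  }

  fr <- networkFractions(network)
  report <- list(
    config = config[setdiff(names(config), "outDir")],
    hashes = as.list(hashes),
    counts = list(
      peaks_a = length(peaksA), peaks_b = length(peaksB),
      peaks_intersected = length(intersected),
      assignments = nrow(assignments),
      genes_bound = length(bound),
      genes_activated = length(networkActivated(network)),
      genes_activated_scrna_only = sum(activated$scrna),
      genes_repressed = length(networkRepressed(network)),
      genes_unchanged = length(unchanged),
      bound_activated = fr$fraction_activated_bound$numerator,
      bound_repressed = fr$fraction_repressed_bound$numerator,
      conflicts = length(network@conflict)),
    fractions = fr,
    network = network, overlap = overlap, motif = motif, gsea = gsea,
    assignments = assignments,
    warnings = warnings,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(config$outDir)) .writeRunOutputs(report, intersected, config)
  class(report) <- "RunReport"
  report
}

.writeRunOutputs <- function(report, intersected, config) {
  d <- config$outDir
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  writeNarrowPeak(intersected, file.path(d, "intersected.narrowPeak"))
  utils::write.table(report$assignments, file.path(d, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  net <- report$network
  calls <- rbind(
    data.frame(gene_id = networkActivated(net), call = "activated"),
    data.frame(gene_id = networkRepressed(net), call = "repressed"),
    data.frame(gene_id = net@conflict,
               call = rep("conflict", length(net@conflict))))
  utils::write.table(calls, file.path(d, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    bound = networkBound(net), activated = networkActivated(net),
    repressed = networkRepressed(net),
    bound_activated = boundActivated(net),
    bound_repressed = boundRepressed(net),
    fractions = networkFractions(net)),
    file.path(d, "network.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  if (!is.null(report$motif))
    utils::write.table(report$motif$candidates_activated,
                       file.path(d, "motif_candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$gsea))
    utils::write.table(report$gsea, file.path(d, "gsea.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  slim <- report[c("hashes", "counts", "fractions", "overlap",
                   "warnings", "timestamp")]
  slim$config <- list(
    focal_tissue = config$focalTissue, max_distance = config$maxDistance,
    thresholds = unclass(config$thresholds),
    motif_flank = config$motifFlank, k_min = config$kMin,
    k_max = config$kMax, e_threshold = config$eThreshold,
    gsea_min_size = config$gseaMinSize, gsea_max_size = config$gseaMaxSize,
    n_perm = config$nPerm, seed = config$seed)
  jsonlite::write_json(slim, file.path(d, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(d)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Pipeline run report\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-26s %d\n", nm, x$counts[[nm]]))
  v <- x$fractions$fraction_bound_regulated
  cat(sprintf("  fraction bound regulated   %s (%d/%d)\n",
              ifelse(is.na(v$value), "NA", sprintf("%.3f", v$value)),
              v$numerator, v$denominator))
  if (length(x$warnings))
    cat(sprintf("  warnings: %d\n", length(x$warnings)))
  invisible(x)
}
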