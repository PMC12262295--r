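## Readers/writers for the external formats the pipeline touches.
## Convention: files use BED-style 0-based half-open coordinates (narrowPeak,
## BED12); GTF is 1-based inclusive. Internally everything is GRanges
## (1-based closed); conversion happens only here, at the parser boundary.

.stopIoError <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Read a narrowPeak (BED6+4) file into a GRanges
#'
#' Each line must have exactly 10 tab-separated fields. File 0-based
#' half-open coordinates become 1-based closed GRanges coordinates; the
#' metadata columns keep the narrowPeak semantics: `signalValue`
#' (non-negative enrichment), `pValueLog`/`qValueLog` (-log10 scale, -1 when
#' absent) and `summitOffset` (0-based offset of the summit from the peak
#' start, -1 when absent).
#'
#' @param path Path to a narrowPeak file.
#' @return A `GRanges` in file order with metadata columns `name`, `score`,
#'   `signalValue`, `pValueLog`, `qValueLog`, `summitOffset`.
#' @examples
#' tf <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr2L\t100\t200\tp1\t0\t.\t5.0\t-1\t-1\t50", tf)
#' readNarrowPeak(tf)
#' @export
readNarrowPeak <- function(path) {
  if (!file.exists(path)) .stopIoError("narrowPeak file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.emptyPeakGRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L)) {
    bad <- which(nf != 10L)[1L]
    .stopIoError("narrowPeak parse error at line %d of %s: %d fields, expected 10",
                 bad, path, nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 10L, byrow = TRUE)
  start0 <- suppressWarnings(as.integer(m[, 2L]))
  end0 <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start0) || anyNA(end0)) {
    bad <- which(is.na(start0) | is.na(end0))[1L]
    .stopIoError("narrowPeak parse error at line %d of %s: non-numeric coordinates",
                 bad, path)
  }
  if (any(start0 < 0L) || any(start0 >= end0)) {
    bad <- which(start0 < 0L | start0 >= end0)[1L]
    .stopIoError("narrowPeak validation error at line %d of %s: require 0 <= start < end",
                 bad, path)
  }
  if (any(!nzchar(m[, 1L])))
    .stopIoError("narrowPeak validation error in %s: empty chromosome name", path)
  strand <- m[, 6L]
  if (!all(strand %in% c("+", "-", ".")))
    .stopIoError("narrowPeak validation error in %s: strand must be +, - or .", path)
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1L],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = ifelse(strand == ".", "*", strand))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = m[, 4L],
    score = as.integer(m[, 5L]),
    signalValue = as.numeric(m[, 7L]),
    pValueLog = as.numeric(m[, 8L]),
    qValueLog = as.numeric(m[, 9L]),
    summitOffset = as.integer(m[, 10L]))
  if (any(gr$signalValue < 0))
    .stopIoError("narrowPeak validation error in %s: negative signalValue", path)
  gr
}

.emptyPeakGRanges <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(0), score = integer(0), signalValue = numeric(0),
    pValueLog = numeric(0), qValueLog = numeric(0), summitOffset = integer(0))
  gr
}

#' Write a peak GRanges back to narrowPeak
#'
#' Inverse of [readNarrowPeak()]: 1-based closed GRanges coordinates are
#' written as 0-based half-open, `*` strand as `.`.
#'
#' @param peaks A `GRanges` with the narrowPeak metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNarrowPeak <- function(peaks, path) {
  strand <- as.character(GenomicRanges::strand(peaks))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = peaks$name, score = peaks$score, strand = strand,
    signalValue = peaks$signalValue, pValueLog = peaks$pValueLog,
    qValueLog = peaks$qValueLog, summitOffset = peaks$summitOffset)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Keeps rows whose feature is `transcript` (or `mRNA`) and requires
#' `gene_id` and `transcript_id` attributes. GTF 1-based inclusive
#' coordinates map directly onto GRanges. Unstranded transcripts are
#' rejected: the 5'-most TSS rule needs an orientation.
#'
#' @param path Path to a GTF file.
#' @return A `GRanges` with metadata columns `gene_id` and `transcript_id`.
#' @export
readTranscriptsGTF <- function(path) {
  if (!file.exists(path)) .stopIoError("GTF file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(fields) && any(nf != 9L))
    .stopIoError("GTF parse error at line %d of %s: expected 9 tab-separated fields",
                 which(nf != 9L)[1L], path)
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  keep <- m[, 3L] %in% c("transcript", "mRNA")
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) .stopIoError("GTF %s contains no transcript features", path)
  attr1 <- function(attrs, key) {
    hit <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
    out <- rep(NA_character_, length(attrs))
    ok <- lengths(regmatches(attrs, gregexpr(paste0(key, ' "'), attrs))) > 0
    out[ok] <- sub(paste0('^', key, ' "'), "", sub('"$', "", hit))
    out
  }
  gene_id <- attr1(m[, 9L], "gene_id")
  transcript_id <- attr1(m[, 9L], "transcript_id")
  if (anyNA(gene_id) || anyNA(transcript_id))
    .stopIoError("GTF validation error in %s: missing gene_id/transcript_id attribute",
                 path)
  strand <- m[, 7L]
  if (!all(strand %in% c("+", "-")))
    .stopIoError("GTF validation error in %s: transcripts must be stranded (+/-)",
                 path)
  start <- as.integer(m[, 4L]); end <- as.integer(m[, 5L])
  if (any(start > end))
    .stopIoError("GTF validation error in %s: start > end", path)
  gr <- GenomicRanges::GRanges(m[, 1L], IRanges::IRanges(start, end), strand)
  gr$gene_id <- gene_id
  gr$transcript_id <- transcript_id
  gr
}

#' Read transcript models from a BED12 file
#'
#' The BED12 `name` field is parsed as `gene_id:transcript_id`; a name
#' without a colon is used as both identifiers. Coordinates are converted
#' from 0-based half-open.
#'
#' @param path Path to a BED12 file.
#' @return A `GRanges` with metadata columns `gene_id` and `transcript_id`.
#' @export
readTranscriptsBED12 <- function(path) {
  if (!file.exists(path)) .stopIoError("BED12 file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(df) < 12L)
    .stopIoError("BED12 parse error in %s: fewer than 12 columns", path)
  strand <- df[[6L]]
  if (!all(strand %in% c("+", "-")))
    .stopIoError("BED12 validation error in %s: transcripts must be stranded", path)
  nm <- strsplit(df[[4L]], ":", fixed = TRUE)
  gene_id <- vapply(nm, `[`, "", 1L)
  transcript_id <- vapply(nm, function(x) x[length(x)], "")
  gr <- GenomicRanges::GRanges(
    df[[1L]],
    IRanges::IRanges(as.integer(df[[2L]]) + 1L, as.integer(df[[3L]])),
    strand)
  gr$gene_id <- gene_id
  gr$transcript_id <- transcript_id
  gr
}

#' Derive the strand-aware 5'-most TSS per gene
#'
#' For a plus-strand gene the TSS is the minimum transcript start; for a
#' minus-strand gene it is the maximum transcript end. All transcripts of a
#' gene must share one chromosome and one strand.
#'
#' @param transcripts A `GRanges` of transcripts with `gene_id` metadata
#'   (as from [readTranscriptsGTF()]).
#' @return A width-1 `GRanges` named by `gene_id`, one range per distinct
#'   gene, ordered by `gene_id`; `start == end` is the TSS position
#'   (1-based).
#' @export
geneTssTable <- function(transcripts) {
  if (length(transcripts) == 0L)
    .stopIoError("geneTssTable: no transcripts supplied")
  strand <- as.character(GenomicRanges::strand(transcripts))
  if (!all(strand %in% c("+", "-")))
    .stopIoError("geneTssTable: all transcripts must be stranded (+/-)")
  gene <- transcripts$gene_id
  chrom <- as.character(GenomicRanges::seqnames(transcripts))
  byg <- split(seq_along(transcripts), gene)
  ids <- names(byg)
  tss <- integer(length(ids)); chr <- character(length(ids))
  str <- character(length(ids))
  for (i in seq_along(byg)) {
    idx <- byg[[i]]
    if (length(unique(chrom[idx])) != 1L || length(unique(strand[idx])) != 1L)
      .stopIoError("geneTssTable validation error: gene %s has transcripts on mixed chromosomes or strands",
                   ids[i])
    chr[i] <- chrom[idx[1L]]
    str[i] <- strand[idx[1L]]
    tss[i] <- if (str[i] == "+") min(GenomicRanges::start(transcripts)[idx])
              else max(GenomicRanges::end(transcripts)[idx])
  }
  out <- GenomicRanges::GRanges(chr, IRanges::IRanges(tss, tss), str)
  names(out) <- ids
  out$gene_id <- ids
  out
}

#' Read a per-tissue differential-expression table
#'
#' Tab-separated with a header naming `gene_id`, `tissue`, `log_fc`,
#' `p_value`, `pct_wt`, `pct_mut`. `log_fc` is mutant relative to wild-type
#' (negative = down in the mutant); `pct_*` are the percent of cells of that
#' tissue expressing the gene. Duplicate (gene, tissue) pairs, p-values
#' outside (0, 1] and percents outside [0, 100] are rejected.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with the six columns above.
#' @export
readDETable <- function(path) {
  if (!file.exists(path)) .stopIoError("DE table not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue", "log_fc", "p_value", "pct_wt", "pct_mut")
  if (!all(need %in% names(df)))
    .stopIoError("DE table %s missing columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  validateDETable(df, path)
  df
}

#' Validate a differential-expression data.frame in place
#' @param df DE table as from [readDETable()].
#' @param label Text used in error messages.
#' @return `df`, invisibly.
#' @export
validateDETable <- function(df, label = "DE table") {
  if (anyDuplicated(df[c("gene_id", "tissue")]))
    .stopIoError("%s: duplicate (gene_id, tissue) pairs", label)
  if (any(df$p_value <= 0 | df$p_value > 1))
    .stopIoError("%s: p_value outside (0, 1]", label)
  if (any(df$pct_wt < 0 | df$pct_wt > 100 | df$pct_mut < 0 | df$pct_mut > 100))
    .stopIoError("%s: percent-expressing outside [0, 100]", label)
  if (any(!is.finite(df$log_fc)))
    .stopIoError("%s: non-finite log_fc", label)
  invisible(df)
}

#' Write a differential-expression table
#' @param df DE table (six canonical columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDETable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a whole-embryo microarray table
#'
#' Tab-separated with header columns `gene_id`, `fold_change` (signed linear
#' fold change, negative = down in mutant, never 0) and `p_value` in (0, 1].
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with those three columns.
#' @export
readMicroarrayTable <- function(path) {
  if (!file.exists(path)) .stopIoError("microarray table not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "fold_change", "p_value")
  if (!all(need %in% names(df)))
    .stopIoError("microarray table %s missing columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  if (any(df$fold_change == 0))
    .stopIoError("microarray table %s: fold_change must be nonzero", path)
  if (any(df$p_value <= 0 | df$p_value > 1))
    .stopIoError("microarray table %s: p_value outside (0, 1]", path)
  df
}

#' Read a GMT gene-set collection
#'
#' Lines are `name<TAB>description<TAB>gene1<TAB>gene2...`. Empty sets are
#' retained at load (size filtering is the GSEA stage's job); duplicate
#' genes within a set are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of gene identifiers.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) .stopIoError("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short))
    .stopIoError("GMT parse error at line %d of %s: need name and description fields",
                 short[1L], path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets)))
    .stopIoError("GMT validation error in %s: duplicate set names", path)
  sets
}

#' Write a named list of gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Sequences are uppercased on load; characters outside ACGTN are rejected.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named `DNAStringSet`, one entry per chromosome.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) .stopIoError("FASTA file not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  freq <- Biostrings::alphabetFrequency(seqs)
  allowed <- c("A", "C", "G", "T", "N")
  other <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(other > 0))
    .stopIoError("FASTA validation error in %s: characters outside ACGTN in %s",
                 path, names(seqs)[which(other > 0)[1L]])
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read a plain-text gene list (one identifier per line)
#' @param path Path to the list file.
#' @return A character vector of unique identifiers, in file order.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) .stopIoError("gene list not found: %s", path)
  x <- readLines(path)
  unique(trimws(x[nzchar(trimws(x))]))
}
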