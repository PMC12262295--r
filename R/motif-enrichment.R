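## Discriminative k-mer motif enrichment with IUPAC generalization, plus
## PWM-library comparison. This is an explicit simplification of
## DREME-style discovery: exact-word seeding, greedy IUPAC hill-climb and
## one-sided Fisher (hypergeometric) scoring, without heuristic word
## sampling or sequential motif erasure. The counting unit is per-sequence
## presence (a word occurring many times in one sequence counts once).

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

.iupacDegenerate <- names(.IUPAC)[lengths(.IUPAC) %in% c(2L, 3L)]

#' Extract fixed-flank sequence windows around peak centers
#'
#' One window per peak: `center - flank` to `center + flank` inclusive
#' (2*flank + 1 bases), clipped at chromosome ends.
#'
#' @param peaks Peak `GRanges` (typically the intersected peaks assigned to
#'   one regulatory class).
#' @param genome Named `DNAStringSet` ([readGenomeFasta()]).
#' @param flank Flank in bases on each side of the center (default 250).
#' @return A `DNAStringSet` of window sequences; `mcols` carry `chrom`,
#'   `start`, `end` (1-based closed window coordinates) and `center`.
#' @export
extractWindows <- function(peaks, genome, flank = 250L) {
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing))
    stop("extractWindows: chromosome(s) missing from genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  centers <- peakCenters(peaks)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  start <- pmax(1L, centers - as.integer(flank))
  end <- pmin(lens[chroms], centers + as.integer(flank))
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(peaks), function(i)
    as.character(Biostrings::subseq(genome[[chroms[i]]], start[i], end[i])),
    ""))
  names(seqs) <- if (!is.null(peaks$name)) peaks$name else
    paste0("window", seq_along(peaks))
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    chrom = chroms, start = as.integer(start), end = as.integer(end),
    center = centers)
  seqs
}

## Distinct k-mers (both strands, N-free) present in one sequence.
.seqKmers <- function(s, rc, kMin, kMax) {
  n <- nchar(s)
  out <- character(0)
  for (k in kMin:kMax) {
    if (k > n) break
    pos <- seq_len(n - k + 1L)
    out <- c(out, substring(s, pos, pos + k - 1L),
             substring(rc, pos, pos + k - 1L))
  }
  out <- unique(out)
  out[!grepl("N", out, fixed = TRUE)]
}

#' One-sided hypergeometric enrichment p-value
#'
#' Probability of observing at least `posWith` word-containing sequences in
#' the positive draw, given the pooled containment counts (Fisher's exact
#' test, greater alternative).
#'
#' @param posWith,posTotal,negWith,negTotal Sequence-containment counts.
#' @return The tail probability.
#' @export
fisherEnrichmentP <- function(posWith, posTotal, negWith, negTotal) {
  stats::phyper(posWith - 1L, posWith + negWith,
                posTotal + negTotal - posWith - negWith, posTotal,
                lower.tail = FALSE)
}

#' Discriminative word enrichment between two window collections
#'
#' Every exact word of length `kMin..kMax` present in at least one positive
#' sequence (on either strand) is scored: per-sequence presence counts in
#' positives vs negatives, one-sided Fisher p for enrichment in positives,
#' and an E-value (p times the number of distinct words tested in the run).
#' Palindromic words count once per sequence. Results are ranked by
#' ascending E-value.
#'
#' @param pos,neg `DNAStringSet` window collections (both non-empty).
#' @param kMin,kMax Word length range (default 3..8); `kMax` longer than
#'   the shortest sequence is truncated with a warning.
#' @return A `data.frame` with columns `word`, `pos_with`, `pos_total`,
#'   `neg_with`, `neg_total`, `fisher_p`, `e_value`, ranked by `e_value`.
#' @export
wordEnrichment <- function(pos, neg, kMin = 3L, kMax = 8L) {
  if (length(pos) == 0L || length(neg) == 0L)
    stop("wordEnrichment: both sequence collections must be non-empty",
         call. = FALSE)
  minLen <- min(Biostrings::width(pos), Biostrings::width(neg))
  if (kMax > minLen) {
    warning(sprintf("wordEnrichment: kMax truncated from %d to %d (shortest sequence)",
                    kMax, minLen))
    kMax <- minLen
  }
  stopifnot(kMin >= 1L, kMin <= kMax)
  posChr <- as.character(pos)
  negChr <- as.character(neg)
  posRc <- as.character(Biostrings::reverseComplement(pos))
  negRc <- as.character(Biostrings::reverseComplement(neg))
  posK <- lapply(seq_along(posChr), function(i)
    .seqKmers(posChr[i], posRc[i], kMin, kMax))
  negK <- lapply(seq_along(negChr), function(i)
    .seqKmers(negChr[i], negRc[i], kMin, kMax))
  posTab <- table(unlist(posK, use.names = FALSE))
  negTab <- table(unlist(negK, use.names = FALSE))
  words <- names(posTab)
  posWith <- as.integer(posTab)
  negWith <- as.integer(negTab[words])
  negWith[is.na(negWith)] <- 0L
  p <- fisherEnrichmentP(posWith, length(pos), negWith, length(neg))
  out <- data.frame(word = words, pos_with = posWith,
                    pos_total = length(pos), neg_with = negWith,
                    neg_total = length(neg), fisher_p = p,
                    e_value = p * length(words))
  out <- out[order(out$e_value, -out$pos_with, out$word), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Per-sequence presence (either strand) of an IUPAC word.
.iupacPresence <- function(word, seqs) {
  pat <- Biostrings::DNAString(word)
  fwd <- Biostrings::vcountPattern(pat, seqs, fixed = FALSE) > 0L
  rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                   seqs, fixed = FALSE) > 0L
  sum(fwd | rev)
}

#' Greedy IUPAC generalization of an enriched word
#'
#' Hill-climb from an exact seed word: at each step every single-position
#' replacement by a 2- or 3-letter IUPAC code is evaluated and the one that
#' most decreases the Fisher p is accepted; the climb stops when no
#' replacement improves. The result's p is never worse than the seed's.
#'
#' @param word Seed word (a row `word` from [wordEnrichment()]).
#' @param pos,neg The window collections the seed was scored on.
#' @return One-row `data.frame` in [wordEnrichment()] candidate layout
#'   (without an E-value, which depends on the run's word count).
#' @export
generalizeWord <- function(word, pos, neg) {
  best <- word
  bestP <- fisherEnrichmentP(.iupacPresence(word, pos), length(pos),
                             .iupacPresence(word, neg), length(neg))
  repeat {
    chars <- strsplit(best, "")[[1]]
    stepBest <- NULL
    stepP <- bestP
    for (i in seq_along(chars)) {
      for (code in setdiff(.iupacDegenerate, chars[i])) {
        cand <- chars
        cand[i] <- code
        cand <- paste(cand, collapse = "")
        p <- fisherEnrichmentP(.iupacPresence(cand, pos), length(pos),
                               .iupacPresence(cand, neg), length(neg))
        if (p < stepP) {
          stepP <- p
          stepBest <- cand
        }
      }
    }
    if (is.null(stepBest)) break
    best <- stepBest
    bestP <- stepP
  }
  data.frame(word = best,
             pos_with = .iupacPresence(best, pos), pos_total = length(pos),
             neg_with = .iupacPresence(best, neg), neg_total = length(neg),
             fisher_p = bestP)
}

#' Compare a query PWM against a motif library
#'
#' For each library target, the score is the maximum over all ungapped
#' offsets and both orientations (the reverse complement reverses the
#' column order and complements the base rows) of the mean Pearson
#' correlation between aligned probability columns, requiring at least
#' `minOverlap` aligned columns. Zero-variance column pairs score 1 when
#' identical and 0 otherwise.
#'
#' @param query A 4-by-W probability matrix with rownames A, C, G, T,
#'   columns summing to 1.
#' @param library Named list of such matrices.
#' @param minOverlap Minimum aligned columns (default 4).
#' @return A `data.frame` with `target`, `score`, `offset` (query start
#'   minus target start in the best alignment) and `orientation`
#'   (`"+"`/`"-"`); targets whose width makes the overlap constraint
#'   unsatisfiable are skipped with a warning.
#' @export
pwmCompare <- function(query, library, minOverlap = 4L) {
  .checkPwm(query, "query")
  rows <- vector("list", length(library))
  for (t in seq_along(library)) {
    target <- library[[t]]
    .checkPwm(target, names(library)[t])
    wq <- ncol(query); wt <- ncol(target)
    if (min(wq, wt) < minOverlap) {
      warning(sprintf("pwmCompare: target %s skipped (overlap < %d unsatisfiable)",
                      names(library)[t], minOverlap))
      next
    }
    best <- list(score = -Inf, offset = NA_integer_, orientation = NA_character_)
    for (orient in c("+", "-")) {
      q <- if (orient == "+") query else .pwmReverseComplement(query)
      for (off in seq(-(wq - minOverlap), wt - minOverlap)) {
        qi <- seq_len(wq) + off       # query column i sits at target position qi
        keep <- qi >= 1L & qi <= wt
        if (sum(keep) < minOverlap) next
        cors <- vapply(which(keep), function(i)
          .colCor(q[, i], target[, qi[i]]), 0)
        sc <- mean(cors)
        if (sc > best$score)
          best <- list(score = sc, offset = off, orientation = orient)
      }
    }
    rows[[t]] <- data.frame(target = names(library)[t], score = best$score,
                            offset = best$offset, orientation = best$orientation)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(target = character(0), score = numeric(0),
                      offset = integer(0), orientation = character(0))
  rownames(out) <- NULL
  out
}

.checkPwm <- function(m, label) {
  if (!is.matrix(m) || nrow(m) != 4L)
    stop(sprintf("PWM %s must be a 4-row matrix (A, C, G, T)", label),
         call. = FALSE)
  if (any(m < 0) || any(abs(colSums(m) - 1) > 1e-9))
    stop(sprintf("PWM %s columns must be probability vectors", label),
         call. = FALSE)
}

.pwmReverseComplement <- function(m) {
  out <- m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

.colCor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(if (isTRUE(all.equal(a, b))) 1 else 0)
  stats::cor(a, b)
}

#' Read a MEME minimal-format motif library
#'
#' Parses `MOTIF` blocks with their letter-probability matrices into the
#' matrix layout [pwmCompare()] expects.
#'
#' @param path Path to a MEME minimal motif file.
#' @return Named list of 4-by-W probability matrices.
#' @export
readMemeMotifs <- function(path) {
  if (!file.exists(path)) stop("MEME motif file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path, call. = FALSE)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- s + grep("^letter-probability matrix",
                    lines[(s + 1):length(lines)])[1]
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
    rowsTxt <- lines[(hdr + 1):(hdr + w)]
    m <- vapply(rowsTxt, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]]), numeric(4))
    dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
    out[[name]] <- m
  }
  out
}

#' Write motifs in MEME minimal format
#' @param motifs Named list of 4-by-W probability matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMemeMotifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  for (name in names(motifs)) {
    m <- motifs[[name]]
    writeLines(sprintf("MOTIF %s", name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(m)), con)
    for (j in seq_len(ncol(m)))
      writeLines(paste(sprintf("%.6f", m[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' IUPAC word to PWM
#'
#' Each position becomes a uniform probability over the letters its IUPAC
#' code admits.
#'
#' @param word IUPAC word.
#' @return A 4-by-nchar(word) probability matrix.
#' @export
iupacToPwm <- function(word) {
  chars <- strsplit(toupper(word), "")[[1]]
  bad <- setdiff(chars, names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC letter(s): ",
                        paste(bad, collapse = ""), call. = FALSE)
  m <- vapply(chars, function(ch) {
    p <- stats::setNames(numeric(4), c("A", "C", "G", "T"))
    p[.IUPAC[[ch]]] <- 1 / length(.IUPAC[[ch]])
    p
  }, numeric(4))
  matrix(m, nrow = 4L, dimnames = list(c("A", "C", "G", "T"), NULL))
}

## Canonical IUPAC form: per-position base sets mapped back to the unique
## code, so two words are equivalent iff their canonical forms are equal
## (mutual pattern containment).
.iupacCanonical <- function(word) {
  chars <- strsplit(toupper(word), "")[[1]]
  codeOf <- vapply(names(.IUPAC), function(k)
    paste(sort(.IUPAC[[k]]), collapse = ""), "")
  paste(vapply(chars, function(ch) {
    key <- paste(sort(.IUPAC[[ch]]), collapse = "")
    names(codeOf)[codeOf == key][1]
  }, ""), collapse = "")
}

#' IUPAC-aware word equivalence
#'
#' Two words are equivalent when they have equal length and, at every
#' position, admit exactly the same base set (mutual containment).
#'
#' @param a,b IUPAC words.
#' @return Logical scalar.
#' @export
iupacEquivalent <- function(a, b) {
  nchar(a) == nchar(b) && .iupacCanonical(a) == .iupacCanonical(b)
}

#' Motifs significant in exactly one regulatory class
#'
#' Given per-class candidate tables computed against a common control, a
#' motif is class-unique when its E-value is below `eThreshold` in exactly
#' one class (IUPAC-equivalent words across classes are treated as the
#' same motif).
#'
#' @param candidates Named list of [wordEnrichment()] tables, one per
#'   class.
#' @param eThreshold Significance threshold on the E-value (default 0.05).
#' @return A `data.frame` with `word`, `unique_class` (`NA` for motifs
#'   significant in several classes) and `classes` (comma-separated
#'   significant classes).
#' @export
classUniqueMotifs <- function(candidates, eThreshold = 0.05) {
  sig <- lapply(candidates, function(tab)
    tab$word[tab$e_value < eThreshold])
  canon <- lapply(sig, function(w) vapply(w, .iupacCanonical, ""))
  allWords <- unique(unlist(canon, use.names = FALSE))
  if (!length(allWords))
    return(data.frame(word = character(0), unique_class = character(0),
                      classes = character(0)))
  inClass <- vapply(canon, function(cw) allWords %in% cw,
                    logical(length(allWords)))
  if (length(allWords) == 1L)
    inClass <- matrix(inClass, nrow = 1L,
                      dimnames = list(NULL, names(candidates)))
  nSig <- rowSums(inClass)
  data.frame(
    word = allWords,
    unique_class = ifelse(nSig == 1L,
                          colnames(inClass)[max.col(inClass)], NA_character_),
    classes = apply(inClass, 1L, function(r)
      paste(colnames(inClass)[r], collapse = ",")))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson style shuffle: each returned sequence has exactly the
#' dinucleotide (and hence mononucleotide) composition of its input, with
#' the first and last letters fixed. Provided as an alternative control to
#' the bound-unchanged windows.
#'
#' @param seqs A `DNAStringSet`.
#' @return A shuffled `DNAStringSet` of the same widths and names. Uses the
#'   current RNG state.
#' @export
dinucleotideShuffle <- function(seqs) {
  out <- vapply(as.character(seqs), .dinucShuffleOne, "")
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(seqs)
  res
}

.dinucShuffleOne <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n <= 3L) return(s)
  last <- ch[n]
  edges <- split(ch[-1L], ch[-n])   # successor multiset per vertex
  verts <- names(edges)
  for (attempt in seq_len(1000L)) {
    inner <- setdiff(verts, last)
    finals <- vapply(inner, function(v)
      edges[[v]][sample.int(length(edges[[v]]), 1L)], "")
    names(finals) <- inner
    # final edges of non-terminal vertices must form an in-tree converging
    # on the last letter (Altschul-Erickson condition)
    ok <- TRUE
    for (v in inner) {
      cur <- v; seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || !cur %in% inner) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- finals[[cur]]
      }
      if (!ok) break
    }
    if (ok) {
      pools <- lapply(verts, function(v) {
        e <- edges[[v]]
        if (v %in% inner) {
          e <- e[-match(finals[[v]], e)]
          c(if (length(e)) sample(e), finals[[v]])
        } else {
          if (length(e) > 1L) sample(e) else e
        }
      })
      names(pools) <- verts
      res <- character(n)
      res[1L] <- ch[1L]
      ptr <- stats::setNames(rep(1L, length(verts)), verts)
      for (i in 2:n) {
        v <- res[i - 1L]
        res[i] <- pools[[v]][ptr[[v]]]
        ptr[[v]] <- ptr[[v]] + 1L
      }
      return(paste(res, collapse = ""))
    }
  }
  stop("dinucleotideShuffle: failed to find an Eulerian arrangement",
       call. = FALSE)
}
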