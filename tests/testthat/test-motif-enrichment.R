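test_that("window extraction is center +/- flank, clipped at chromosome ends", {
  genome <- Biostrings::DNAStringSet(c(chrA = paste(rep("ACGT", 2500),
                                                    collapse = "")))
  # peak with 0-based center 1000: window [750, 1251) i.e. 501 bases
  gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(951, 1050))
  gr$name <- "p1"
  win <- extractWindows(gr, genome)
  expect_equal(Biostrings::width(win), 501L)
  md <- S4Vectors::mcols(win)
  expect_equal(md$start, 751L)   # 1-based; 0-based 750
  expect_equal(md$end, 1251L)
  expect_equal(as.character(win[[1]]),
               as.character(Biostrings::subseq(genome[["chrA"]], 751, 1251)))

  # center near the start: clipped to [0, 351) = 351 bases
  gr2 <- GenomicRanges::GRanges("chrA", IRanges::IRanges(51, 150))
  gr2$name <- "p2"
  win2 <- extractWindows(gr2, genome)
  expect_equal(Biostrings::width(win2), 351L)
  expect_equal(S4Vectors::mcols(win2)$start, 1L)

  expect_error(extractWindows(GenomicRanges::GRanges("chrZ",
                                                     IRanges::IRanges(1, 10)),
                              genome), "chrZ")
})

test_that("perfectly separating word gets the exact hypergeometric tail", {
  word <- "TGACGTCA"
  set.seed(51)
  pos <- Biostrings::DNAStringSet(paste0(
    vapply(1:10, function(i) paste(sample(c("A", "C"), 30, TRUE),
                                   collapse = ""), ""), word))
  neg <- Biostrings::DNAStringSet(vapply(1:10, function(i)
    paste(sample(c("A", "C"), 38, TRUE), collapse = ""), ""))
  cand <- wordEnrichment(pos, neg, kMin = 3L, kMax = 8L)
  row <- cand[cand$word == word, ]
  expect_equal(row$pos_with, 10L)
  expect_equal(row$neg_with, 0L)
  # P(all 10 draws from the 10 word-carrying sequences) = 1/C(20,10)
  expect_equal(row$fisher_p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(row$e_value, row$fisher_p * nrow(cand))
  # a no-signal word never outranks a perfectly separating one
  null_rows <- cand[cand$pos_with == cand$neg_with, ]
  if (nrow(null_rows)) expect_true(all(null_rows$fisher_p >= 0.5))
  expect_true(row$fisher_p <= min(cand$fisher_p))
})

test_that("word counting is strand-symmetric and counts palindromes once", {
  set.seed(52)
  pos <- randomSeqs(8, 60)
  neg <- randomSeqs(8, 60)
  fwd <- wordEnrichment(pos, neg, 3L, 5L)
  rcp <- wordEnrichment(Biostrings::reverseComplement(pos),
                        Biostrings::reverseComplement(neg), 3L, 5L)
  key <- function(df) df[order(df$word), c("word", "pos_with", "neg_with")]
  expect_equal(key(fwd), key(rcp), ignore_attr = TRUE)

  # palindrome present on both strands of one sequence counts once
  pal <- Biostrings::DNAStringSet(c("AAAGAATTCAAA", "CCCCCCCCCCCC"))
  ref <- Biostrings::DNAStringSet(c("GGGGGGGGGGGG", "GGGGGGGGGGGG"))
  tab <- wordEnrichment(pal, ref, 6L, 6L)
  expect_equal(tab$pos_with[tab$word == "GAATTC"], 1L)
})

test_that("containment counts agree with raw string scanning", {
  set.seed(53)
  pos <- randomSeqs(12, 50)
  neg <- randomSeqs(12, 50)
  tab <- wordEnrichment(pos, neg, 4L, 4L)
  pick <- tab[sample(nrow(tab), 25), ]
  for (i in seq_len(nrow(pick))) {
    expect_equal(pick$pos_with[i], bruteWordCounts(pick$word[i], pos))
    expect_equal(pick$neg_with[i], bruteWordCounts(pick$word[i], neg))
  }
})

test_that("enrichment p is monotone in pos_with and kMax is truncated to fit", {
  p <- fisherEnrichmentP(0:10, 10, 2, 10)
  expect_true(all(diff(p) <= 0))
  expect_warning(wordEnrichment(randomSeqs(3, 6), randomSeqs(3, 6),
                                3L, 10L), "truncated")
})

test_that("IUPAC generalization improves or keeps the seed and finds Y", {
  # positives split between TGACGT and TGACGC; negatives carry neither
  pos <- Biostrings::DNAStringSet(c(rep("AAAATGACGTAAAA", 5),
                                    rep("AAAATGACGCAAAA", 5)))
  set.seed(54)
  neg <- randomSeqs(10, 14)
  out <- generalizeWord("TGACGT", pos, neg)
  expect_equal(substr(out$word, 6, 6), "Y")
  expect_equal(out$pos_with, 10L)
  seedP <- fisherEnrichmentP(5L, 10L, bruteWordCounts("TGACGT", neg), 10L)
  expect_lte(out$fisher_p, seedP)

  # already-optimal seed is returned unchanged
  pos2 <- Biostrings::DNAStringSet(rep("AAAATGACGTAAAA", 8))
  neg2 <- Biostrings::DNAStringSet(rep("CCCCCCCCCCCCCC", 8))
  out2 <- generalizeWord("TGACGT", pos2, neg2)
  expect_equal(out2$word, "TGACGT")
})

test_that("PWM comparison finds identity, reverse complements and the brute optimum", {
  set.seed(55)
  q <- randomPwm(8)
  hit <- pwmCompare(q, list(self = q))
  expect_equal(hit$score, 1, tolerance = 1e-12)
  expect_equal(hit$offset, 0L)
  expect_equal(hit$orientation, "+")

  rc <- q[4:1, 8:1]
  rownames(rc) <- c("A", "C", "G", "T")
  hitRc <- pwmCompare(q, list(rc = rc))
  expect_equal(hitRc$score, 1, tolerance = 1e-12)
  expect_equal(hitRc$orientation, "-")

  for (rep in 1:20) {
    a <- randomPwm(sample(4:9, 1))
    b <- randomPwm(sample(4:9, 1))
    expect_equal(pwmCompare(a, list(t = b))$score, brutePwmScore(a, b),
                 tolerance = 1e-12)
  }

  expect_warning(out <- pwmCompare(q, list(short = randomPwm(3))), "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("class-unique calls respect IUPAC equivalence", {
  mk <- function(word, e) data.frame(word = word, pos_with = 5, pos_total = 5,
                                     neg_with = 0, neg_total = 5,
                                     fisher_p = e / 10, e_value = e)
  out <- classUniqueMotifs(list(activated = mk("TGACGT", 1e-4),
                                repressed = mk("CCCCCC", 0.9)))
  expect_equal(out$unique_class[out$word == "TGACGT"], "activated")

  shared <- classUniqueMotifs(list(a = mk("TGAY", 1e-4),
                                   b = mk("TGAY", 1e-3),
                                   c = mk("TGAY", 0.9)))
  expect_true(is.na(shared$unique_class[1]))
  expect_equal(shared$classes[1], "a,b")

  expect_true(iupacEquivalent("TGAY", "TGAY"))
  expect_false(iupacEquivalent("TGAY", "TGAR"))
  expect_false(iupacEquivalent("TGA", "TGAY"))
})

test_that("dinucleotide shuffle preserves dinucleotide composition exactly", {
  dinucs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  set.seed(56)
  seqs <- randomSeqs(5, 80)
  shuf <- dinucleotideShuffle(seqs)
  for (i in seq_along(seqs)) {
    a <- as.character(seqs[[i]]); b <- as.character(shuf[[i]])
    expect_equal(dinucs(a), dinucs(b))
    expect_equal(substr(a, 1, 1), substr(b, 1, 1))
    expect_equal(substr(a, 80, 80), substr(b, 80, 80))
  }
  expect_false(all(as.character(seqs) == as.character(shuf)))
})

test_that("MEME minimal motif files round-trip", {
  motifs <- list(M1 = randomPwm(6), M2 = randomPwm(9))
  tf <- withr::local_tempfile(fileext = ".meme")
  writeMemeMotifs(motifs, tf)
  back <- readMemeMotifs(tf)
  expect_equal(names(back), names(motifs))
  expect_equal(back$M1, motifs$M1, tolerance = 1e-5)
  expect_equal(ncol(back$M2), 9L)
})

test_that("IUPAC words convert to uniform-column PWMs", {
  m <- iupacToPwm("AR")
  expect_equal(m[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(m[, 2], c(A = 0.5, C = 0, G = 0.5, T = 0))
  expect_error(iupacToPwm("AXZ"), "IUPAC")
})
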