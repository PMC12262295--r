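mkDe <- function(gene, lfc, p = 0.01, pct_wt = 50, pct_mut = 25,
                 tissue = "SG") {
  data.frame(gene_id = gene, tissue = tissue, log_fc = lfc, p_value = p,
             pct_wt = pct_wt, pct_mut = pct_mut)
}

thr <- classificationThresholds()

test_that("scRNA activation route applies strict inequalities", {
  expect_equal(classifyActivated(mkDe("g", -0.20, 0.01))$gene_id, "g")
  expect_equal(nrow(classifyActivated(mkDe("g", -0.15, 0.01))), 0L)
  expect_equal(nrow(classifyActivated(mkDe("g", -0.20, 0.05))), 0L)
})

test_that("in-situ membership activates regardless of focal logFC", {
  act <- classifyActivated(mkDe("g", +0.05, 0.5), insitu = "g")
  expect_equal(act$gene_id, "g")
  expect_true(act$insitu)
  expect_false(act$scrna)
})

test_that("microarray route enforces the expression and direction filters", {
  ma <- data.frame(gene_id = "g", fold_change = -1.5, p_value = 0.01)
  # fails the >10 percent-expressing filter
  expect_equal(nrow(classifyActivated(mkDe("g", -0.05, 0.5, pct_wt = 5),
                                      microarray = ma)), 0L)
  # boundary: exactly 10 percent fails (strict >)
  expect_equal(nrow(classifyActivated(mkDe("g", -0.05, 0.5, pct_wt = 10),
                                      microarray = ma)), 0L)
  # passes with pct_wt > 10 and negative focal logFC
  act <- classifyActivated(mkDe("g", -0.05, 0.5, pct_wt = 11),
                           microarray = ma)
  expect_true(act$microarray)
  # focal logFC must be strictly negative
  expect_equal(nrow(classifyActivated(mkDe("g", 0.0, 0.5, pct_wt = 50),
                                      microarray = ma)), 0L)
  # microarray gene absent from the DE table fails closed
  ma2 <- data.frame(gene_id = "absent", fold_change = -2, p_value = 0.01)
  expect_message(out <- classifyActivated(mkDe("g", -0.05, 0.5),
                                          microarray = ma2),
                 "fails closed")
  expect_equal(nrow(out), 0L)
})

test_that("activation matches the brute-force truth-table oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 80
    de <- mkDe(sprintf("g%02d", 1:n),
               lfc = round(stats::runif(n, -0.5, 0.5), 3),
               p = round(stats::runif(n, 1e-4, 1), 4),
               pct_wt = round(stats::runif(n, 0, 40), 2))
    insitu <- sample(de$gene_id, 5)
    ma <- data.frame(gene_id = sample(c(de$gene_id, "outside"), 30),
                     fold_change = round(stats::runif(30, -3, 2), 3),
                     p_value = round(stats::runif(30, 1e-4, 1), 4))
    ma <- ma[ma$fold_change != 0, ]
    got <- suppressMessages(classifyActivated(de, insitu, ma, thr))
    expect_equal(got$gene_id, bruteActivated(de, insitu, ma, thr))
  }
})

test_that("repression uses only the scRNA route with strict thresholds", {
  expect_equal(classifyRepressed(mkDe("g", 0.20, 0.01)), "g")
  expect_length(classifyRepressed(mkDe("g", 0.20, 0.10)), 0L)
  expect_length(classifyRepressed(mkDe("g", 0.15, 0.01)), 0L)
})

test_that("a gene activated by in-situ but repressed by scRNA is a conflict", {
  de <- mkDe("g", +0.20, 0.01)
  act <- classifyActivated(de, insitu = "g")
  rep_ <- classifyRepressed(de)
  expect_warning(net <- buildNetwork("g", act, rep_), "conflict")
  expect_equal(net@conflict, "g")
  expect_length(networkActivated(net), 0L)
  expect_length(networkRepressed(net), 0L)
})

test_that("unchanged selection takes smallest |logFC| with documented tie-break", {
  de <- mkDe(c("a", "b", "c"), c(0.01, -0.02, 0.5))
  expect_setequal(selectUnchanged(de, n = 2L), c("a", "b"))

  # tie on |logFC|: larger p first, then gene_id
  de2 <- mkDe(c("x", "y", "z"), c(0.1, -0.1, 0.1),
              p = c(0.5, 0.9, 0.9))
  expect_equal(selectUnchanged(de2, n = 2L), c("y", "z"))

  set.seed(22)
  de3 <- mkDe(sprintf("g%03d", 1:300),
              lfc = round(stats::rnorm(300, 0, 0.3), 4),
              p = round(stats::runif(300), 4))
  expect_equal(selectUnchanged(de3, n = 150L), bruteUnchanged(de3, 150L))

  expect_warning(all3 <- selectUnchanged(de, n = 10L), "only 3")
  expect_length(all3, 3L)

  # excluding the regulated calls guarantees disjointness by construction
  expect_equal(selectUnchanged(de, n = 1L, exclude = c("a", "b")), "c")
})

test_that("network fractions follow the set arithmetic", {
  net <- suppressWarnings(
    buildNetwork(c("A", "B", "C", "D"), c("A", "E"), "B"))
  fr <- networkFractions(net)
  expect_equal(fr$fraction_bound_regulated$value, 0.5)
  expect_equal(fr$fraction_activated_bound$value, 0.5)
  expect_equal(fr$fraction_repressed_bound$value, 1.0)
  expect_equal(boundActivated(net), "A")
  expect_equal(boundRepressed(net), "B")

  disjoint <- buildNetwork(c("A", "B"), c("C"), "D")
  expect_equal(networkFractions(disjoint)$fraction_bound_regulated$value, 0)

  # empty bound set: NA sentinel, not zero
  empty <- buildNetwork(character(0), "A", character(0))
  expect_true(is.na(networkFractions(empty)$fraction_bound_regulated$value))
})

test_that("SPCG counts are intersections with bound and bound-activated sets", {
  net <- buildNetwork(bound = c("s1", "s2", "s3", "x"),
                      activated = c("s1", "s2"), repressed = character(0),
                      spcg = c("s1", "s2", "s3", "s4"))
  fr <- networkFractions(net)
  expect_equal(fr$spcg_bound_count$numerator, 3L)
  expect_equal(fr$spcg_bound_down_count$numerator, 2L)
  expect_output(show(net), "SPCGs bound:\\s+3/4")
})

test_that("classification is invariant under input row permutation", {
  set.seed(23)
  de <- mkDe(sprintf("g%02d", 1:50),
             lfc = round(stats::runif(50, -0.5, 0.5), 3),
             p = round(stats::runif(50, 1e-4, 1), 4))
  perm <- de[sample(nrow(de)), ]
  expect_equal(classifyActivated(de)$gene_id, classifyActivated(perm)$gene_id)
  expect_equal(classifyRepressed(de), classifyRepressed(perm))
  expect_equal(sort(selectUnchanged(de, n = 20L)),
               sort(selectUnchanged(perm, n = 20L)))
})

test_that("BH-adjusted mode is available and more conservative", {
  de <- mkDe(sprintf("g%02d", 1:20), lfc = rep(-0.3, 20),
             p = seq(0.001, 0.049, length.out = 20))
  raw <- classifyActivated(de)
  adj <- classifyActivated(de, thr = classificationThresholds(adjustP = TRUE))
  expect_true(nrow(adj) <= nrow(raw))
})
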