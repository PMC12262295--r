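test_that("config invariants are enforced", {
  expect_error(syntheticConfig(nGenes = 20, nTrueTargets = 15,
                               nDecoyBound = 10), "exceed")
  expect_error(syntheticConfig(motif = "TGA"), "length")
  expect_error(syntheticConfig(motif = "TGXA"), "IUPAC")
  expect_error(syntheticConfig(effectSizeLfc = 0.15), "0.15")
  expect_error(generateBundle(smallBundleConfig(chromLength = 30000L)),
               "too small")
})

test_that("same config and seed give byte-identical bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- generateBundle(smallBundleConfig(seed = 3L), d1)
  b2 <- generateBundle(smallBundleConfig(seed = 3L), d2)
  for (key in names(b1$paths)) {
    expect_equal(unname(tools::md5sum(b1$paths[[key]])),
                 unname(tools::md5sum(b2$paths[[key]])),
                 label = key)
  }
  b3 <- generateBundle(smallBundleConfig(seed = 4L), withr::local_tempdir())
  expect_false(identical(tools::md5sum(b1$paths$genome)[[1]],
                         tools::md5sum(b3$paths$genome)[[1]]))
})

test_that("planted peaks respect the <1 kb intersected-center rule", {
  b <- generateBundle(smallBundleConfig(seed = 5L), withr::local_tempdir())
  peaksA <- readNarrowPeak(b$paths$peaks_a)
  peaksB <- readNarrowPeak(b$paths$peaks_b)
  tss <- geneTssTable(readTranscriptsGTF(b$paths$annotation))
  inter <- intersectKeepA(peaksA, peaksB)
  centers <- peakCenters(inter)
  p2g <- b$truth$peak_to_gene
  planted <- inter$name %in% names(p2g)
  expect_true(all(planted))  # driver-specific peaks never intersect
  for (i in which(planted)) {
    g <- p2g[[inter$name[i]]]
    expect_lt(abs(centers[i] - GenomicRanges::start(tss[g])), 1000L)
  }
  # every planted bound gene is covered by both drivers
  expect_setequal(unlist(p2g), b$truth$bound_genes)
})

test_that("planted DE effects straddle the thresholds as configured", {
  b <- generateBundle(smallBundleConfig(seed = 6L), withr::local_tempdir())
  de <- readDETable(b$paths$de)
  focal <- de[de$tissue == b$truth$focal_tissue, ]
  tr <- b$truth
  full <- setdiff(tr$activated_genes, c(tr$insitu_only, tr$microarray_only))
  fi <- match(full, focal$gene_id)
  expect_true(all(focal$log_fc[fi] <= -0.5))
  expect_true(all(focal$p_value[fi] < 0.05))
  ri <- match(tr$repressed_genes, focal$gene_id)
  expect_true(all(focal$log_fc[ri] >= 0.5))
  di <- match(tr$decoy_genes, focal$gene_id)
  expect_true(all(abs(focal$log_fc[di]) < 0.15))
  # route-only genes stay above the scRNA threshold but remain recoverable
  io <- match(tr$insitu_only, focal$gene_id)
  expect_true(all(focal$log_fc[io] > -0.15 & focal$log_fc[io] < 0))
  expect_true(all(tr$insitu_only %in% readGeneList(b$paths$insitu)))
  mo <- match(tr$microarray_only, focal$gene_id)
  expect_true(all(focal$log_fc[mo] > -0.15 & focal$log_fc[mo] < 0))
  expect_true(all(focal$pct_wt[mo] > 10))
  ma <- readMicroarrayTable(b$paths$microarray)
  mi <- match(tr$microarray_only, ma$gene_id)
  expect_true(all(ma$fold_change[mi] < -1.25 & ma$p_value[mi] < 0.05))
})

test_that("motif planting writes a matching instance inside the window", {
  set.seed(71)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
             collapse = "")
  out <- plantMotif(s, 1000L, "TGACGT")
  at <- attr(out, "planted_at")
  expect_true(at >= 750L && at + 6L - 1L <= 1250L)
  expect_equal(substr(out, at, at + 5L), "TGACGT", ignore_attr = TRUE)
  # only the planted positions differ
  diffs <- which(strsplit(s, "")[[1]] != strsplit(as.character(out), "")[[1]])
  expect_true(all(diffs >= at & diffs <= at + 5L))

  # degenerate code R realises as A or G at that position
  hits <- vapply(1:50, function(i) {
    o <- plantMotif(s, 1000L, "TTTTRTTTT")
    substr(o, attr(o, "planted_at") + 4L, attr(o, "planted_at") + 4L)
  }, "")
  expect_true(all(hits %in% c("A", "G")))
  expect_true(all(c("A", "G") %in% hits))

  expect_error(plantMotif(s, 100L, "TGACGT"), "out of")
})

test_that("motif plants are reproducible under a fixed seed", {
  set.seed(72)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
             collapse = "")
  runPlants <- function() {
    set.seed(99)
    vapply(1:200, function(i)
      attr(plantMotif(s, 1500L, "TGWCGT"), "planted_at"), 0L)
  }
  expect_identical(runPlants(), runPlants())
})

test_that("a bundle without true targets yields an empty regulated network", {
  b <- generateBundle(smallBundleConfig(seed = 8L, nTrueTargets = 0L),
                      withr::local_tempdir())
  expect_length(b$truth$activated_genes, 0L)
  expect_length(b$truth$repressed_genes, 0L)
  net <- classifyBundle(b)
  expect_length(boundActivated(net), 0L)
  expect_length(boundRepressed(net), 0L)
})

test_that("recall degrades monotonically (on average) as logFC noise grows", {
  recallAt <- function(noise, seeds) {
    mean(vapply(seeds, function(s) {
      b <- generateBundle(smallBundleConfig(seed = s, noiseLfcSd = noise),
                          withr::local_tempdir())
      net <- classifyBundle(b)
      truthReg <- union(b$truth$activated_genes, b$truth$repressed_genes)
      called <- union(networkActivated(net), networkRepressed(net))
      length(intersect(called, truthReg)) / length(truthReg)
    }, 0))
  }
  seeds <- 1:10
  r0 <- recallAt(0, seeds)
  r1 <- recallAt(0.35, seeds)
  r2 <- recallAt(0.7, seeds)
  expect_equal(r0, 1)
  expect_gte(r0, r1 - 0.02)
  expect_gte(r1, r2 - 0.02)
})
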