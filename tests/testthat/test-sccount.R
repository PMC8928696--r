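mkFrags <- function(starts, ends, barcodes, counts = NULL) {
  gr <- GRanges("chr1", IRanges(starts, ends))
  mcols(gr)$barcode <- barcodes
  mcols(gr)$count <- if (is.null(counts)) rep(1L, length(gr)) else counts
  gr
}

mkPeakSet <- function(starts, ends, targets) {
  gr <- GRanges("chr1", IRanges(starts, ends))
  mcols(gr)$target <- targets
  mcols(gr)$summit <- NA_real_
  mcols(gr)$score <- 1
  gr
}

test_that("pseudo-bulk pooling collapses identical fragments", {
  fr <- mkFrags(c(101, 101, 101, 501), c(200, 200, 200, 700),
                c("c1", "c2", "c3", "c1"))
  pb <- pseudobulk(fr)
  expect_equal(length(pb), 2L)
  expect_equal(mcols(pb)$count[1], 3L)      # same fragment in 3 cells
  expect_equal(sum(mcols(pb)$count), 4L)
  # pseudobulk of a single cell is that cell's fragments
  one <- mkFrags(c(101, 301), c(200, 400), c("c1", "c1"))
  pb1 <- pseudobulk(one)
  expect_equal(start(pb1), start(one))
  expect_error(pseudobulk(mkFrags(1, 10, NA_character_)), "barcoded")
})

test_that("count matrix respects overlaps, zeros, and conservation", {
  peaks <- mkPeakSet(c(101, 301, 1001), c(200, 400, 1200),
                     c("Pol2S5p", "Pol2S5p", "H3K27me3"))
  fr <- mkFrags(c(150, 180, 5001, 1100, 1100), c(350, 190, 5100, 1150, 1150),
                c("c1", "c2", "c3", "c1", "c1"))
  se <- countMatrix(fr, peaks)
  m <- as.matrix(SummarizedExperiment::assay(se, "counts"))
  # fragment c1:[150,350] spans two adjacent peaks -> counted in both
  expect_equal(m[, "c1"], c(1, 1, 2), ignore_attr = TRUE)
  # c3 has no in-peak fragments but keeps its all-zero column
  expect_equal(sum(m[, "c3"]), 0)
  expect_equal(SummarizedExperiment::colData(se)$librarySize,
               c(3, 1, 1), ignore_attr = TRUE)
  # column sums equal the pseudo-bulk in-peak count per cell
  ov <- findOverlaps(pseudobulk(fr), peaks)
  expect_equal(sum(m), length(ov) * 1 + 1)  # dup fragment carries count 2
  # overlap-class peaks are excluded
  peaks2 <- c(peaks, mkPeakSet(101, 150, "overlap"))
  expect_equal(nrow(countMatrix(fr, peaks2)), 3L)
  expect_error(countMatrix(fr, mkPeakSet(1, 10, "overlap")), "overlap")
})

test_that("TF-IDF is binarization-invariant and follows the pinned formula", {
  peaks <- mkPeakSet(c(101, 301, 601), c(200, 400, 700),
                     c("Pol2S5p", "Pol2S5p", "H3K27me3"))
  fr <- c(mkFrags(c(110, 120, 310), c(150, 160, 350), c("c1", "c1", "c1")),
          mkFrags(c(110, 610), c(150, 650), c("c2", "c2")),
          mkFrags(c(310, 610), c(350, 650), c("c3", "c3")))
  se <- countMatrix(fr, peaks)
  norm <- tfidfNormalize(se)
  # manual recomputation for the Pol2S5p block
  b <- (as.matrix(SummarizedExperiment::assay(se))[1:2, ] > 0) * 1
  tf <- sweep(b, 2, pmax(colSums(b), 1), "/")
  idf <- log(1 + 3 / (1 + rowSums(b)))
  expect_equal(as.matrix(norm)[1:2, ], log(tf * idf * 1e4 + 1),
               ignore_attr = TRUE)
  # scaling all counts leaves the output unchanged
  se2 <- se
  SummarizedExperiment::assay(se2, "counts") <-
    SummarizedExperiment::assay(se, "counts") * 7
  expect_equal(as.matrix(tfidfNormalize(se2)), as.matrix(norm))
  # a peak present in every cell gets the minimal IDF ~ log 2
  expect_equal(idf[1], log(1 + 3 / (1 + 2)), ignore_attr = TRUE)
  expect_equal(attr(norm, "target"), c("Pol2S5p", "Pol2S5p", "H3K27me3"))
})

test_that("LSI embedding is deterministic and duplicates map together", {
  set.seed(8)
  m <- Matrix::Matrix(matrix(rpois(40 * 12, 1.5), 12, 40), sparse = TRUE)
  rownames(m) <- paste0("p", 1:12)
  colnames(m) <- paste0("c", 1:40)
  lib <- colSums(as.matrix(m)) + 1
  emb <- lsiEmbed(log1p(m), lib, nComponents = 8)
  emb2 <- lsiEmbed(log1p(m), lib, nComponents = 8)
  expect_identical(emb@coords, emb2@coords)
  # duplicating every cell gives paired identical coordinates
  m2 <- cbind(m, m)
  colnames(m2) <- c(colnames(m), paste0("d", 1:40))
  embD <- lsiEmbed(log1p(m2), c(lib, lib), nComponents = 8)
  expect_equal(unname(embD@allCoords[1:40, ]),
               unname(embD@allCoords[41:80, ]), tolerance = 1e-8)
  expect_error(lsiEmbed(m[1, , drop = FALSE], lib), "rank")
})

test_that("variable-peak ranking ignores flat peaks and caps at k", {
  coords <- matrix(rnorm(20), 10, 2)
  load <- matrix(c(0.9, 0.5, 0, 0.1, -0.7, 0.2), 6, 1)
  emb <- new("LsiEmbedding", coords = coords, allCoords = coords,
             loadings = cbind(load, 0), d = c(3, 1), excluded = integer(0),
             libSize = rep(1, 10))
  rownames(emb@loadings) <- paste0("p", 1:6)
  targets <- c("Pol2S5p", "Pol2S5p", "Pol2S5p", "H3K27me3", "H3K27me3",
               "H3K27me3")
  expect_equal(nrow(variablePeaks(emb, targets, k = 0)), 0L)
  top <- variablePeaks(emb, targets, k = 1)
  expect_equal(top$peak, c("p1", "p5"))     # largest |loading| per target
  # zero-loading peak cannot outrank varying peaks
  all3 <- suppressWarnings(variablePeaks(emb, targets, k = 3))
  polRanks <- all3$peak[all3$target == "Pol2S5p"]
  expect_equal(polRanks[3], "p3")
  w <- testthat::capture_warnings(variablePeaks(emb, targets, k = 10))
  expect_true(any(grepl("exceeds", w)))
})
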