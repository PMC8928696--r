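test_that("target-fraction formula respects its bounds and endpoints", {
  # r = (1 + 2 rhat) / 8 maps [0, 1] to [0.125, 0.375] with midpoint 0.25
  rFrac <- function(rHat) (1 + 2 * rHat) / 8
  expect_equal(rFrac(0), 0.125)
  expect_equal(rFrac(1), 0.375)
  expect_equal(rFrac(0.5), 0.25)
  # large equal integrals push rhat to 0.5
  res <- fakeResult(gridPos = seq(0, 990, 10), polDens = rep(1, 100),
                    k27Dens = rep(1, 100), cutPos = c(100, 500),
                    cutPolDens = c(1, 1), cutK27Dens = c(1, 1))
  est <- estimateTargetFraction(res, "pol")
  expect_equal(est$rHat, 0.5, tolerance = 1e-3)
  expect_equal(est$rFrac, 0.25, tolerance = 1e-3)
  # zero combined integral errors
  res0 <- fakeResult(seq(0, 90, 10), rep(0, 10), rep(0, 10), 10, 1, 1)
  expect_error(estimateTargetFraction(res0), "zero combined")
})

test_that("weighted quantile is left-continuous in cumulative weight", {
  expect_equal(weightedQuantile(c(1, 2, 3), c(1, 1, 1), 0.5), 2)
  expect_equal(weightedQuantile(c(1, 2, 3), c(10, 1, 1), 0.5), 1)
  expect_equal(weightedQuantile(5, 2, 0.99), 5)
})

test_that("a single strong bump yields exactly one summit-bearing peak", {
  gridPos <- seq(0, 4990, by = 10)
  bump <- 1 + 10 * exp(-((gridPos - 2500) / 150)^2 / 2)   # 10x background
  cutPos <- seq(2100, 2900, by = 20)
  cutDens <- 1 + 10 * exp(-((cutPos - 2500) / 150)^2 / 2)
  res <- fakeResult(gridPos, bump, rep(1, length(gridPos)), cutPos,
                    cutDens, rep(1, length(cutPos)))
  est <- list(rHat = 0.5, rFrac = 0.25)
  pk <- callPolPeaks(res, est)
  expect_length(pk, 1)
  expect_gt(width(pk), 100)
  summit <- mcols(pk)$summit
  expect_true(summit >= start(pk) - 1 && summit < end(pk))
  expect_lt(abs(summit - 2500), 20)
  # brute-force threshold oracle: same supra-threshold run
  thr <- weightedQuantile(cutDens, rep(1, length(cutDens)), 1 - 0.25)
  above <- gridPos[bump >= thr]
  expect_equal(start(pk) - 1, min(above))
  expect_equal(end(pk), max(above) + 10)
})

test_that("width filters are strict and contraction is monotone", {
  gridPos <- seq(0, 2990, by = 10)
  sig <- rep(1, length(gridPos))
  sig[gridPos >= 1000 & gridPos < 1080] <- 50    # 80 bp wide run
  cutPos <- c(500, 1040, 2000)
  res <- fakeResult(gridPos, sig, rep(1, 300), cutPos, c(1, 50, 1),
                    rep(1, 3))
  pk <- callPolPeaks(res, list(rHat = 0.5, rFrac = 0.25))
  expect_length(pk, 0)                           # 80 <= 100 discarded
  # a cut-free supra-threshold run is not a candidate peak, and a cut-bearing
  # one at 80 bp fails the width filter
  sig2 <- rep(0.5, length(gridPos))
  sig2[gridPos >= 1000 & gridPos < 1300] <- 50
  sig2[gridPos >= 2460 & gridPos < 2540] <- 5
  res2 <- fakeResult(gridPos, sig2, rep(1, 300), c(500, 2000, 2500),
                     c(0.5, 0.5, 5), rep(1, 3))
  expect_length(callPolPeaks(res2, list(rHat = 0.5, rFrac = 0.25)), 0)
  # raising the threshold never widens any run
  v <- 1 + 5 * exp(-((gridPos - 1500) / 300)^2 / 2)
  lo <- tagsep:::.callRuns(gridPos, v, 2, gridPos, 10)
  hi <- tagsep:::.callRuns(gridPos, v, 4, gridPos, 10)
  expect_true(hi[1, 1] >= lo[1, 1] && hi[1, 2] <= lo[1, 2])
})

test_that("domain smoothing bridges shallow dips and unions stay supersets", {
  pitch <- 10
  gridPos <- seq(0, 39990, by = pitch)
  # two 2-kb blocks separated by a 500-bp dip, on a long low background
  bg <- 0.02 + 0.06 * gridPos / max(gridPos)
  sig <- bg
  sig[gridPos >= 8000 & gridPos < 10000] <- 1
  sig[gridPos >= 10500 & gridPos < 12500] <- 1
  blockCuts <- seq(8000, 12490, by = 30)
  bgCuts <- setdiff(seq(50, 39950, by = 60), 7500:13000)
  cutPos <- sort(c(blockCuts, bgCuts))
  cutDens <- approx(gridPos, sig, xout = cutPos, rule = 2)$y
  cutDens[cutPos >= 10000 & cutPos < 10500] <- 0.05
  sig[gridPos >= 10000 & gridPos < 10500] <- 0.05
  res <- fakeResult(gridPos, rep(0.05, length(gridPos)), sig, cutPos,
                    rep(0.05, length(cutPos)), cutDens)
  est <- list(rHat = 0.5, rFrac = 0.25)
  dom <- callK27Domains(res, est, minWidth = 400, smoothSd = 2000)
  # the dip is bridged: one domain containing both blocks
  covers <- start(dom) - 1 <= 8100 & end(dom) >= 12400
  expect_true(any(covers))
  # while the raw-signal calls keep the blocks separate
  raw <- tagsep:::.callTarget(deconvGridTable(res), deconvCutTable(res),
                              "k27", est$rFrac, pitch, NULL)
  expect_gte(nrow(raw), 2)
  # every raw-signal domain is contained in some final domain
  for (i in seq_len(nrow(raw)))
    expect_true(any(start(dom) - 1 <= raw$start[i] & end(dom) >= raw$end[i]))
  # a 350-bp block is discarded by the strict 400-bp filter
  sig2 <- rep(0.05, length(gridPos))
  sig2[gridPos >= 5000 & gridPos < 5350] <- 5
  cp2 <- seq(50, 39950, by = 40)
  inBlock <- cp2 >= 5000 & cp2 < 5350
  res2 <- fakeResult(gridPos, rep(0.05, length(gridPos)), sig2, cp2,
                     rep(0.05, length(cp2)), ifelse(inBlock, 5, 0.05),
                     cutWeight = ifelse(inBlock, 100, 1))
  expect_length(callK27Domains(res2, list(rHat = 0.1, rFrac = 0.15),
                               minWidth = 400, smoothSd = 2000), 0)
})

test_that("smoothing leaves a constant signal unchanged", {
  v <- rep(3.7, 500)
  expect_equal(tagsep:::.gaussSmooth(v, 20), v, tolerance = 1e-12)
})

test_that("overlap resolution follows the 50%-of-own-span rule", {
  mkPeaks <- function(s, e, tg) {
    gr <- GRanges("chr1", IRanges(s, e))
    mcols(gr)$target <- tg
    mcols(gr)$summit <- NA_real_
    mcols(gr)$score <- 1
    gr
  }
  # 1000-bp domain overlapped 400 bp by a Pol peak: 40% < 50%, keeps label;
  # the 200-bp Pol peak fully inside is 100% covered -> overlap class
  k27 <- mkPeaks(1001, 2000, "H3K27me3")
  pol <- mkPeaks(c(1601, 1201), c(2000, 1400), "Pol2S5p")
  out <- resolveOverlaps(mkPeaks(1201, 1400, "Pol2S5p"), k27)
  expect_equal(mcols(out)$target[width(out) == 200], "overlap")
  expect_equal(mcols(out)$target[width(out) == 1000], "H3K27me3")
  # 400/1000 overlap: domain keeps label; 400-bp pol peak is fully inside
  out2 <- resolveOverlaps(mkPeaks(1601, 2000, "Pol2S5p"), k27)
  expect_equal(sort(as.character(mcols(out2)$target)),
               c("H3K27me3", "overlap"))
  # disjoint sets keep their labels and conserve counts
  polD <- mkPeaks(c(101, 3001), c(400, 3300), "Pol2S5p")
  k27D <- mkPeaks(5001, 7000, "H3K27me3")
  out3 <- resolveOverlaps(polD, k27D)
  expect_length(out3, 3)
  expect_equal(sum(mcols(out3)$target == "overlap"), 0)
})
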