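test_that("per-peak mean fragment size is weighted and half-open", {
  genome <- Seqinfo("chr1", 100000L)
  peaks <- GRanges("chr1", IRanges(c(1001, 5001), c(1500, 5500)))
  frags <- GRanges("chr1", IRanges(c(1101, 1201, 901, 4801, 5101),
                                   c(1200, 1400, 1000, 5000, 5400)))
  mcols(frags)$count <- rep(1L, 5)
  mcols(frags)$barcode <- NA_character_
  # fragments chr1:[900,1000) and [4800,5000) abut peaks -> no overlap
  prof <- meanFragmentSizePerPeak(frags, peaks)
  expect_equal(prof$peak, c(1L, 2L))
  expect_equal(prof$meanFraglen[1], mean(c(100, 200)))
  expect_equal(prof$meanFraglen[2], 300)   # abutting [4800,5000) excluded
  # count weighting: lengths 100 (count 3) and 200 (count 1) -> 125
  mcols(frags)$count <- c(3L, 1L, 1L, 1L, 1L)
  prof <- meanFragmentSizePerPeak(frags, peaks)
  expect_equal(prof$meanFraglen[1], 125)
  # dropped peak is reported
  peaks3 <- c(peaks, GRanges("chr1", IRanges(90001, 90500)))
  expect_message(meanFragmentSizePerPeak(frags, peaks3), "1 peaks without")
  expect_error(meanFragmentSizePerPeak(frags, rev(peaks)), "sorted")
  expect_error(
    meanFragmentSizePerPeak(frags,
      GRanges("chr1", IRanges(c(1001, 1200), c(1500, 1600)))),
    "non-overlapping")
})

test_that("EM recovers two separated components deterministically", {
  set.seed(204)
  truthClass <- rbinom(1000, 1, 0.5)
  x <- ifelse(truthClass == 1, rnorm(1000, 250, 40), rnorm(1000, 90, 15))
  fit <- fitTwoGaussianEM(x)
  expect_lt(abs(fit@means[1] - 90), 10)
  expect_lt(abs(fit@means[2] - 250), 10)
  expect_true(all(diff(fit@loglikTrace) > -1e-8))
  # classification against the simulation truth
  cls <- as.integer(x >= fit@threshold)
  expect_gte(mean(cls == truthClass), 0.95)
  # independent EM implementation agrees on the component means
  if (requireNamespace("mclust", quietly = TRUE)) {
    suppressMessages(library(mclust))
    mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    expect_lt(max(abs(sort(mc$parameters$mean) - fit@means)), 2)
  }
  expect_error(fitTwoGaussianEM(rep(100, 50)), "degenerate")
  expect_error(fitTwoGaussianEM(c(1, 2)), "at least 4")
})

test_that("intersection threshold matches closed forms and a grid oracle", {
  mk <- function(w, mu, sg) new("TwoGaussianFit", weights = w, means = mu,
                                sds = sg, loglikTrace = 0,
                                threshold = NA_real_, degenerate = FALSE,
                                thresholdFallback = FALSE)
  # equal weights, equal sds: midpoint
  f <- intersectionThreshold(mk(c(0.5, 0.5), c(100, 300), c(20, 20)))
  expect_equal(f@threshold, 200, tolerance = 1e-9)
  f2 <- intersectionThreshold(mk(c(0.3, 0.7), c(80, 260), c(25, 25)))
  # equal sds closed form: midpoint shifted by log-weight ratio
  shift <- 25^2 / (260 - 80) * log(0.3 / 0.7)
  expect_equal(f2@threshold, 170 + shift, tolerance = 1e-9)
  # unequal sds: compare with brute-force argmin of |difference| on a grid
  w <- c(0.45, 0.55); mu <- c(95, 240); sg <- c(14, 55)
  f3 <- intersectionThreshold(mk(w, mu, sg))
  grid <- seq(95, 240, by = 0.01)
  diffs <- abs(w[1] * dnorm(grid, mu[1], sg[1]) -
               w[2] * dnorm(grid, mu[2], sg[2]))
  expect_lt(abs(f3@threshold - grid[which.min(diffs)]), 0.02)
  expect_false(f3@thresholdFallback)
  # no crossing between the means -> midpoint fallback, flagged
  f4 <- intersectionThreshold(mk(c(0.999, 0.001), c(100, 120), c(30, 30)))
  expect_true(f4@thresholdFallback)
  expect_equal(f4@threshold, 110)
})

test_that("partition is exhaustive, disjoint, and ties go large", {
  prof <- data.frame(peak = 1:4, chrom = "chr1", start = 0, end = 1,
                     nFragments = 1, meanFraglen = c(150, 160, 159.999, 300))
  part <- partitionPeaks(prof, 160)
  expect_equal(nrow(part$small) + nrow(part$large), 4L)
  expect_true(160 %in% part$large$meanFraglen)       # tie -> large
  expect_true(all(part$small$meanFraglen < 160))
  expect_length(intersect(part$small$peak, part$large$peak), 0)
})

test_that("end-to-end size classification separates simulated classes", {
  set.seed(77)
  genome <- Seqinfo("chr1", 1000000L)
  nP <- 60
  starts <- seq(2000, 990000, length.out = 2 * nP)
  peaks <- GRanges("chr1", IRanges(starts, starts + 400))
  isLarge <- rep(c(FALSE, TRUE), nP)
  frs <- lapply(seq_along(starts), function(i) {
    n <- 30
    len <- round(rnorm(n, if (isLarge[i]) 250 else 90,
                       if (isLarge[i]) 40 else 15))
    len <- pmax(len, 20)
    s <- round(runif(n, starts[i], starts[i] + 400 - 1))
    GRanges("chr1", IRanges(s, s + len - 1))
  })
  frags <- do.call(c, frs)
  mcols(frags)$count <- 1L
  mcols(frags)$barcode <- NA_character_
  res <- classifyPeaksBySize(frags, peaks)
  called <- res$profiles$peak %in% res$large$peak
  expect_gte(mean(called == isLarge[res$profiles$peak]), 0.95)
  expect_true(all(diff(res$fit@loglikTrace) > -1e-8))
})
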