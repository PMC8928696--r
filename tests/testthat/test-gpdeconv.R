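test_that("Matern-3/2 kernel has unit variance and known values", {
  expect_equal(matern32(0, 500), 1)
  expect_equal(matern32(500, 500), (1 + sqrt(3)) * exp(-sqrt(3)),
               tolerance = 1e-12)
  d <- seq(0, 5000, by = 50)
  expect_true(all(diff(matern32(d, 700)) < 0))
  expect_error(matern32(1, 0), "positive")
  expect_error(matern32(-1, 10), "nonnegative")
})

test_that("state-space representation reproduces the Matern kernel exactly", {
  set.seed(5)
  pos <- sort(sample(1:20000, 15))
  for (ell in c(500, 2000)) {
    pre <- tagsep:::.ssm_precompute(pos, ell)
    # the map z -> states is linear; build it column by column and check
    # that the implied covariance of g equals the dense kernel matrix
    n <- length(pos)
    Tm <- vapply(seq_len(2 * n), function(k) {
      z <- numeric(2 * n); z[k] <- 1
      as.numeric(tagsep:::.ssm_states(z, pre$A, pre$L, pre$lambda))
    }, numeric(2 * n))
    S <- Tm %*% t(Tm)
    # .ssm_states returns n x 2; as.numeric is column-major: g rows first
    gIdx <- seq_len(n)
    K <- S[gIdx, gIdx]
    expect_equal(K, maternKernelMatrix(pos, ell), tolerance = 1e-7)
  }
})

test_that("rectangle rule uses midpoint widths with full terminal gaps", {
  expect_equal(rectangleWidths(c(0, 10, 30)), c(10, 15, 20))
  expect_equal(rectangleWidths(5), 1)
  # equally spaced constant values: ~ v * s * n
  pos <- seq(0, 90, by = 10)
  expect_equal(rectangleIntegral(pos, rep(2, 10)), 2 * 10 * 10)
  # smooth function: agrees with fine-grid quadrature within 20% on a toy
  pos <- c(0, 10, 30)
  vals <- exp(-((pos - 15) / 20)^2)
  fine <- seq(-5, 50, by = 0.01)
  ref <- sum(exp(-((fine - 15) / 20)^2)) * 0.01
  expect_lt(abs(rectangleIntegral(pos, vals) / ref - 1), 0.2)
  expect_error(rectangleWidths(c(3, 2)), "increasing")
})

test_that("log posterior matches a hand computation on a one-cut instance", {
  cfg <- gpConfig()
  prior <- lengthPrior()
  reg <- makeRegion(pos = 1000, fraglen = 150, coreStart = 999,
                    coreEnd = 1001, cfg = cfg)
  gP <- -0.3; gK <- -0.5
  wP <- dirichletMean(prior@alphaPol); wK <- dirichletMean(prior@alphaK27)
  lp <- logPosterior(reg, gP, gK, wP, wK, cfg, prior)
  # by hand: single unique position, rectangle width 1
  hP <- lengthPdf(150, wP, prior); hK <- lengthPdf(150, wK, prior)
  I <- exp(gP) + exp(gK)
  lik <- log(exp(gP) * hP + exp(gK) * hK) - 1 * (log(I) - log(1))
  gp <- dnorm(gP, 0, sqrt(1 + cfg@jitter), log = TRUE) +
    dnorm(gK, 0, sqrt(1 + cfg@jitter), log = TRUE)
  dir <- dirichletLogDensity(wP, prior@alphaPol) +
    dirichletLogDensity(wK, prior@alphaK27)
  pen <- dlnorm(I, 0, cfg@integralSd, log = TRUE)
  expect_equal(lp, lik + gp + dir + pen, tolerance = 1e-10)
  # pushing g far positive is punished by the integral constraint
  expect_lt(logPosterior(reg, 5, gK, wP, wK, cfg, prior), lp)
  expect_error(logPosterior(reg, NaN, gK, wP, wK, cfg, prior), "finite")
})

test_that("region selection matches a brute-force KDE oracle", {
  cfg <- gpConfig()
  genome <- Seqinfo("chrT", 100000L)
  empty <- cutSites(character(0), numeric(0), numeric(0), numeric(0))
  expect_length(selectRegions(empty, genome, cfg), 0)
  # 1000 cuts uniform in a 10-kb window: one region covering the window
  set.seed(31)
  pos <- sort(sample(40000:50000, 1000))
  cuts <- cutSites(rep("chrT", length(pos)), pos, rep(100, length(pos)))
  reg <- selectRegions(cuts, genome, cfg)
  expect_length(reg, 1)
  expect_lt(abs(start(reg) - 1 - 40000), 3 * cfg@kdeBandwidth)
  expect_lt(abs(end(reg) - 50000), 3 * cfg@kdeBandwidth)
  # interval endpoints agree with the brute-force KDE threshold crossing
  at <- seq(39000, 51000, by = 7)
  dens <- bruteKde(at, cuts@pos, cuts@weight, cfg@kdeBandwidth)
  above <- at[dens >= cfg@minDensity]
  expect_lt(abs(min(above) - (start(reg) - 1)), 15)
  expect_lt(abs(max(above) - end(reg)), 15)
  # two dense clusters 5 kb apart merge into one region
  pos2 <- c(sort(sample(10000:12000, 500)), sort(sample(17000:19000, 500)))
  cuts2 <- cutSites(rep("chrT", 1000), pos2, rep(100, 1000))
  expect_length(selectRegions(cuts2, genome, cfg), 1)
  # 15 kb apart stays two regions
  pos3 <- c(sort(sample(10000:12000, 500)), sort(sample(27000:29000, 500)))
  cuts3 <- cutSites(rep("chrT", 1000), pos3, rep(100, 1000))
  expect_length(selectRegions(cuts3, genome, cfg), 2)
})

test_that("interval splitting respects the unique-site cap and padding", {
  cfg <- gpConfig()
  mkCuts <- function(n) cutSites(rep("chrT", n), seq_len(n) * 2,
                                 rep(100, n))
  expect_length(splitIntervals("chrT", 0, 20010, mkCuts(9999), cfg), 1)
  chunks <- splitIntervals("chrT", 0, 20010, mkCuts(10001), cfg)
  expect_length(chunks, 2)
  expect_true(all(vapply(chunks, function(r)
    sum(r@pos >= r@coreStart & r@pos < r@coreEnd), 1) <= 10000))
  # cores tile the region
  expect_equal(chunks[[1]]@coreEnd, chunks[[2]]@coreStart)
  # a cut 9,999 bp outside the core is used in inference, not in output
  cuts <- cutSites(rep("chrT", 3), c(30000, 39999, 50000), rep(100, 3))
  ch <- splitIntervals("chrT", 40000 - 1, 50001, cuts, cfg)[[1]]
  expect_true(30000 %in% ch@pos)            # within 10 kb padding
  tr <- mapDeconvolve(ch, gpConfig(gridPitch = 100), lengthPrior())
  expect_false(30000 %in% tr@cutPos)
  expect_true(all(tr@cutPos >= ch@coreStart & tr@cutPos < ch@coreEnd))
})

test_that("MAP matches the dense-kernel multi-start oracle on small data", {
  set.seed(11)
  pos <- sort(sample(500:4500, 18))
  events <- sample(pos, 36, replace = TRUE)
  frl <- ifelse(events < 2500, sample(c(70, 90), 36, replace = TRUE),
                sample(c(350, 450), 36, replace = TRUE))
  cfg <- gpConfig()
  prior <- lengthPrior()
  reg <- makeRegion(events, frl, coreStart = 400, coreEnd = 4600,
                    cfg = cfg)
  expect_lte(length(reg@pos), 30)
  tr <- mapDeconvolve(reg, cfg, prior)
  lp <- logPosterior(reg, tr@cutLogPol, tr@cutLogK27, tr@wPol, tr@wK27,
                     cfg, prior)
  oracle <- denseMapOracle(reg, cfg, prior, nStarts = 3, seed = 42)
  expect_lt(abs(lp - oracle), 1e-3)
  # integral conservation within 1% on the converged chunk
  expect_lt(abs((tr@integralFullPol + tr@integralFullK27) /
                tr@totalWeightFull - 1), 0.01)
  # determinism: a rerun is bitwise identical
  tr2 <- mapDeconvolve(reg, cfg, prior)
  expect_identical(tr@cutLogPol, tr2@cutLogPol)
  expect_identical(tr@gridLogK27, tr2@gridLogK27)
})

test_that("exchange-symmetric targets yield identical tracks", {
  set.seed(19)
  pos <- sort(sample(1000:3000, 25))
  cfg <- gpConfig(lengthscalePol = 800, lengthscaleK27 = 800)
  prior <- lengthPrior(alphaPol = c(100, 100, 20, 5),
                       alphaK27 = c(100, 100, 20, 5))
  reg <- makeRegion(pos, sample(c(100, 300), 25, replace = TRUE),
                    cfg = cfg)
  tr <- mapDeconvolve(reg, cfg, prior)
  expect_equal(tr@cutLogPol, tr@cutLogK27, tolerance = 1e-4)
  expect_equal(tr@wPol, tr@wK27, tolerance = 1e-4)
})

test_that("grid interpolation equals the dense GP conditional mean", {
  set.seed(23)
  pos <- sort(sample(1000:4000, 12))
  cfg <- gpConfig(gridPitch = 50)
  prior <- lengthPrior()
  reg <- makeRegion(pos, sample(c(80, 400), 12, replace = TRUE),
                    coreStart = 950, coreEnd = 4050, cfg = cfg)
  tr <- mapDeconvolve(reg, cfg, prior)
  K <- maternKernelMatrix(reg@pos, cfg@lengthscalePol, cfg@jitter)
  kx <- matern32(abs(outer(tr@gridPos, reg@pos, "-")), cfg@lengthscalePol)
  dense <- drop(kx %*% solve(K, tr@cutLogPol))
  expect_equal(tr@gridLogPol, dense, tolerance = 1e-3)
})

test_that("padding keeps chunk boundaries consistent across a feature", {
  # one broad feature astride a forced split: adjacent chunks agree at the
  # boundary because each sees 10 kb of context
  set.seed(41)
  centers <- rnorm(3000, 20000, 1500)
  pos <- round(c(centers - 100, centers + 100))
  pos <- pos[pos > 0]
  cuts <- cutSites(rep("chrT", length(pos)), pos,
                   rep(c(200, 200), length.out = length(pos)))
  cfg <- gpConfig(maxSitesPerChunk = 1000)
  genome <- Seqinfo("chrT", 50000L)
  res <- deconvolveGenome(cuts, genome, cfg)
  expect_gt(length(res@tracks), 1)
  for (i in seq_len(length(res@tracks) - 1)) {
    a <- res@tracks[[i]]; b <- res@tracks[[i + 1]]
    va <- exp(a@gridLogK27[length(a@gridLogK27)])
    vb <- exp(b@gridLogK27[1])
    expect_lt(abs(va / vb - 1), 0.1)
  }
  # concatenated grid is strictly increasing with no overlap
  allPos <- unlist(lapply(res@tracks, function(t) t@gridPos))
  expect_true(all(diff(allPos) > 0))
})

test_that("independent far-apart regions give order-stable tracks", {
  set.seed(43)
  pos <- c(sort(sample(10000:12000, 400)), sort(sample(60000:62000, 400)))
  cuts <- cutSites(rep("chrT", 800), pos,
                   sample(c(80, 300), 800, replace = TRUE))
  genome <- Seqinfo("chrT", 100000L)
  res <- deconvolveGenome(cuts, genome, gpConfig())
  expect_length(res@tracks, 2)
  expect_lt(res@tracks[[1]]@coreEnd, res@tracks[[2]]@coreStart)
  # a second run reproduces the result bitwise
  res2 <- deconvolveGenome(cuts, genome, gpConfig())
  expect_identical(deconvGridTable(res), deconvGridTable(res2))
})
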