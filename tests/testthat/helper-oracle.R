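# Independent oracles used across the suite.

# Whitened dense-kernel MAP oracle: multi-start L-BFGS on the dense
# logPosterior objective with g = L z (L the kernel Cholesky) and analytic
# gradients. Independent of the package's Markov/state-space optimizer path.
denseMapOracle <- function(reg, cfg, prior, nStarts = 4, seed = 1) {
  n <- length(reg@pos)
  phi <- lengthComponentDensities(reg@events$fraglen, prior)
  LP <- t(chol(maternKernelMatrix(reg@pos, cfg@lengthscalePol, cfg@jitter)))
  LK <- t(chol(maternKernelMatrix(reg@pos, cfg@lengthscaleK27, cfg@jitter)))
  widths <- rectangleWidths(reg@pos)
  W <- reg@totalWeight
  u <- reg@events$uidx
  wE <- reg@events$weight
  KPi <- chol2inv(chol(LP %*% t(LP)))
  KKi <- chol2inv(chol(LK %*% t(LK)))
  sm <- function(eta) { e <- exp(c(0, eta) - max(0, eta)); e / sum(e) }
  fn <- function(p) {
    gP <- drop(LP %*% p[1:n]); gK <- drop(LK %*% p[n + 1:n])
    -logPosterior(reg, gP, gK, sm(p[2 * n + 1:3]), sm(p[2 * n + 4:6]),
                  cfg, prior)
  }
  gr <- function(p) {
    gP <- drop(LP %*% p[1:n]); gK <- drop(LK %*% p[n + 1:n])
    eP <- exp(gP); eK <- exp(gK)
    wP <- sm(p[2 * n + 1:3]); wK <- sm(p[2 * n + 4:6])
    hP <- drop(phi %*% wP); hK <- drop(phi %*% wK)
    tP <- eP[u] * hP; tK <- eK[u] * hK; D <- tP + tK
    dgP <- -as.numeric(tapply(wE * tP / D, factor(u, 1:n), sum))
    dgK <- -as.numeric(tapply(wE * tK / D, factor(u, 1:n), sum))
    dgP[is.na(dgP)] <- 0; dgK[is.na(dgK)] <- 0
    dwP <- -colSums(wE * eP[u] * phi / D)
    dwK <- -colSums(wE * eK[u] * phi / D)
    I <- sum(widths * (eP + eK))
    dI <- W / I + (log(I) - log(W)) / (cfg@integralSd^2 * I) + 1 / I
    dgP <- dgP + dI * widths * eP + drop(KPi %*% gP)
    dgK <- dgK + dI * widths * eK + drop(KKi %*% gK)
    dwP <- dwP - (prior@alphaPol - 1) / wP
    dwK <- dwK - (prior@alphaK27 - 1) / wK
    etaG <- function(dw, w) { cc <- sum(dw * w); w[2:4] * (dw[2:4] - cc) }
    c(drop(t(LP) %*% dgP), drop(t(LK) %*% dgK), etaG(dwP, wP),
      etaG(dwK, wK))
  }
  best <- Inf
  for (s in seq_len(nStarts)) {
    set.seed(seed + s)
    p0 <- c(rnorm(2 * n) * 0.8, rnorm(6) * 0.5)
    o <- optim(p0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = 30000, factr = 1e1, pgtol = 0))
    best <- min(best, o$value)
  }
  -best
}

# quantile of a four-mode log-normal mixture by grid inversion of the CDF
mixtureLengthQuantile <- function(p, weights, logSd = 0.4,
                                  modes = c(70, 200, 400, 600)) {
  mu <- log(modes) + logSd^2
  grid <- seq(1, 4000, by = 0.5)
  cdf <- rowSums(vapply(1:4, function(k)
    weights[k] * plnorm(grid, mu[k], logSd), numeric(length(grid))))
  vapply(p, function(pp) grid[which(cdf >= pp)[1]], numeric(1))
}

# brute-force weighted Gaussian KDE at integer positions
bruteKde <- function(at, pos, weight, sigma) {
  vapply(at, function(x) sum(weight * dnorm(x, pos, sigma)), numeric(1))
}

# small helper: build a DeconvRegion directly from cut vectors
makeRegion <- function(pos, fraglen, weight = rep(1, length(pos)),
                       coreStart = min(pos) - 1, coreEnd = max(pos) + 1,
                       cfg = gpConfig()) {
  cuts <- cutSites(rep("chrT", length(pos)), pos, fraglen, weight)
  tagsep:::.makeRegion("chrT", coreStart, coreEnd, cuts, cfg)
}

# minimal DeconvResult wrapping hand-constructed grid/cut tracks
fakeResult <- function(gridPos, polDens, k27Dens, cutPos, cutPolDens,
                       cutK27Dens, cutWeight = rep(1, length(cutPos)),
                       chrom = "chrT", pitch = 10) {
  track <- new("DeconvTrack", chrom = chrom, coreStart = min(gridPos),
               coreEnd = max(gridPos) + pitch, cutPos = cutPos,
               cutLogPol = log(cutPolDens), cutLogK27 = log(cutK27Dens),
               cutWeight = cutWeight, gridPos = gridPos,
               gridLogPol = log(polDens), gridLogK27 = log(k27Dens),
               wPol = c(0.7, 0.2, 0.07, 0.03), wK27 = c(0.3, 0.5, 0.15, 0.05),
               integralFullPol = sum(polDens) * pitch,
               integralFullK27 = sum(k27Dens) * pitch,
               integralCorePol = sum(polDens) * pitch,
               integralCoreK27 = sum(k27Dens) * pitch,
               totalWeightFull = sum(cutWeight), converged = TRUE,
               iterations = 0, objective = 0)
  new("DeconvResult", tracks = list(track), wPol = track@wPol,
      wK27 = track@wK27, config = gpConfig(gridPitch = pitch),
      prior = lengthPrior())
}
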