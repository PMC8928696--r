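#' Construct a deconvolution configuration
#'
#' Defaults are the model constants of the mixed-readout deconvolution:
#' Matern-3/2 length scales of 500 bp (Pol2S5p) and 2000 bp (H3K27me3),
#' integral constraint log-sd 0.001, KDE region selection with bandwidth
#' 200 bp and a floor of 2 cuts per 100 bp (0.02 cuts/bp), regions merged
#' when closer than 10,000 bp, inference chunks capped at 10,000 unique cut
#' positions with 10,000 bp padding, and a 10-bp output grid. Optimizer
#' controls are package choices: L-BFGS-B with an iteration cap of 15,000
#' and convergence on relative objective change (\code{factr}) or projected
#' gradient (\code{pgtol}).
#'
#' @param lengthscalePol,lengthscaleK27 kernel length scales in bp.
#' @param jitter diagonal stabilizer for dense kernel matrices.
#' @param integralSd log-scale sd of the integral constraint.
#' @param gridPitch output grid pitch in bp.
#' @param maxSitesPerChunk unique cut positions per inference chunk.
#' @param padding chunk padding in bp.
#' @param kdeBandwidth region-selection KDE bandwidth in bp.
#' @param minDensity region-selection density floor in cuts/bp.
#' @param mergeGap region merge distance in bp.
#' @param maxIterations,factr,pgtol L-BFGS-B controls.
#' @return a \code{\linkS4class{GPConfig}}.
#' @export
gpConfig <- function(lengthscalePol = 500, lengthscaleK27 = 2000,
                     jitter = 1e-6, integralSd = 0.001, gridPitch = 10,
                     maxSitesPerChunk = 10000, padding = 10000,
                     kdeBandwidth = 200, minDensity = 0.02,
                     mergeGap = 10000, maxIterations = 15000,
                     factr = 1e5, pgtol = 0) {
  new("GPConfig", lengthscalePol = lengthscalePol,
      lengthscaleK27 = lengthscaleK27, jitter = jitter,
      integralSd = integralSd, gridPitch = gridPitch,
      maxSitesPerChunk = maxSitesPerChunk, padding = padding,
      kdeBandwidth = kdeBandwidth, minDensity = minDensity,
      mergeGap = mergeGap, maxIterations = maxIterations, factr = factr,
      pgtol = pgtol)
}

#' Matern-3/2 covariance
#'
#' Unit-variance Matern kernel with smoothness 3/2:
#' \eqn{(1 + \sqrt{3} d/\ell) \exp(-\sqrt{3} d/\ell)}.
#'
#' @param d nonnegative distances in bp.
#' @param lengthscale positive length scale in bp.
#' @return covariances.
#' @export
matern32 <- function(d, lengthscale) {
  if (lengthscale <= 0) stop("lengthscale must be positive")
  if (any(d < 0)) stop("distances must be nonnegative")
  s <- sqrt(3) * d / lengthscale
  (1 + s) * exp(-s)
}

#' Dense Matern-3/2 kernel matrix over positions
#' @param pos numeric positions.
#' @param lengthscale length scale in bp.
#' @param jitter value added to the diagonal.
#' @return covariance matrix.
#' @export
maternKernelMatrix <- function(pos, lengthscale, jitter = 0) {
  K <- matern32(abs(outer(pos, pos, "-")), lengthscale)
  K + diag(jitter, length(pos))
}

#' Rectangle-rule widths for irregular support points
#'
#' One rectangle per cut position: neighboring rectangles touch at the
#' midpoint between positions, and each terminal rectangle additionally
#' extends outwards by its one-sided gap, so terminal widths equal the full
#' adjacent gap. A single position gets width one.
#'
#' @param positions strictly increasing positions.
#' @return widths, same length as \code{positions}.
#' @export
rectangleWidths <- function(positions) {
  n <- length(positions)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(1)
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  gaps <- diff(positions)
  c(gaps[1], if (n > 2L) (positions[3:n] - positions[1:(n - 2)]) / 2,
    gaps[n - 1])
}

#' Rectangle-rule integral over cut positions
#' @param positions strictly increasing positions.
#' @param values nonnegative density values at the positions.
#' @return the approximate integral (in cuts when values are cuts/bp).
#' @export
rectangleIntegral <- function(positions, values) {
  sum(rectangleWidths(positions) * values)
}

.selectRegions0 <- function(pos, weight, chromLen, cfg) {
  if (!length(pos)) return(matrix(numeric(0), ncol = 2))
  sigma <- cfg@kdeBandwidth
  reach <- ceiling(4 * sigma)
  binWidth <- if (diff(range(pos)) > 5e6) 10L else 1L
  lo <- max(0, floor(min(pos)) - reach)
  hi <- min(chromLen, ceiling(max(pos)) + reach)
  nb <- floor((hi - lo) / binWidth) + 1L
  counts <- numeric(nb)
  idx <- pmin(nb, floor((pos - lo) / binWidth) + 1L)
  tw <- tapply(weight, idx, sum)
  counts[as.integer(names(tw))] <- tw
  kHalf <- ceiling(reach / binWidth)
  kernel <- dnorm(seq(-kHalf, kHalf) * binWidth, 0, sigma)
  # zero-pad so edge bins see the full kernel window (no cuts lie outside)
  padded <- c(numeric(kHalf), counts, numeric(kHalf))
  dens <- stats::filter(padded, kernel, sides = 2)[kHalf + seq_len(nb)]
  keep <- as.numeric(dens) >= cfg@minDensity
  if (!any(keep)) return(matrix(numeric(0), ncol = 2))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  iv <- cbind(lo + (runs[, 1] - 1L) * binWidth,
              pmin(chromLen, lo + runs[, 2] * binWidth))
  # merge intervals separated by fewer than mergeGap bp
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    if (iv[i, 1] - merged[nrow(merged), 2] < cfg@mergeGap)
      merged[nrow(merged), 2] <- iv[i, 2]
    else merged <- rbind(merged, iv[i, ])
  }
  merged
}

#' Select dense regions for deconvolution
#'
#' Gaussian kernel density estimate (bandwidth \code{kdeBandwidth}) of the
#' weighted cut positions; maximal intervals where the density reaches
#' \code{minDensity} cuts/bp are retained and neighboring intervals closer
#' than \code{mergeGap} bp are merged.
#'
#' @param cuts a \code{\linkS4class{CutSites}}.
#' @param genome a \code{Seqinfo}.
#' @param cfg a \code{\linkS4class{GPConfig}}.
#' @return \code{GRanges} of selected regions (possibly empty).
#' @export
selectRegions <- function(cuts, genome, cfg = gpConfig()) {
  out <- list()
  for (ch in unique(cuts@chrom)) {
    k <- cuts@chrom == ch
    iv <- .selectRegions0(cuts@pos[k], cuts@weight[k],
                          as.numeric(seqlengths(genome)[ch]), cfg)
    if (nrow(iv))
      out[[ch]] <- GRanges(ch, IRanges(iv[, 1] + 1, iv[, 2]),
                           seqinfo = genome)
  }
  if (!length(out)) return(GRanges(seqinfo = genome))
  GenomicRanges::sort(do.call(c, unname(out)))
}

#' Inference chunk of weighted cut sites
#'
#' One padded chunk of the chunked MAP inference: a core span (0-based
#' half-open) reported in the output, plus the cut events inside the core
#' and inside \code{padding} bp of context on each side, which stabilize
#' the fit at the boundaries and are discarded from the output.
#'
#' @slot chrom chromosome.
#' @slot coreStart,coreEnd 0-based half-open core span.
#' @slot pos unique cut positions of the padded chunk, sorted.
#' @slot events data.frame (uidx into \code{pos}, fraglen, weight).
#' @slot totalWeight total cut weight of the padded chunk.
#' @export
setClass("DeconvRegion",
  representation(chrom = "character", coreStart = "numeric",
                 coreEnd = "numeric", pos = "numeric", events = "data.frame",
                 totalWeight = "numeric"))

setMethod("show", "DeconvRegion", function(object) {
  cat(sprintf("DeconvRegion %s:%d-%d | %d unique positions, weight %.0f\n",
              object@chrom, object@coreStart, object@coreEnd,
              length(object@pos), object@totalWeight))
})

.makeRegion <- function(chrom, coreStart, coreEnd, cuts, cfg) {
  sel <- cuts@chrom == chrom & cuts@pos >= coreStart - cfg@padding &
    cuts@pos < coreEnd + cfg@padding
  pos <- sort(unique(cuts@pos[sel]))
  ev <- data.frame(uidx = match(cuts@pos[sel], pos),
                   fraglen = cuts@fraglen[sel], weight = cuts@weight[sel])
  new("DeconvRegion", chrom = chrom, coreStart = coreStart,
      coreEnd = coreEnd, pos = pos, events = ev,
      totalWeight = sum(ev$weight))
}

#' Split a selected region into inference chunks
#'
#' Contiguous chunks each holding at most \code{maxSitesPerChunk} unique
#' cut positions in their core; chunk boundaries fall at midpoints between
#' flanking cut positions so chunk cores tile the region, and every chunk
#' carries \code{padding} bp of context cuts on each side.
#'
#' @param chrom chromosome of the region.
#' @param start0,end0 0-based half-open region span.
#' @param cuts a \code{\linkS4class{CutSites}} (whole-genome; the relevant
#'   positions are extracted here).
#' @param cfg a \code{\linkS4class{GPConfig}}.
#' @return list of \code{\linkS4class{DeconvRegion}}.
#' @export
splitIntervals <- function(chrom, start0, end0, cuts, cfg = gpConfig()) {
  onChrom <- cuts@chrom == chrom
  u <- sort(unique(cuts@pos[onChrom & cuts@pos >= start0 &
                            cuts@pos < end0]))
  if (!length(u))
    return(list())
  nChunks <- ceiling(length(u) / cfg@maxSitesPerChunk)
  grp <- ceiling(seq_along(u) / (length(u) / nChunks))
  grp <- pmin(grp, nChunks)
  bounds <- numeric(nChunks + 1L)
  bounds[1] <- start0
  bounds[nChunks + 1L] <- end0
  if (nChunks > 1L) for (i in seq_len(nChunks - 1L))
    bounds[i + 1L] <- floor((max(u[grp == i]) + min(u[grp == i + 1L])) / 2)
  lapply(seq_len(nChunks), function(i)
    .makeRegion(chrom, bounds[i], bounds[i + 1L], cuts, cfg))
}

#' Log posterior of the deconvolution model (dense reference)
#'
#' The objective maximized by the MAP fit, written with the dense
#' Matern-3/2 kernel matrices: the weighted per-cut mixture log-likelihood
#' \eqn{\sum_i w_i \log[e^{g_P(x_i)} h_P(l_i) + e^{g_K(x_i)} h_K(l_i)]},
#' two zero-mean GP log-priors over the unique cut positions, Dirichlet
#' log-priors on both length-weight vectors, and the log-normal penalty
#' tying the rectangle-rule integral of the summed exponentiated densities
#' to the total cut weight. Intended for small instances (tests, oracles);
#' the optimizer uses an equivalent Markovian formulation.
#'
#' @param region a \code{\linkS4class{DeconvRegion}}.
#' @param gPol,gK27 log densities at \code{region@pos}.
#' @param wPol,wK27 length-mode weight vectors (4-simplex each).
#' @param cfg a \code{\linkS4class{GPConfig}}.
#' @param prior a \code{\linkS4class{LengthPrior}}.
#' @return the log posterior (up to parameterization-independent
#'   constants).
#' @export
logPosterior <- function(region, gPol, gK27, wPol, wK27,
                         cfg = gpConfig(), prior = lengthPrior()) {
  if (any(!is.finite(gPol)) || any(!is.finite(gK27)))
    stop("non-finite log densities")
  phi <- lengthComponentDensities(region@events$fraglen, prior)
  hP <- drop(phi %*% wPol)
  hK <- drop(phi %*% wK27)
  u <- region@events$uidx
  I <- rectangleIntegral(region@pos, exp(gPol) + exp(gK27))
  # mixture position factors are PDFs scaled to the total cut weight W:
  # each event's density carries a 1/(I/W) normalization
  lik <- sum(region@events$weight *
             log(exp(gPol[u]) * hP + exp(gK27[u]) * hK)) -
    region@totalWeight * (log(I) - log(region@totalWeight))
  gpLog <- function(g, ell) {
    K <- maternKernelMatrix(region@pos, ell, cfg@jitter)
    ch <- chol(K)
    alpha <- backsolve(ch, forwardsolve(t(ch), g))
    -0.5 * sum(g * alpha) - sum(log(diag(ch))) -
      length(g) / 2 * log(2 * pi)
  }
  pri <- gpLog(gPol, cfg@lengthscalePol) + gpLog(gK27, cfg@lengthscaleK27)
  dir <- dirichletLogDensity(wPol, prior@alphaPol) +
    dirichletLogDensity(wK27, prior@alphaK27)
  pen <- dlnorm(I, meanlog = log(region@totalWeight),
                sdlog = cfg@integralSd, log = TRUE)
  lik + pri + dir + pen
}

.deconvPrep <- function(region, cfg, prior) {
  pos <- region@pos
  list(preP = .ssm_precompute(pos, cfg@lengthscalePol),
       preK = .ssm_precompute(pos, cfg@lengthscaleK27),
       phi = lengthComponentDensities(region@events$fraglen, prior),
       widths = rectangleWidths(pos),
       uidx0 = as.integer(region@events$uidx - 1L),
       wEvent = region@events$weight,
       logW = log(region@totalWeight))
}

#' MAP deconvolution of one chunk
#'
#' Maximizes the model posterior over the two log-density vectors and the
#' two length-weight vectors by L-BFGS-B, starting from zero log densities
#' and the Dirichlet prior-mean weights. The Matern-3/2 processes are
#' optimized in their exact Markov (state-space) form with a non-centered
#' innovation parameterization, which leaves the maximizing log densities
#' identical to those of the dense-kernel objective. Densities are
#' reported at the core's unique cut positions and interpolated onto a
#' regular grid by the GP conditional mean; padding is discarded.
#'
#' @param region a \code{\linkS4class{DeconvRegion}} with at least one cut.
#' @param cfg a \code{\linkS4class{GPConfig}}.
#' @param prior a \code{\linkS4class{LengthPrior}}.
#' @return a \code{\linkS4class{DeconvTrack}}; non-convergence is flagged
#'   in the \code{converged} slot and the best iterate is returned.
#' @export
mapDeconvolve <- function(region, cfg = gpConfig(), prior = lengthPrior()) {
  n <- length(region@pos)
  if (n == 0L) stop("region has no cuts")
  prep <- .deconvPrep(region, cfg, prior)
  meanP <- dirichletMean(prior@alphaPol)
  meanK <- dirichletMean(prior@alphaK27)
  par0 <- c(numeric(4 * n), log(meanP[2:4] / meanP[1]),
            log(meanK[2:4] / meanK[1]))
  evalAt <- function(par, wantGrad) {
    .deconv_objective(par, n, prep$preP$A, prep$preP$L, prep$preP$lambda,
                      prep$preK$A, prep$preK$L, prep$preK$lambda,
                      prep$uidx0, prep$wEvent, prep$phi, prep$phi,
                      prep$widths, prep$logW, cfg@integralSd,
                      prior@alphaPol, prior@alphaK27, wantGrad)
  }
  cache <- new.env(parent = emptyenv())
  fn <- function(par) {
    r <- evalAt(par, TRUE)
    cache$par <- par
    cache$grad <- r$gradient
    r$value
  }
  gr <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$grad)
    evalAt(par, TRUE)$gradient
  }
  opt <- optim(par0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = cfg@maxIterations, factr = cfg@factr,
                              pgtol = cfg@pgtol, lmm = 10))
  par <- opt$par
  sP <- .ssm_states(par[seq_len(2 * n)], prep$preP$A, prep$preP$L,
                    prep$preP$lambda)
  sK <- .ssm_states(par[2 * n + seq_len(2 * n)], prep$preK$A, prep$preK$L,
                    prep$preK$lambda)
  wP <- softmaxRef(par[4 * n + 1:3])
  wK <- softmaxRef(par[4 * n + 4:6])
  core <- region@pos >= region@coreStart & region@pos < region@coreEnd
  pitch <- cfg@gridPitch
  gStart <- ceiling(region@coreStart / pitch) * pitch
  gridPos <- if (gStart < region@coreEnd)
    seq(gStart, region@coreEnd - 1e-9, by = pitch) else numeric(0)
  gridP <- if (length(gridPos))
    .ssm_interpolate(sP, region@pos, gridPos, cfg@lengthscalePol) else
    numeric(0)
  gridK <- if (length(gridPos))
    .ssm_interpolate(sK, region@pos, gridPos, cfg@lengthscaleK27) else
    numeric(0)
  cw <- tapply(region@events$weight, region@events$uidx, sum)
  cutWeight <- numeric(n)
  cutWeight[as.integer(names(cw))] <- cw
  ePfull <- exp(sP[, 1]); eKfull <- exp(sK[, 1])
  new("DeconvTrack", chrom = region@chrom, coreStart = region@coreStart,
      coreEnd = region@coreEnd, cutPos = region@pos[core],
      cutLogPol = sP[core, 1], cutLogK27 = sK[core, 1],
      cutWeight = cutWeight[core], gridPos = as.numeric(gridPos),
      gridLogPol = as.numeric(gridP), gridLogK27 = as.numeric(gridK),
      wPol = wP, wK27 = wK,
      integralFullPol = sum(prep$widths * ePfull),
      integralFullK27 = sum(prep$widths * eKfull),
      integralCorePol = sum(prep$widths[core] * ePfull[core]),
      integralCoreK27 = sum(prep$widths[core] * eKfull[core]),
      totalWeightFull = region@totalWeight,
      converged = opt$convergence == 0L,
      iterations = as.numeric(opt$counts[1]), objective = opt$value)
}

softmaxRef <- function(eta) {
  e <- exp(c(0, eta) - max(0, eta))
  e / sum(e)
}

#' Deconvolve a genome of cut sites
#'
#' Full pipeline: select dense regions, split them into padded chunks, run
#' the MAP fit per chunk, and pool the per-chunk length-weight estimates
#' (weighted by core cut weight). Chunks are independent; the result is
#' deterministic for fixed inputs and configuration.
#'
#' @param cuts a \code{\linkS4class{CutSites}}.
#' @param genome a \code{Seqinfo}.
#' @param cfg a \code{\linkS4class{GPConfig}}.
#' @param prior a \code{\linkS4class{LengthPrior}}.
#' @param verbose print per-chunk progress.
#' @return a \code{\linkS4class{DeconvResult}} (possibly with zero tracks
#'   when no region passes selection).
#' @export
deconvolveGenome <- function(cuts, genome, cfg = gpConfig(),
                             prior = lengthPrior(), verbose = FALSE) {
  regions <- selectRegions(cuts, genome, cfg)
  tracks <- list()
  for (i in seq_along(regions)) {
    ch <- as.character(GenomeInfoDb::seqnames(regions))[i]
    chunks <- splitIntervals(ch, start(regions)[i] - 1, end(regions)[i],
                             cuts, cfg)
    for (chunk in chunks) {
      if (verbose)
        message(sprintf("chunk %s:%d-%d (%d sites)", chunk@chrom,
                        chunk@coreStart, chunk@coreEnd, length(chunk@pos)))
      tracks[[length(tracks) + 1L]] <- mapDeconvolve(chunk, cfg, prior)
    }
  }
  if (!length(tracks)) {
    warning("no regions passed density selection; empty result")
    return(new("DeconvResult", tracks = list(),
               wPol = dirichletMean(prior@alphaPol),
               wK27 = dirichletMean(prior@alphaK27), config = cfg,
               prior = prior))
  }
  cw <- vapply(tracks, function(t) sum(t@cutWeight), 1)
  wP <- colSums(do.call(rbind, lapply(tracks, function(t) t@wPol)) *
                cw) / sum(cw)
  wK <- colSums(do.call(rbind, lapply(tracks, function(t) t@wK27)) *
                cw) / sum(cw)
  new("DeconvResult", tracks = tracks, wPol = wP, wK27 = wK, config = cfg,
      prior = prior)
}

#' Per-cut deconvolved densities
#'
#' Concatenated core cut positions of all chunks with the exponentiated
#' MAP densities of both targets and the cut weights; the machine-readable
#' sidecar consumed by peak calling and per-cut classification.
#'
#' @param result a \code{\linkS4class{DeconvResult}}.
#' @return data.frame (chrom, pos, weight, pol, k27).
#' @export
deconvCutTable <- function(result) {
  rows <- lapply(result@tracks, function(t)
    data.frame(chrom = rep(t@chrom, length(t@cutPos)), pos = t@cutPos,
               weight = t@cutWeight, pol = exp(t@cutLogPol),
               k27 = exp(t@cutLogK27)))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = numeric(0),
                      weight = numeric(0), pol = numeric(0),
                      k27 = numeric(0))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Gridded deconvolved densities
#'
#' @param result a \code{\linkS4class{DeconvResult}}.
#' @return data.frame (chrom, pos, pol, k27) on the output grid.
#' @export
deconvGridTable <- function(result) {
  rows <- lapply(result@tracks, function(t)
    data.frame(chrom = rep(t@chrom, length(t@gridPos)), pos = t@gridPos,
               pol = exp(t@gridLogPol), k27 = exp(t@gridLogK27)))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = numeric(0),
                      pol = numeric(0), k27 = numeric(0))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Per-cut posterior target assignment
#'
#' Ratio of the Pol2S5p mixture term to the total mixture density for each
#' cut event, combining the deconvolved position densities with the
#' fragment-length factors at the pooled weight estimates.
#'
#' @param result a \code{\linkS4class{DeconvResult}}.
#' @param cuts the \code{\linkS4class{CutSites}} that were deconvolved.
#' @return data.frame (chrom, pos, fraglen, weight, pPol) restricted to
#'   cuts inside deconvolved cores.
#' @export
assignCuts <- function(result, cuts) {
  tab <- deconvCutTable(result)
  key <- paste(cuts@chrom, cuts@pos)
  m <- match(key, paste(tab$chrom, tab$pos))
  keep <- !is.na(m)
  phi <- lengthComponentDensities(cuts@fraglen[keep], result@prior)
  hP <- drop(phi %*% result@wPol)
  hK <- drop(phi %*% result@wK27)
  tP <- tab$pol[m[keep]] * hP
  tK <- tab$k27[m[keep]] * hK
  data.frame(chrom = cuts@chrom[keep], pos = cuts@pos[keep],
             fraglen = cuts@fraglen[keep], weight = cuts@weight[keep],
             pPol = tP / (tP + tK))
}
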