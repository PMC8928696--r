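#' Mean fragment size per peak
#'
#' A fragment overlaps a peak when their half-open intervals intersect by
#' at least one bp. The per-peak mean fragment length is weighted by the
#' fragments' duplicate counts. Peaks with no overlapping fragment are
#' dropped with a message.
#'
#' @param frags fragment \code{GRanges} with a \code{count} column.
#' @param peaks peak \code{GRanges}, sorted and non-overlapping.
#' @return data.frame with columns \code{peak} (index into \code{peaks}),
#'   \code{chrom}, \code{start}, \code{end}, \code{nFragments},
#'   \code{meanFraglen}.
#' @export
meanFragmentSizePerPeak <- function(frags, peaks) {
  if (length(peaks) > 1L) {
    if (is.unsorted(GenomicRanges::order(peaks)))
      stop("peaks must be sorted")
    red <- reduce(granges(peaks))
    if (length(red) < length(peaks))
      stop("peaks must be non-overlapping")
  }
  ov <- findOverlaps(frags, peaks)
  count <- mcols(frags)$count
  if (is.null(count)) count <- rep(1L, length(frags))
  dt <- data.table::data.table(peak = subjectHits(ov),
                               len = width(frags)[queryHits(ov)],
                               w = as.numeric(count[queryHits(ov)]))
  agg <- dt[, list(nFragments = sum(w),
                   meanFraglen = sum(len * w) / sum(w)), by = "peak"]
  data.table::setorderv(agg, "peak")
  dropped <- length(peaks) - nrow(agg)
  if (dropped > 0)
    message(dropped, " peaks without overlapping fragments were dropped")
  data.frame(peak = agg$peak,
             chrom = as.character(GenomeInfoDb::seqnames(peaks))[agg$peak],
             start = start(peaks)[agg$peak] - 1L,
             end = end(peaks)[agg$peak],
             nFragments = agg$nFragments, meanFraglen = agg$meanFraglen)
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Deterministic expectation-maximization on a vector of per-peak average
#' fragment sizes: components start at the 25th and 75th percentiles with
#' the pooled sd and equal weights, iterate until the absolute
#' log-likelihood change falls below \code{tol} or \code{maxIter}
#' iterations, with a 1-bp floor on the component sds. Components are
#' ordered by mean. The log-likelihood trace is non-decreasing.
#'
#' @param sizes numeric observations (>= 4, not all identical).
#' @param tol absolute log-likelihood convergence tolerance.
#' @param maxIter iteration cap.
#' @param sdFloor lower bound for component sds in bp.
#' @return a \code{\linkS4class{TwoGaussianFit}} (threshold slot filled by
#'   \code{\link{intersectionThreshold}}).
#' @export
fitTwoGaussianEM <- function(sizes, tol = 1e-8, maxIter = 1000L,
                             sdFloor = 1) {
  x <- as.numeric(sizes)
  if (length(x) < 4L) stop("need at least 4 observations")
  if (diff(range(x)) == 0) stop("degenerate data: all observations identical")
  mu <- as.numeric(quantile(x, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-0.5, 0.5) * max(sd(x), 1)
  sg <- rep(max(sd(x), sdFloor), 2L)
  w <- c(0.5, 0.5)
  trace <- numeric(0)
  degenerate <- FALSE
  for (it in seq_len(maxIter)) {
    d1 <- w[1] * dnorm(x, mu[1], sg[1])
    d2 <- w[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (it > 1L && abs(ll - trace[it - 1L]) < tol) break
    r1 <- d1 / tot
    n1 <- sum(r1); n2 <- length(x) - n1
    w <- c(n1, n2) / length(x)
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    sg <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1,
                 sum((1 - r1) * (x - mu[2])^2) / n2))
    if (any(sg < sdFloor)) {
      sg <- pmax(sg, sdFloor)
      degenerate <- TRUE
    }
  }
  ord <- order(mu)
  fit <- new("TwoGaussianFit", weights = w[ord], means = mu[ord],
             sds = sg[ord], loglikTrace = trace, threshold = NA_real_,
             degenerate = degenerate, thresholdFallback = FALSE)
  fit@threshold <- intersectionThreshold(fit)@threshold
  fit
}

#' Intersection threshold of two weighted Gaussians
#'
#' The point between the two component means where the weighted densities
#' are equal, found as a root of the (quadratic) log-density difference.
#' When both roots fall between the means the one where the low-mean
#' component's responsibility crosses 0.5 downwards is used; when no root
#' lies between the means the midpoint is used and flagged.
#'
#' @param fit a \code{\linkS4class{TwoGaussianFit}}.
#' @return the fit with \code{threshold} (and possibly
#'   \code{thresholdFallback}) updated.
#' @export
intersectionThreshold <- function(fit) {
  mu <- fit@means; sg <- fit@sds; w <- fit@weights
  if (mu[1] == mu[2]) stop("component means must be distinct")
  # (x-mu2)^2/(2 s2^2) - (x-mu1)^2/(2 s1^2) + log(w1 s2 / (w2 s1)) = 0
  a <- 1 / (2 * sg[2]^2) - 1 / (2 * sg[1]^2)
  b <- mu[1] / sg[1]^2 - mu[2] / sg[2]^2
  cc <- mu[2]^2 / (2 * sg[2]^2) - mu[1]^2 / (2 * sg[1]^2) +
    log(w[1] * sg[2] / (w[2] * sg[1]))
  roots <- if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else
      (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > mu[1] & roots < mu[2]]
  fallback <- FALSE
  if (length(inside) == 0L) {
    thr <- mean(mu)
    fallback <- TRUE
  } else if (length(inside) == 1L) {
    thr <- inside
  } else {
    resp <- function(x) {
      d1 <- w[1] * dnorm(x, mu[1], sg[1])
      d1 / (d1 + w[2] * dnorm(x, mu[2], sg[2]))
    }
    eps <- diff(mu) * 1e-6
    crossing <- vapply(inside, function(r)
      resp(r - eps) > 0.5 && resp(r + eps) < 0.5, logical(1))
    thr <- if (any(crossing)) inside[which(crossing)[1]] else inside[1]
  }
  fit@threshold <- thr
  fit@thresholdFallback <- fallback
  fit
}

#' Partition peak size profiles at a threshold
#'
#' Peaks with mean fragment length below the threshold go to the small
#' (Pol2S5p-like) class, all others to the large (H3K27me3-like) class;
#' a tie at the threshold resolves to the large class. The split is
#' exhaustive and disjoint.
#'
#' @param profiles data.frame from \code{\link{meanFragmentSizePerPeak}}.
#' @param threshold bp threshold.
#' @return list with \code{small} and \code{large} data.frames.
#' @export
partitionPeaks <- function(profiles, threshold) {
  small <- profiles$meanFraglen < threshold
  list(small = profiles[small, , drop = FALSE],
       large = profiles[!small, , drop = FALSE])
}

#' Bulk fragment-size peak classification
#'
#' End-to-end wrapper: per-peak mean fragment sizes, two-Gaussian EM fit,
#' intersection threshold, partition into small and large classes.
#'
#' @param frags fragment \code{GRanges}.
#' @param peaks peak \code{GRanges}, sorted and non-overlapping.
#' @return list with \code{profiles}, \code{fit}, \code{small},
#'   \code{large}.
#' @export
classifyPeaksBySize <- function(frags, peaks) {
  profiles <- meanFragmentSizePerPeak(frags, peaks)
  fit <- fitTwoGaussianEM(profiles$meanFraglen)
  part <- partitionPeaks(profiles, fit@threshold)
  list(profiles = profiles, fit = fit, small = part$small,
       large = part$large)
}
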