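#' Robust estimate of a target's cut fraction and peak-weight fraction
#'
#' The raw fraction is the ratio of the target's deconvolved-density
#' integral to the combined integral (core spans only, so no padding is
#' double-counted). A Beta(0.5, 0.5) prior stabilizes it via pseudo-counts
#' on the integrals, \eqn{\hat r = (I_t + 0.5) / (I_{pol} + I_{k27} + 1)}.
#' Under the conservative assumption that half of a target's cuts fall
#' into its reproducible peaks, the expected fraction of all cuts inside
#' that target's peaks is \eqn{r = (1 + 2\hat r)/8}, bounded in
#' [1/8, 3/8].
#'
#' @param result a \code{\linkS4class{DeconvResult}}.
#' @param target \code{"pol"} or \code{"k27"}.
#' @return list with \code{rHat}, \code{rFrac} and the raw integrals.
#' @export
estimateTargetFraction <- function(result, target = c("pol", "k27")) {
  target <- match.arg(target)
  iP <- sum(vapply(result@tracks, function(t) t@integralCorePol, 1))
  iK <- sum(vapply(result@tracks, function(t) t@integralCoreK27, 1))
  if (iP + iK <= 0) stop("zero combined integral")
  iT <- if (target == "pol") iP else iK
  rHat <- (iT + 0.5) / (iP + iK + 1)
  list(target = target, rHat = rHat, rFrac = (1 + 2 * rHat) / 8,
       integralPol = iP, integralK27 = iK)
}

#' Weighted quantile (left-continuous)
#'
#' Smallest value whose cumulative weight reaches \code{prob} of the total.
#'
#' @param values numeric values.
#' @param weights positive weights.
#' @param prob probability in [0, 1].
#' @return the weighted quantile.
#' @export
weightedQuantile <- function(values, weights, prob) {
  o <- order(values)
  cw <- cumsum(weights[o])
  values[o][which(cw >= prob * cw[length(cw)])[1]]
}

# contiguous grid blocks (index ranges) of one chromosome's grid
.gridBlocks <- function(pos, pitch) {
  if (!length(pos)) return(NULL)
  brk <- c(0L, which(diff(pos) > pitch + 1e-9), length(pos))
  lapply(seq_len(length(brk) - 1L), function(i)
    (brk[i] + 1L):brk[i + 1L])
}

# supra-threshold runs on one contiguous grid block that contain a cut
.callRuns <- function(gridPos, values, threshold, cutPos, pitch) {
  keep <- values >= threshold
  if (!any(keep)) return(NULL)
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- NULL
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    s0 <- gridPos[i0]; e0 <- gridPos[i1] + pitch
    if (!any(cutPos >= s0 & cutPos < e0)) next
    j <- i0 + which.max(values[i0:i1]) - 1L
    out <- rbind(out, c(s0, e0, gridPos[j], max(values[i0:i1])))
  }
  out
}

.callTarget <- function(grid, cutTab, valueCol, rFrac, pitch,
                        minWidth = NULL) {
  threshold <- weightedQuantile(cutTab[[valueCol]], cutTab$weight, 1 - rFrac)
  rows <- NULL
  for (ch in unique(grid$chrom)) {
    g <- grid[grid$chrom == ch, , drop = FALSE]
    cp <- cutTab$pos[cutTab$chrom == ch]
    for (ix in .gridBlocks(g$pos, pitch)) {
      runs <- .callRuns(g$pos[ix], g[[valueCol]][ix], threshold, cp, pitch)
      if (!is.null(runs))
        rows <- rbind(rows, data.frame(chrom = ch, start = runs[, 1],
                                       end = runs[, 2], summit = runs[, 3],
                                       score = runs[, 4]))
    }
  }
  if (is.null(rows))
    rows <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), summit = numeric(0),
                       score = numeric(0))
  if (!is.null(minWidth))
    rows <- rows[rows$end - rows$start > minWidth, , drop = FALSE]
  attr(rows, "threshold") <- threshold
  rows
}

#' Call narrow Pol2S5p peaks from deconvolved signal
#'
#' Threshold at the weighted \eqn{(1 - r_{Pol})} quantile of the
#' deconvolved Pol2S5p density evaluated at the cut positions (weights are
#' cut weights over all cuts, either target), so that about an
#' \eqn{r_{Pol}} fraction of cut weight lies above it. Maximal
#' supra-threshold runs of the output grid containing at least one cut are
#' candidate peaks; peaks strictly wider than \code{minWidth} bp are
#' retained, with the grid argmax (leftmost on ties) as summit.
#'
#' @param result a \code{\linkS4class{DeconvResult}}.
#' @param est estimate from \code{\link{estimateTargetFraction}}; computed
#'   when \code{NULL}.
#' @param minWidth retain peaks strictly wider than this (bp).
#' @return \code{GRanges} with \code{target}, \code{summit} (0-based grid
#'   position), \code{score}; threshold and fractions in
#'   \code{metadata()}.
#' @export
callPolPeaks <- function(result, est = NULL, minWidth = 100) {
  if (is.null(est)) est <- estimateTargetFraction(result, "pol")
  grid <- deconvGridTable(result)
  cutTab <- deconvCutTable(result)
  rows <- .callTarget(grid, cutTab, "pol", est$rFrac,
                      result@config@gridPitch, minWidth)
  gr <- GRanges(rows$chrom, IRanges(rows$start + 1, rows$end))
  mcols(gr)$target <- rep("Pol2S5p", nrow(rows))
  mcols(gr)$summit <- rows$summit
  mcols(gr)$score <- rows$score
  metadata(gr) <- list(rHat = est$rHat, rFrac = est$rFrac,
                       threshold = attr(rows, "threshold"))
  gr
}

# truncated-renormalized Gaussian smoothing of one contiguous block
.gaussSmooth <- function(v, sdSamples) {
  h <- max(1L, ceiling(4 * sdSamples))
  k <- dnorm(seq(-h, h), 0, sdSamples)
  pad <- rep(0, h)
  num <- stats::filter(c(pad, v, pad), k, sides = 2)
  den <- stats::filter(c(pad, rep(1, length(v)), pad), k, sides = 2)
  as.numeric(num[h + seq_along(v)] / den[h + seq_along(v)])
}

#' Call broad H3K27me3 domains from deconvolved signal
#'
#' Broad domains can surface as discontinuous blocks of deconvolved
#' signal, so domains are called twice: once on the raw deconvolved
#' H3K27me3 density, and once on the average of the raw density and a
#' Gaussian-smoothed copy (\code{smoothSd}, default 2000 bp, the H3K27me3
#' GP length scale), which bridges shallow dips. Each pass uses the same
#' quantile-threshold procedure as Pol2S5p peak calling with the
#' H3K27me3 fraction estimate; the final domains are the interval union of
#' both passes (overlapping intervals merged), retaining domains strictly
#' wider than \code{minWidth} bp. Domains carry no summit.
#'
#' @param result a \code{\linkS4class{DeconvResult}}.
#' @param est estimate from \code{\link{estimateTargetFraction}}.
#' @param minWidth retain domains strictly wider than this (bp).
#' @param smoothSd Gaussian filter sd in bp.
#' @return \code{GRanges} with \code{target}, \code{summit = NA},
#'   \code{score}.
#' @export
callK27Domains <- function(result, est = NULL, minWidth = 400,
                           smoothSd = 2000) {
  if (is.null(est)) est <- estimateTargetFraction(result, "k27")
  pitch <- result@config@gridPitch
  grid <- deconvGridTable(result)
  cutTab <- deconvCutTable(result)
  raw <- .callTarget(grid, cutTab, "k27", est$rFrac, pitch, NULL)

  # averaged (raw + smoothed) signal on the grid and at the cut positions
  grid$k27avg <- grid$k27
  cutTab$k27avg <- cutTab$k27
  for (ch in unique(grid$chrom)) {
    gi <- which(grid$chrom == ch)
    for (ix in .gridBlocks(grid$pos[gi], pitch)) {
      sel <- gi[ix]
      sm <- .gaussSmooth(grid$k27[sel], smoothSd / pitch)
      grid$k27avg[sel] <- (grid$k27[sel] + sm) / 2
      ci <- which(cutTab$chrom == ch &
                  cutTab$pos >= grid$pos[sel][1] &
                  cutTab$pos < grid$pos[sel][length(sel)] + pitch)
      if (length(ci))
        cutTab$k27avg[ci] <- approx(grid$pos[sel], grid$k27avg[sel],
                                    xout = cutTab$pos[ci],
                                    rule = 2)$y
    }
  }
  smc <- .callTarget(grid, cutTab, "k27avg", est$rFrac, pitch, NULL)

  both <- rbind(raw[, c("chrom", "start", "end")],
                smc[, c("chrom", "start", "end")])
  if (!nrow(both)) {
    gr <- GRanges()
    mcols(gr)$target <- character(0)
    mcols(gr)$summit <- numeric(0)
    mcols(gr)$score <- numeric(0)
    return(gr)
  }
  merged <- reduce(GRanges(both$chrom, IRanges(both$start + 1, both$end)))
  merged <- merged[width(merged) > minWidth]
  score <- vapply(seq_along(merged), function(i) {
    sel <- grid$chrom == as.character(GenomeInfoDb::seqnames(merged))[i] &
      grid$pos >= start(merged)[i] - 1 & grid$pos < end(merged)[i]
    if (any(sel)) max(grid$k27[sel]) else NA_real_
  }, 1)
  mcols(merged)$target <- rep("H3K27me3", length(merged))
  mcols(merged)$summit <- rep(NA_real_, length(merged))
  mcols(merged)$score <- score
  metadata(merged) <- list(rHat = est$rHat, rFrac = est$rFrac,
                           thresholdRaw = attr(raw, "threshold"),
                           thresholdSmoothed = attr(smc, "threshold"))
  merged
}

#' Resolve overlapping peak calls between the two targets
#'
#' A peak whose overlap with the other target's calls spans less than 50\%
#' of its own width keeps its label; all other peaks are relabelled
#' \code{"overlap"}. Peak count is conserved and the labels partition into
#' at most three classes.
#'
#' @param pol Pol2S5p peak \code{GRanges}.
#' @param k27 H3K27me3 domain \code{GRanges}.
#' @return combined, sorted \code{GRanges} with updated \code{target}.
#' @export
resolveOverlaps <- function(pol, k27) {
  overlapBp <- function(x, other) {
    if (!length(x) || !length(other)) return(numeric(length(x)))
    red <- reduce(granges(other))
    hits <- findOverlaps(x, red)
    bp <- width(pintersect(x[queryHits(hits)], red[subjectHits(hits)]))
    out <- numeric(length(x))
    agg <- tapply(bp, queryHits(hits), sum)
    out[as.integer(names(agg))] <- agg
    out
  }
  if (length(pol)) {
    ovP <- overlapBp(pol, k27)
    mcols(pol)$target <- ifelse(ovP < 0.5 * width(pol), "Pol2S5p",
                                "overlap")
  }
  if (length(k27)) {
    ovK <- overlapBp(k27, pol)
    mcols(k27)$target <- ifelse(ovK < 0.5 * width(k27), "H3K27me3",
                                "overlap")
  }
  out <- c(pol, k27)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Call and classify peaks from a deconvolution result
#'
#' Runs Pol2S5p peak calling and H3K27me3 domain calling, then resolves
#' cross-target overlaps. The returned \code{GRanges} carries the
#' estimates and thresholds in \code{metadata()}.
#'
#' @param result a \code{\linkS4class{DeconvResult}}.
#' @param minPolWidth,minK27Width strict width filters in bp.
#' @param smoothSd H3K27me3 smoothing bandwidth in bp.
#' @return classified peak \code{GRanges}.
#' @export
callPeaks <- function(result, minPolWidth = 100, minK27Width = 400,
                      smoothSd = 2000) {
  estP <- estimateTargetFraction(result, "pol")
  estK <- estimateTargetFraction(result, "k27")
  pol <- callPolPeaks(result, estP, minPolWidth)
  k27 <- callK27Domains(result, estK, minK27Width, smoothSd)
  peaks <- resolveOverlaps(pol, k27)
  metadata(peaks) <- list(
    rHatPol = estP$rHat, rFracPol = estP$rFrac,
    rHatK27 = estK$rHat, rFracK27 = estK$rFrac,
    thresholdPol = metadata(pol)$threshold,
    thresholdK27 = metadata(k27)$thresholdRaw,
    classCounts = table(factor(mcols(peaks)$target,
                               c("Pol2S5p", "H3K27me3", "overlap"))))
  peaks
}
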