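#' @import methods
#' @importFrom stats dnorm dlnorm rnorm runif approx convolve optim
#'   kmeans quantile sd cor setNames rmultinom
#' @importFrom utils head tail
#' @importClassesFrom GenomeInfoDb Seqinfo
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqlevels
#' @importFrom GenomicRanges GRanges start end width strand granges
#' @importFrom IRanges IRanges findOverlaps reduce pintersect
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#'   queryHits subjectHits
#' @importFrom data.table data.table fread fwrite setorderv rbindlist
#' @useDynLib tagsep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Fragment-length mixture prior
#'
#' Per-target probability model for CUT&Tag fragment lengths: a mixture of
#' four log-normal components whose modes sit at the characteristic
#' nucleosomal length scales (default 70, 200, 400 and 600 bp), with a
#' Dirichlet prior on the mode weights for each target. Components are
#' parameterized so that the stated numbers are the modes of the densities
#' (\code{meanlog = log(mode) + logSd^2}). Fragments longer than
#' \code{maxLen} (default 800 bp) are not distinguished from \code{maxLen}.
#'
#' @slot modes numeric(4), strictly increasing mode locations in bp.
#' @slot logSd log-scale standard deviation shared by the components.
#' @slot alphaPol Dirichlet parameters for the Pol2S5p weight vector.
#' @slot alphaK27 Dirichlet parameters for the H3K27me3 weight vector.
#' @slot maxLen clamp length in bp.
#' @export
setClass("LengthPrior",
  representation(modes = "numeric", logSd = "numeric", alphaPol = "numeric",
                 alphaK27 = "numeric", maxLen = "numeric"))

setValidity("LengthPrior", function(object) {
  if (length(object@modes) != 4L || any(diff(object@modes) <= 0))
    return("modes must be four strictly increasing values")
  if (object@logSd <= 0) return("logSd must be positive")
  if (length(object@alphaPol) != 4L || any(object@alphaPol <= 0))
    return("alphaPol must be four positive values")
  if (length(object@alphaK27) != 4L || any(object@alphaK27 <= 0))
    return("alphaK27 must be four positive values")
  if (object@maxLen < object@modes[4L]) return("maxLen below largest mode")
  TRUE
})

#' Gaussian-process deconvolution configuration
#'
#' Settings of the cut-site density model and of the chunked MAP inference.
#' The two targets get zero-mean Gaussian processes with unit-variance
#' Matern-3/2 covariance at target-specific length scales (500 bp for the
#' narrow Pol2S5p features, 2000 bp for broad H3K27me3 domains). The summed
#' exponentiated densities are softly constrained, through a log-normal
#' penalty with log-scale sd \code{integralSd}, to integrate (rectangle rule
#' over cut sites) to the total observed cut weight.
#'
#' @slot lengthscalePol,lengthscaleK27 kernel length scales in bp.
#' @slot jitter diagonal stabilizer added to dense kernel matrices.
#' @slot integralSd log-scale sd of the integral constraint.
#' @slot gridPitch output grid pitch in bp.
#' @slot maxSitesPerChunk maximum unique cut positions per inference chunk.
#' @slot padding bp of context kept on each side of a chunk.
#' @slot kdeBandwidth Gaussian KDE bandwidth (bp) for region selection.
#' @slot minDensity minimum KDE density (cuts/bp) for a region.
#' @slot mergeGap regions closer than this (bp) are merged.
#' @slot maxIterations optimizer iteration cap.
#' @slot factr,pgtol L-BFGS-B convergence controls (see \code{\link{optim}}).
#' @export
setClass("GPConfig",
  representation(lengthscalePol = "numeric", lengthscaleK27 = "numeric",
                 jitter = "numeric", integralSd = "numeric",
                 gridPitch = "numeric", maxSitesPerChunk = "numeric",
                 padding = "numeric", kdeBandwidth = "numeric",
                 minDensity = "numeric", mergeGap = "numeric",
                 maxIterations = "numeric", factr = "numeric",
                 pgtol = "numeric"))

setValidity("GPConfig", function(object) {
  if (object@lengthscalePol <= 0 || object@lengthscaleK27 <= 0)
    return("length scales must be positive")
  if (object@jitter <= 0) return("jitter must be positive")
  if (object@integralSd <= 0) return("integralSd must be positive")
  if (object@gridPitch < 1) return("gridPitch must be >= 1")
  if (object@maxSitesPerChunk < 1) return("maxSitesPerChunk must be >= 1")
  TRUE
})

#' Weighted cut sites
#'
#' One adapter-integration event per row: a genomic position (0-based,
#' BED-style insertion coordinate), the length of the parent fragment, and a
#' multiplicity weight. Each fragment contributes two cut sites, one at each
#' endpoint. Rows are sorted by (chrom, pos, fraglen) and identical
#' (chrom, pos, fraglen) triples are collapsed with summed weight.
#'
#' @slot chrom character chromosome per cut.
#' @slot pos numeric 0-based position per cut.
#' @slot fraglen parent fragment length in bp.
#' @slot weight positive multiplicity.
#' @export
setClass("CutSites",
  representation(chrom = "character", pos = "numeric", fraglen = "numeric",
                 weight = "numeric"))

setValidity("CutSites", function(object) {
  n <- length(object@pos)
  if (length(object@chrom) != n || length(object@fraglen) != n ||
      length(object@weight) != n)
    return("slot lengths differ")
  if (n && any(object@fraglen < 1)) return("fraglen must be >= 1")
  if (n && any(object@weight <= 0)) return("weights must be positive")
  TRUE
})

#' @describeIn CutSites number of cut-site records
#' @param x a \code{CutSites} object
#' @export
setMethod("length", "CutSites", function(x) length(x@pos))

setMethod("show", "CutSites", function(object) {
  cat("CutSites with", length(object), "records,",
      "total weight", sum(object@weight), "\n")
  if (length(object)) {
    tab <- table(object@chrom)
    cat("  chromosomes:", paste(names(tab), collapse = ", "), "\n")
  }
})

#' Deconvolved signal for one inference chunk
#'
#' MAP log cut-site densities of the two targets over one padded inference
#' chunk, reported at the unique cut positions of the chunk core and on a
#' regular output grid (padding discarded). Densities are in cuts per bp;
#' \code{integralFull} values cover the padded chunk and should match the
#' padded total cut weight to within the integral constraint.
#'
#' @slot chrom chromosome.
#' @slot coreStart,coreEnd 0-based half-open span of the reported core.
#' @slot cutPos 0-based unique cut positions inside the core.
#' @slot cutLogPol,cutLogK27 log densities at \code{cutPos}.
#' @slot cutWeight total cut weight at each core position.
#' @slot gridPos 0-based grid bin starts.
#' @slot gridLogPol,gridLogK27 log densities at grid positions.
#' @slot wPol,wK27 inferred length-mode weights.
#' @slot integralFullPol,integralFullK27 rectangle-rule integrals, padded span.
#' @slot integralCorePol,integralCoreK27 integrals restricted to the core.
#' @slot totalWeightFull total cut weight of the padded chunk.
#' @slot converged optimizer convergence flag.
#' @slot iterations optimizer iteration count.
#' @slot objective final negative log posterior (optimizer scale).
#' @export
setClass("DeconvTrack",
  representation(chrom = "character", coreStart = "numeric",
                 coreEnd = "numeric", cutPos = "numeric",
                 cutLogPol = "numeric", cutLogK27 = "numeric",
                 cutWeight = "numeric", gridPos = "numeric",
                 gridLogPol = "numeric", gridLogK27 = "numeric",
                 wPol = "numeric", wK27 = "numeric",
                 integralFullPol = "numeric", integralFullK27 = "numeric",
                 integralCorePol = "numeric", integralCoreK27 = "numeric",
                 totalWeightFull = "numeric", converged = "logical",
                 iterations = "numeric", objective = "numeric"))

setMethod("show", "DeconvTrack", function(object) {
  cat(sprintf("DeconvTrack %s:%d-%d | %d cut sites, %d grid points\n",
              object@chrom, object@coreStart, object@coreEnd,
              length(object@cutPos), length(object@gridPos)))
  cat(sprintf("  wPol = (%s)  wK27 = (%s)  converged = %s\n",
              paste(round(object@wPol, 3), collapse = ", "),
              paste(round(object@wK27, 3), collapse = ", "),
              object@converged))
})

#' Whole-run deconvolution result
#'
#' Concatenation of per-chunk \code{\linkS4class{DeconvTrack}} objects plus
#' pooled length-mode weight estimates (chunk estimates averaged with the
#' chunks' core cut weights).
#'
#' @slot tracks list of \code{DeconvTrack}.
#' @slot wPol,wK27 pooled length-mode weights.
#' @slot config the \code{GPConfig} used.
#' @slot prior the \code{LengthPrior} used.
#' @export
setClass("DeconvResult",
  representation(tracks = "list", wPol = "numeric", wK27 = "numeric",
                 config = "GPConfig", prior = "LengthPrior"))

setMethod("show", "DeconvResult", function(object) {
  cat("DeconvResult with", length(object@tracks), "chunks;",
      sum(vapply(object@tracks, function(t) length(t@cutPos), 1L)),
      "core cut sites\n")
  cat(sprintf("  pooled wPol = (%s)\n  pooled wK27 = (%s)\n",
              paste(round(object@wPol, 3), collapse = ", "),
              paste(round(object@wK27, 3), collapse = ", ")))
  cat("  converged chunks:",
      sum(vapply(object@tracks, function(t) t@converged, TRUE)), "/",
      length(object@tracks), "\n")
})

#' Two-component Gaussian mixture fit of per-peak fragment sizes
#'
#' Result of the deterministic EM fit used by the bulk fragment-size
#' classifier, with the intersection threshold separating the small
#' (Pol2S5p-like) and large (H3K27me3-like) size classes.
#'
#' @slot weights mixing weights (sum to one), ordered by component mean.
#' @slot means,sds component parameters in bp.
#' @slot loglikTrace per-iteration log-likelihood (non-decreasing).
#' @slot threshold intersection point of the two weighted densities.
#' @slot degenerate TRUE when a variance floor was hit.
#' @slot thresholdFallback TRUE when no crossing lay between the means and
#'   the midpoint was used instead.
#' @export
setClass("TwoGaussianFit",
  representation(weights = "numeric", means = "numeric", sds = "numeric",
                 loglikTrace = "numeric", threshold = "numeric",
                 degenerate = "logical", thresholdFallback = "logical"))

setValidity("TwoGaussianFit", function(object) {
  if (any(object@sds <= 0)) return("sds must be positive")
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  if (is.unsorted(object@means)) return("components must be ordered by mean")
  TRUE
})

setMethod("show", "TwoGaussianFit", function(object) {
  cat(sprintf(
    "TwoGaussianFit: %.1f%% N(%.1f, %.1f^2) + %.1f%% N(%.1f, %.1f^2)\n",
    100 * object@weights[1], object@means[1], object@sds[1],
    100 * object@weights[2], object@means[2], object@sds[2]))
  cat(sprintf("  threshold = %.2f bp after %d EM iterations%s\n",
              object@threshold, length(object@loglikTrace),
              if (object@degenerate) " (degenerate)" else ""))
})

#' Synthetic two-target fragment simulation settings
#'
#' Configuration of the generative mirror of the deconvolution model: two
#' latent targets lay Gaussian-shaped features on a small genome (narrow
#' Pol2S5p-like features, broad H3K27me3-like features), fragments pick a
#' target, then a position from that target's density and a length from the
#' target's four-mode log-normal mixture. A fraction of each target's mass
#' is uniform background. With \code{nCells > 0} fragments are distributed
#' over barcoded cells of two types; features can be shared or type
#' specific, and per-cell depth factors can impose a depth gradient.
#'
#' @slot genome \code{Seqinfo} describing the synthetic genome.
#' @slot nPolFeatures,nK27Features feature counts.
#' @slot polFeatureWidth,k27FeatureWidth Gaussian sd of the features in bp.
#' @slot polLengthWeights,k27LengthWeights true length-mode weights.
#' @slot lengthLogSd log-scale sd of the length components.
#' @slot nFragments total fragments to draw.
#' @slot nCells number of cells (0 = bulk, unbarcoded).
#' @slot polMassFraction fraction of fragments from the Pol2S5p target.
#' @slot backgroundFraction per-target fraction of uniform background mass.
#' @slot typeSpecificFraction fraction of each target's features private to
#'   one cell type (split evenly between the two types).
#' @slot depthRange per-cell relative depth factors interpolated linearly
#'   across cells, e.g. \code{c(1, 5)} for a five-fold gradient.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  representation(genome = "Seqinfo", nPolFeatures = "numeric",
                 nK27Features = "numeric", polFeatureWidth = "numeric",
                 k27FeatureWidth = "numeric", polLengthWeights = "numeric",
                 k27LengthWeights = "numeric", lengthLogSd = "numeric",
                 nFragments = "numeric", nCells = "numeric",
                 polMassFraction = "numeric", backgroundFraction = "numeric",
                 typeSpecificFraction = "numeric", depthRange = "numeric",
                 seed = "numeric"))

setValidity("SimConfig", function(object) {
  simplex <- function(w) length(w) == 4L && all(w >= 0) &&
    abs(sum(w) - 1) < 1e-8
  if (!simplex(object@polLengthWeights)) return("polLengthWeights off simplex")
  if (!simplex(object@k27LengthWeights)) return("k27LengthWeights off simplex")
  if (object@polFeatureWidth <= 0 || object@k27FeatureWidth <= 0)
    return("feature widths must be positive")
  if (object@polFeatureWidth >= object@k27FeatureWidth)
    return("Pol2S5p features must be narrower than H3K27me3 features")
  if (object@polMassFraction < 0 || object@polMassFraction > 1)
    return("polMassFraction must be in [0, 1]")
  if (object@backgroundFraction < 0 || object@backgroundFraction >= 1)
    return("backgroundFraction must be in [0, 1)")
  if (object@nCells > 0 && object@nCells %% 2 != 0)
    return("nCells must be even (two balanced cell types)")
  if (length(object@depthRange) != 2L || any(object@depthRange <= 0))
    return("depthRange must be two positive values")
  TRUE
})

#' LSI embedding of a cell-by-peak matrix
#'
#' Truncated SVD of the TF-IDF-normalized binary matrix. Among the first two
#' components, any whose cell coordinates correlate with log library size
#' beyond \code{corCutoff} in absolute value is excluded from the retained
#' coordinates.
#'
#' @slot coords cells x retained-components coordinate matrix.
#' @slot allCoords cells x all-components coordinates (U D).
#' @slot loadings peaks x components loading matrix (V).
#' @slot d singular values.
#' @slot excluded indices of excluded components.
#' @slot libSize per-cell library sizes used for the exclusion rule.
#' @export
setClass("LsiEmbedding",
  representation(coords = "matrix", allCoords = "matrix",
                 loadings = "matrix", d = "numeric", excluded = "integer",
                 libSize = "numeric"))

setMethod("show", "LsiEmbedding", function(object) {
  cat(sprintf("LsiEmbedding: %d cells x %d retained components (%d excluded)\n",
              nrow(object@coords), ncol(object@coords),
              length(object@excluded)))
})
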