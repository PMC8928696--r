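#' Construct a fragment-length mixture prior
#'
#' Defaults encode the two-target fragment-length model: four log-normal
#' modes at 70/200/400/600 bp shared by both targets, a Dirichlet prior of
#' (450, 100, 10, 1) on the Pol2S5p mode weights (mass concentrated on
#' sub-nucleosomal lengths) and (150, 300, 50, 10) on the H3K27me3 weights
#' (mono-nucleosomal and longer). Lengths above \code{maxLen} are clamped
#' before evaluation.
#'
#' @param modes mode locations in bp.
#' @param logSd log-scale sd of each component.
#' @param alphaPol,alphaK27 Dirichlet parameter vectors.
#' @param maxLen clamp length in bp.
#' @return a \code{\linkS4class{LengthPrior}}.
#' @examples
#' pr <- lengthPrior()
#' lengthPdf(70, c(1, 0, 0, 0), pr)
#' @export
lengthPrior <- function(modes = c(70, 200, 400, 600), logSd = 0.4,
                        alphaPol = c(450, 100, 10, 1),
                        alphaK27 = c(150, 300, 50, 10), maxLen = 800) {
  new("LengthPrior", modes = as.numeric(modes), logSd = as.numeric(logSd),
      alphaPol = as.numeric(alphaPol), alphaK27 = as.numeric(alphaK27),
      maxLen = as.numeric(maxLen))
}

#' Per-component log-normal densities for fragment lengths
#'
#' Evaluates the four component densities at the given lengths, after
#' clamping lengths above \code{maxLen}. Each component k is a log-normal
#' with \code{meanlog = log(modes[k]) + logSd^2}, so its mode is exactly
#' \code{modes[k]}.
#'
#' @param l fragment lengths in bp (>= 1).
#' @param prior a \code{\linkS4class{LengthPrior}}.
#' @return a \code{length(l) x 4} matrix of densities.
#' @export
lengthComponentDensities <- function(l, prior = lengthPrior()) {
  if (any(l < 1)) stop("fragment lengths must be >= 1")
  lc <- pmin(l, prior@maxLen)
  mu <- log(prior@modes) + prior@logSd^2
  vapply(seq_len(4L),
         function(k) dlnorm(lc, meanlog = mu[k], sdlog = prior@logSd),
         numeric(length(l)))
}

#' Fragment-length mixture density
#'
#' @param l lengths in bp.
#' @param weights 4-simplex of mode weights.
#' @param prior a \code{\linkS4class{LengthPrior}}.
#' @return densities at \code{l}.
#' @export
lengthPdf <- function(l, weights, prior = lengthPrior()) {
  if (length(weights) != 4L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be a 4-simplex")
  phi <- lengthComponentDensities(l, prior)
  drop(phi %*% weights)
}

#' Dirichlet log density
#'
#' Full log density (normalizing constant included, so values are
#' comparable across parameter vectors) of a weight vector interior to the
#' simplex.
#'
#' @param weights positive weights summing to one.
#' @param alpha Dirichlet parameters.
#' @return log density.
#' @export
dirichletLogDensity <- function(weights, alpha) {
  if (any(weights <= 0)) stop("weights must be strictly positive")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to one")
  logB <- sum(lgamma(alpha)) - lgamma(sum(alpha))
  sum((alpha - 1) * log(weights)) - logB
}

#' Prior mean weights of a Dirichlet vector
#' @param alpha Dirichlet parameters.
#' @return normalized parameter vector.
#' @export
dirichletMean <- function(alpha) alpha / sum(alpha)
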