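#' Construct a simulation configuration
#'
#' Defaults describe the benchmark condition used throughout the package:
#' a 200-kb synthetic chromosome carrying nine narrow Pol2S5p-like features
#' (Gaussian sd 400 bp) and six broad H3K27me3-like features (sd 2000 bp),
#' equal cut mass for the two targets, 5\% uniform background per target,
#' true length-mode weights at the Dirichlet prior means, and 25,000
#' fragments (50,000 cut sites).
#'
#' @param genome a \code{Seqinfo} (default one 200-kb chromosome "chrS").
#' @param nPolFeatures,nK27Features feature counts.
#' @param polFeatureWidth,k27FeatureWidth Gaussian sd per feature, bp.
#' @param polLengthWeights,k27LengthWeights true 4-simplex mode weights.
#' @param lengthLogSd log-scale sd of the length components.
#' @param nFragments fragments to draw.
#' @param nCells cells (0 = bulk); must be even, types alternate.
#' @param polMassFraction fraction of fragments from the Pol2S5p target.
#' @param backgroundFraction per-target uniform background fraction.
#' @param typeSpecificFraction fraction of features private to one type.
#' @param depthRange relative per-cell depth factors, linear across cells.
#' @param seed RNG seed.
#' @return a \code{\linkS4class{SimConfig}}.
#' @export
simConfig <- function(genome = Seqinfo("chrS", 200000L),
                      nPolFeatures = 9, nK27Features = 6,
                      polFeatureWidth = 400, k27FeatureWidth = 2000,
                      polLengthWeights = dirichletMean(c(450, 100, 10, 1)),
                      k27LengthWeights = dirichletMean(c(150, 300, 50, 10)),
                      lengthLogSd = 0.4, nFragments = 25000, nCells = 0,
                      polMassFraction = 0.5, backgroundFraction = 0.05,
                      typeSpecificFraction = 0, depthRange = c(1, 1),
                      seed = 1) {
  new("SimConfig", genome = genome, nPolFeatures = nPolFeatures,
      nK27Features = nK27Features, polFeatureWidth = polFeatureWidth,
      k27FeatureWidth = k27FeatureWidth,
      polLengthWeights = polLengthWeights,
      k27LengthWeights = k27LengthWeights, lengthLogSd = lengthLogSd,
      nFragments = nFragments, nCells = nCells,
      polMassFraction = polMassFraction,
      backgroundFraction = backgroundFraction,
      typeSpecificFraction = typeSpecificFraction, depthRange = depthRange,
      seed = seed)
}

placeFeatures <- function(genome, n, width, occupied, maxTries = 20000L) {
  chroms <- seqnames(genome)
  lens <- as.numeric(seqlengths(genome))
  centers <- numeric(0); chrom <- character(0)
  tries <- 0L
  while (length(centers) < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("features cannot be placed without exceeding chromosome bounds; ",
           "reduce feature count or width")
    ci <- if (length(chroms) == 1L) 1L else
      sample.int(length(chroms), 1L, prob = lens)
    L <- lens[ci]
    if (L <= 6 * width) next
    c0 <- runif(1, 3 * width, L - 3 * width)
    cand <- c(c0 - 3 * width, c0 + 3 * width)
    clash <- FALSE
    occ <- occupied[[chroms[ci]]]
    if (!is.null(occ) && nrow(occ))
      clash <- any(cand[1] < occ[, 2] & cand[2] > occ[, 1])
    if (length(centers)) {
      own <- which(chrom == chroms[ci])
      if (length(own))
        clash <- clash || any(cand[1] < centers[own] + 3 * width &
                              cand[2] > centers[own] - 3 * width)
    }
    if (clash) next
    centers <- c(centers, c0)
    chrom <- c(chrom, chroms[ci])
  }
  data.frame(chrom = chrom, center = centers,
             width = rep(width, length(centers)), stringsAsFactors = FALSE)
}

assignFeatureTypes <- function(n, typeSpecificFraction) {
  nSpec <- round(n * typeSpecificFraction)
  if (nSpec %% 2L == 1L) nSpec <- nSpec + ifelse(nSpec < n, 1L, -1L)
  c(rep("shared", n - nSpec), rep(c("typeA", "typeB"), nSpec / 2))
}

#' Simulate ground-truth feature geometry and densities
#'
#' Lays out non-overlapping Gaussian-shaped features for the two targets on
#' the configured genome and records, per feature, the ground-truth
#' interval \code{[center - width, center + width)} (the bump core at one
#' sd, holding about 68\% of the feature's fragment centers). Each
#' target's position density is the equal-weight mixture of its feature
#' bumps plus a uniform background carrying \code{backgroundFraction} of
#' the target's mass; densities are nonnegative by construction.
#'
#' @param cfg a \code{\linkS4class{SimConfig}}.
#' @return a list with \code{features} (data.frame: id, target, chrom,
#'   center, width, cellType, start, end with 0-based half-open truth
#'   intervals), \code{genome} and \code{cfg}.
#' @export
simulateTruth <- function(cfg) {
  validObject(cfg)
  set.seed(as.integer(cfg@seed))
  occupied <- list()
  pol <- placeFeatures(cfg@genome, cfg@nPolFeatures, cfg@polFeatureWidth,
                       occupied)
  for (ch in unique(pol$chrom)) {
    k <- pol$chrom == ch
    occupied[[ch]] <- cbind(pol$center[k] - 3 * pol$width[k],
                            pol$center[k] + 3 * pol$width[k])
  }
  k27 <- placeFeatures(cfg@genome, cfg@nK27Features, cfg@k27FeatureWidth,
                       occupied)
  feats <- rbind(
    if (nrow(pol)) cbind(pol, target = "Pol2S5p") else NULL,
    if (nrow(k27)) cbind(k27, target = "H3K27me3") else NULL)
  if (is.null(feats))
    feats <- data.frame(chrom = character(0), center = numeric(0),
                        width = numeric(0), target = character(0))
  feats$cellType <- c(
    if (nrow(pol)) assignFeatureTypes(nrow(pol), cfg@typeSpecificFraction),
    if (nrow(k27)) assignFeatureTypes(nrow(k27), cfg@typeSpecificFraction))
  feats$id <- c(if (nrow(pol)) sprintf("pol_%02d", seq_len(nrow(pol))),
                if (nrow(k27)) sprintf("k27_%02d", seq_len(nrow(k27))))
  feats$start <- round(feats$center - feats$width)
  feats$end <- round(feats$center + feats$width)
  rownames(feats) <- NULL
  list(features = feats[, c("id", "target", "chrom", "center", "width",
                            "cellType", "start", "end")],
       genome = cfg@genome, cfg = cfg)
}

#' Evaluate a true target density
#'
#' Fragment-center probability density (per bp, integrating to one over the
#' genome) for one target, optionally restricted to the features visible to
#' one cell type.
#'
#' @param truth result of \code{\link{simulateTruth}}.
#' @param target \code{"Pol2S5p"} or \code{"H3K27me3"}.
#' @param chrom chromosome of the query positions.
#' @param pos numeric positions (0-based bp).
#' @param cellType \code{"all"}, \code{"typeA"} or \code{"typeB"}.
#' @return density values at \code{pos}.
#' @export
trueDensity <- function(truth, target, chrom, pos, cellType = "all") {
  cfg <- truth$cfg
  f <- truth$features[truth$features$target == target, , drop = FALSE]
  if (cellType != "all")
    f <- f[f$cellType %in% c("shared", cellType), , drop = FALSE]
  bg <- cfg@backgroundFraction
  totalLen <- sum(as.numeric(seqlengths(cfg@genome)))
  d <- rep(bg / totalLen, length(pos))
  if (nrow(f)) {
    fc <- f[f$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(fc)))
      d <- d + (1 - bg) / nrow(f) *
        dnorm(pos, mean = fc$center[i], sd = fc$width[i])
  }
  d
}

#' Draw synthetic fragments with ground-truth labels
#'
#' For each fragment: pick a cell (probability proportional to the cell's
#' depth factor) when cells are simulated, pick the target with probability
#' \code{polMassFraction}, draw a center position from the target's density
#' (restricted to the cell type's features), draw a length from the
#' target's log-normal mode mixture, and emit the half-open interval
#' \code{[center - len/2, center + len/2)} clipped to the chromosome.
#'
#' @param cfg a \code{\linkS4class{SimConfig}}.
#' @param truth result of \code{\link{simulateTruth}} for the same config.
#' @return a list with \code{fragments} (sorted \code{GRanges} with
#'   \code{id}, \code{barcode}, \code{count}) and \code{table} (the truth
#'   table: id, target, feature, cell, cellType, fraglen).
#' @export
sampleFragments <- function(cfg, truth) {
  if (cfg@nFragments <= 0) stop("nFragments must be positive")
  set.seed(as.integer(cfg@seed) + 1L)
  n <- as.integer(cfg@nFragments)
  nc <- as.integer(cfg@nCells)
  feats <- truth$features
  lens <- as.numeric(seqlengths(cfg@genome))
  chroms <- seqnames(cfg@genome)

  if (nc > 0L) {
    cellIds <- sprintf("cell%04d", seq_len(nc))
    cellTypes <- rep(c("typeA", "typeB"), length.out = nc)
    depth <- seq(cfg@depthRange[1], cfg@depthRange[2], length.out = nc)
    cellIdx <- sample.int(nc, n, replace = TRUE, prob = depth)
  } else {
    cellIds <- NA_character_
    cellTypes <- "all"
    cellIdx <- rep(1L, n)
  }
  fragType <- if (nc > 0L) cellTypes[cellIdx] else rep("all", n)
  isPol <- runif(n) < cfg@polMassFraction
  target <- ifelse(isPol, "Pol2S5p", "H3K27me3")
  isBg <- runif(n) < cfg@backgroundFraction

  chrom <- character(n); center <- numeric(n)
  featId <- rep(NA_character_, n)
  bgIdx <- which(isBg)
  if (length(bgIdx)) {
    ci <- if (length(lens) == 1L) rep(1L, length(bgIdx)) else
      sample.int(length(lens), length(bgIdx), replace = TRUE, prob = lens)
    chrom[bgIdx] <- chroms[ci]
    center[bgIdx] <- runif(length(bgIdx), 0, lens[ci])
  }
  for (tg in c("Pol2S5p", "H3K27me3")) {
    for (ty in unique(fragType)) {
      sel <- which(!isBg & target == tg & fragType == ty)
      if (!length(sel)) next
      fs <- feats[feats$target == tg &
                  (ty == "all" | feats$cellType %in% c("shared", ty)), ,
                  drop = FALSE]
      if (!nrow(fs)) {            # target without features: background only
        ci <- if (length(lens) == 1L) rep(1L, length(sel)) else
          sample.int(length(lens), length(sel), replace = TRUE, prob = lens)
        chrom[sel] <- chroms[ci]
        center[sel] <- runif(length(sel), 0, lens[ci])
        next
      }
      fi <- sample.int(nrow(fs), length(sel), replace = TRUE)
      chrom[sel] <- fs$chrom[fi]
      center[sel] <- rnorm(length(sel), fs$center[fi], fs$width[fi])
      featId[sel] <- fs$id[fi]
    }
  }

  mu <- log(c(70, 200, 400, 600)) + cfg@lengthLogSd^2
  comp <- integer(n)
  comp[isPol] <- sample.int(4L, sum(isPol), replace = TRUE,
                            prob = cfg@polLengthWeights)
  comp[!isPol] <- sample.int(4L, sum(!isPol), replace = TRUE,
                             prob = cfg@k27LengthWeights)
  len <- pmax(1, round(exp(rnorm(n, mu[comp], cfg@lengthLogSd))))

  L <- setNames(lens, chroms)[chrom]
  start0 <- pmax(0, round(center - len / 2))
  end0 <- pmin(L, start0 + len)
  start0 <- pmin(start0, end0 - 1)

  id <- sprintf("frag%07d", seq_len(n))
  barcode <- if (nc > 0L) cellIds[cellIdx] else NA_character_
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), seqinfo = cfg@genome)
  mcols(gr)$id <- id
  mcols(gr)$barcode <- barcode
  mcols(gr)$count <- 1L
  ord <- GenomicRanges::order(gr)
  tab <- data.frame(id = id, target = target, feature = featId,
                    cell = if (nc > 0L) cellIds[cellIdx] else NA_character_,
                    cellType = if (nc > 0L) fragType else NA_character_,
                    fraglen = end0 - start0, stringsAsFactors = FALSE)
  list(fragments = gr[ord], table = tab[ord, , drop = FALSE])
}

#' Simulate a complete labelled dataset
#'
#' Convenience wrapper running \code{\link{simulateTruth}} and
#' \code{\link{sampleFragments}}.
#'
#' @param cfg a \code{\linkS4class{SimConfig}}.
#' @return list with \code{truth}, \code{fragments}, \code{table}.
#' @export
simulateTagMix <- function(cfg) {
  truth <- simulateTruth(cfg)
  fr <- sampleFragments(cfg, truth)
  list(truth = truth, fragments = fr$fragments, table = fr$table)
}

#' Write a fragment truth table
#' @param table truth table from \code{\link{sampleFragments}}.
#' @param path output path (TSV).
#' @export
writeTruthTable <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t", quote = FALSE, na = ".")
  invisible(path)
}

#' Benchmark study conditions
#'
#' The two fixed synthetic conditions used by the package's validation
#' suite. \code{"bulk"}: the \code{\link{simConfig}} defaults (200-kb
#' chromosome, 25,000 fragments = 50,000 cuts, nine narrow vs six broad
#' features, equal target mass). \code{"singlecell"}: a 600-kb chromosome
#' with 36 narrow and 33 broad features, two thirds of them private to one
#' of two cell types, and 200 cells (100 per type) with a five-fold linear
#' depth gradient. The mean depth of 125 fragments per cell (25,000
#' fragments) keeps per-peak per-cell coverage (~1-2 in-peak fragments per
#' visible feature) in the sparse regime that single-cell chromatin count
#' matrices occupy; higher depths saturate the binarized matrix on a
#' desk-scale peak panel.
#'
#' @param type \code{"bulk"} or \code{"singlecell"}.
#' @param seed RNG seed.
#' @return a \code{\linkS4class{SimConfig}}.
#' @export
benchmarkConfig <- function(type = c("bulk", "singlecell"), seed = 1) {
  type <- match.arg(type)
  if (type == "bulk") return(simConfig(seed = seed))
  simConfig(genome = Seqinfo("chrS", 600000L),
            nPolFeatures = 36, nK27Features = 33,
            polFeatureWidth = 300, k27FeatureWidth = 1000,
            nFragments = 25000, nCells = 200,
            typeSpecificFraction = 2 / 3, depthRange = c(1, 5),
            seed = seed)
}

#' Per-cut assignment accuracy against simulation truth
#'
#' Fraction of cut weight whose posterior target assignment (Pol2S5p when
#' \code{pPol > 0.5}) matches the generating target recorded in the truth
#' table. Cuts outside deconvolved cores are ignored; the covered fraction
#' is reported alongside.
#'
#' @param result a \code{\linkS4class{DeconvResult}}.
#' @param sim output of \code{\link{simulateTagMix}}.
#' @return list with \code{accuracy} and \code{covered}.
#' @export
assignmentAccuracy <- function(result, sim) {
  fr <- sim$fragments
  cuts <- fragmentsToCuts(fr)
  asn <- assignCuts(result, cuts)
  key <- paste(rep(as.character(GenomeInfoDb::seqnames(fr)), 2),
               c(start(fr) - 1, end(fr)), c(width(fr), width(fr)))
  lab <- rep(sim$table$target, 2)
  m <- match(key, paste(asn$chrom, asn$pos, asn$fraglen))
  ok <- !is.na(m)
  pP <- asn$pPol[m[ok]]
  correct <- ifelse(lab[ok] == "Pol2S5p", pP > 0.5, pP <= 0.5)
  list(accuracy = mean(correct), covered = mean(ok))
}

#' Base-pair precision and recall of called peaks against truth features
#'
#' Compares the called intervals of one target class with the recorded
#' ground-truth feature intervals, both reduced to disjoint bp sets.
#'
#' @param peaks classified peak \code{GRanges}.
#' @param truth output of \code{\link{simulateTruth}}.
#' @param target \code{"Pol2S5p"} or \code{"H3K27me3"}.
#' @return list with \code{precision}, \code{recall}, \code{nCalled}.
#' @export
peakRecovery <- function(peaks, truth, target) {
  sel <- mcols(peaks)$target == target
  f <- truth$features[truth$features$target == target, , drop = FALSE]
  if (!sum(sel) || !nrow(f))
    return(list(precision = NA_real_, recall = NA_real_,
                nCalled = sum(sel)))
  called <- reduce(GRanges(as.character(GenomeInfoDb::seqnames(peaks[sel])),
                           IRanges(start(peaks[sel]), end(peaks[sel]))))
  tru <- reduce(GRanges(f$chrom, IRanges(f$start + 1, f$end)))
  ov <- sum(width(GenomicRanges::intersect(called, tru)))
  list(precision = ov / sum(width(called)),
       recall = ov / sum(width(tru)), nCalled = sum(sel))
}
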