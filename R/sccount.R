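#' Pool barcoded fragments into a pseudo-bulk set
#'
#' Drops the barcode column and collapses identical intervals with summed
#' counts; the result feeds the bulk deconvolution.
#'
#' @param frags barcoded fragment \code{GRanges}.
#' @return unbarcoded, collapsed, sorted \code{GRanges}.
#' @export
pseudobulk <- function(frags) {
  if (!length(frags) || all(is.na(mcols(frags)$barcode)))
    stop("no barcoded fragments")
  mcols(frags)$barcode <- NA_character_
  collapseFragments(frags)
}

#' Cell-by-peak fragment count matrix
#'
#' Counts, for every cell and every retained peak, the fragments whose
#' half-open interval intersects the peak by at least one bp (a fragment
#' spanning two peaks is counted in both), weighted by duplicate count.
#' Peaks of the \code{"overlap"} class are excluded. Cells with no
#' in-peak fragments keep an all-zero column; per-cell library sizes count
#' all fragments, in peaks or not.
#'
#' @param frags barcoded fragment \code{GRanges}.
#' @param peaks classified peak \code{GRanges} with a \code{target} column.
#' @return a \code{SummarizedExperiment} (peaks x cells) with a sparse
#'   \code{counts} assay, peak ranges as rows and \code{librarySize} in
#'   \code{colData}.
#' @export
countMatrix <- function(frags, peaks) {
  keep <- mcols(peaks)$target != "overlap"
  peaks <- peaks[keep]
  if (!length(peaks)) stop("no peaks left after removing the overlap class")
  bc <- mcols(frags)$barcode
  if (all(is.na(bc))) stop("fragments carry no barcodes")
  cells <- sort(unique(bc[!is.na(bc)]))
  count <- mcols(frags)$count
  if (is.null(count)) count <- rep(1L, length(frags))
  ov <- findOverlaps(frags, peaks)
  ci <- match(bc[queryHits(ov)], cells)
  ok <- !is.na(ci)
  m <- Matrix::sparseMatrix(
    i = subjectHits(ov)[ok], j = ci[ok], x = as.numeric(count[queryHits(ov)[ok]]),
    dims = c(length(peaks), length(cells)))
  rownames(m) <- sprintf("%s:%d-%d", as.character(GenomeInfoDb::seqnames(peaks)),
                         start(peaks) - 1L, end(peaks))
  colnames(m) <- cells
  lib <- tapply(as.numeric(count)[!is.na(bc)], bc[!is.na(bc)], sum)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m), rowRanges = peaks,
    colData = DataFrame(row.names = cells,
                        librarySize = as.numeric(lib[cells])))
}

.tfidfOne <- function(counts) {
  b <- counts
  b@x <- rep(1, length(b@x))          # binarize
  cellSum <- Matrix::colSums(b)
  cellSum[cellSum == 0] <- 1
  nCells <- ncol(b)
  idf <- log(1 + nCells / (1 + Matrix::rowSums(b)))
  tf <- b %*% Matrix::Diagonal(x = 1 / cellSum)
  m <- Matrix::Diagonal(x = idf) %*% tf
  m@x <- log(m@x * 1e4 + 1)
  dimnames(m) <- dimnames(counts)
  methods::as(m, "CsparseMatrix")
}

#' TF-IDF normalization of a cell-by-peak matrix
#'
#' Binarizes the counts and applies term-frequency / inverse-document
#' frequency weighting per target, then concatenates the targets: for cell
#' j and peak i, \code{TF = b_ij / sum_i b_ij},
#' \code{IDF = log(1 + nCells / (1 + nCellsWithPeak_i))}, and the
#' normalized value is \code{log(TF * IDF * 1e4 + 1)}. Output is invariant
#' to count scaling (binarize first) and computed independently per
#' target.
#'
#' @param se \code{SummarizedExperiment} from \code{\link{countMatrix}}.
#' @param targets peak classes to use (default both).
#' @return sparse normalized matrix (selected peaks x cells) with the
#'   peaks' target labels as \code{"target"} attribute.
#' @export
tfidfNormalize <- function(se, targets = c("Pol2S5p", "H3K27me3")) {
  counts <- SummarizedExperiment::assay(se, "counts")
  lab <- as.character(mcols(SummarizedExperiment::rowRanges(se))$target)
  parts <- list(); partLab <- character(0)
  for (tg in targets) {
    rows <- which(lab == tg)
    if (!length(rows)) next
    sub <- counts[rows, , drop = FALSE]
    if (all(sub == 0)) stop("all-zero count matrix for target ", tg)
    parts[[tg]] <- .tfidfOne(sub)
    partLab <- c(partLab, rep(tg, length(rows)))
  }
  if (!length(parts)) stop("no peaks for the requested targets")
  out <- do.call(rbind, parts)
  attr(out, "target") <- partLab
  out
}

#' LSI embedding with library-size component exclusion
#'
#' Truncated singular value decomposition of the normalized matrix; cell
#' coordinates are \code{U D}. Among the first two components, any whose
#' coordinates have absolute Pearson correlation with log library size
#' above \code{corCutoff} is excluded from the retained coordinates.
#' Component signs follow a deterministic convention (largest-magnitude
#' peak loading positive).
#'
#' @param norm normalized matrix (peaks x cells) from
#'   \code{\link{tfidfNormalize}}.
#' @param libSize per-cell library sizes (same order as columns).
#' @param nComponents number of singular vectors (default 30).
#' @param corCutoff exclusion threshold.
#' @return a \code{\linkS4class{LsiEmbedding}}.
#' @export
lsiEmbed <- function(norm, libSize, nComponents = 30, corCutoff = 0.9) {
  x <- t(as.matrix(norm))                      # cells x peaks
  k <- min(nComponents, nrow(x), ncol(x))
  if (k < 2) stop("rank-deficient input: need at least 2 components")
  sv <- svd(x, nu = k, nv = k)
  u <- sv$u; v <- sv$v; d <- sv$d[seq_len(k)]
  for (j in seq_len(k)) {
    s <- sign(v[which.max(abs(v[, j])), j])
    if (s < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  coords <- u %*% diag(d, k)
  rownames(coords) <- rownames(x)
  rownames(v) <- colnames(x)
  lg <- log(libSize)
  excl <- integer(0)
  for (j in seq_len(min(2L, k))) {
    r <- suppressWarnings(cor(coords[, j], lg))
    if (!is.na(r) && abs(r) > corCutoff) excl <- c(excl, j)
  }
  retained <- setdiff(seq_len(k), excl)
  new("LsiEmbedding", coords = coords[, retained, drop = FALSE],
      allCoords = coords, loadings = v, d = d, excluded = as.integer(excl),
      libSize = as.numeric(libSize))
}

#' Most variable peaks by first-component loading
#'
#' Ranks peaks by the absolute loading on the first retained component and
#' returns the top \code{k} per target.
#'
#' @param embedding a \code{\linkS4class{LsiEmbedding}}.
#' @param targets character vector of peak target labels, parallel to the
#'   rows of the normalized matrix (e.g. the \code{"target"} attribute of
#'   \code{\link{tfidfNormalize}} output).
#' @param k peaks to keep per target (default 400).
#' @return data.frame (peak, target, loading) ranked within target.
#' @export
variablePeaks <- function(embedding, targets, k = 400) {
  firstRetained <- setdiff(seq_along(embedding@d), embedding@excluded)[1]
  load <- embedding@loadings[, firstRetained]
  peaks <- rownames(embedding@loadings)
  if (is.null(peaks)) peaks <- as.character(seq_along(load))
  out <- NULL
  for (tg in unique(targets)) {
    sel <- which(targets == tg)
    if (k > length(sel))
      warning("k exceeds the number of ", tg, " peaks; returning all")
    ord <- sel[order(abs(load[sel]), decreasing = TRUE)]
    ord <- head(ord, k)
    if (length(ord))
      out <- rbind(out, data.frame(peak = peaks[ord], target = tg,
                                   loading = load[ord]))
  }
  if (is.null(out))
    out <- data.frame(peak = character(0), target = character(0),
                      loading = numeric(0))
  rownames(out) <- NULL
  out
}
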