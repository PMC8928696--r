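#' Read a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path file path.
#' @return a \code{Seqinfo}.
#' @export
readGenome <- function(path) {
  tab <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = list(character = 1))
  if (ncol(tab) < 2L) stop("chrom.sizes file needs two columns: ", path)
  nm <- as.character(tab[[1L]])
  len <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(len) || any(len <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(nm)) stop("duplicated chromosome names")
  Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' Read a fragment BED file
#'
#' Tab-separated BED-style fragments: chrom, start, end (0-based half-open),
#' optional cell barcode in column 4 and multiplicity count in column 5.
#' Malformed coordinate lines abort with their line numbers; fragments on
#' chromosomes absent from \code{genome} are dropped with a message. By
#' default identical records (same interval and barcode) are collapsed into
#' one row with summed count.
#'
#' @param path file path (plain or gzip).
#' @param genome a \code{Seqinfo}; fragments must fit inside its bounds.
#' @param collapse collapse duplicate records, summing counts.
#' @return a sorted \code{GRanges} with metadata columns \code{barcode}
#'   (character or \code{NA}) and \code{count} (positive integer).
#' @export
readFragments <- function(path, genome, collapse = TRUE) {
  if (!file.exists(path)) stop("cannot read fragment file: ", path)
  if (file.size(path) == 0) return(emptyFragments(genome))
  tab <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                           colClasses = "character")
  if (nrow(tab) == 0L) return(emptyFragments(genome))
  if (ncol(tab) < 3L) stop("fragment file needs at least three columns")
  chrom <- tab[[1L]]
  start0 <- suppressWarnings(as.numeric(tab[[2L]]))
  end0 <- suppressWarnings(as.numeric(tab[[3L]]))
  bad <- which(is.na(start0) | is.na(end0) | start0 != floor(start0) |
               end0 != floor(end0) | start0 < 0 | start0 >= end0)
  if (length(bad))
    stop("malformed fragment lines (start/end): line ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  barcode <- if (ncol(tab) >= 4L) {
    b <- tab[[4L]]
    b[!nzchar(b) | b == "."] <- NA_character_
    b
  } else rep(NA_character_, nrow(tab))
  count <- if (ncol(tab) >= 5L) {
    raw <- tab[[5L]]
    raw[!nzchar(raw) | raw == "."] <- "1"   # rows with fewer columns
    cnt <- suppressWarnings(as.numeric(raw))
    badc <- which(is.na(cnt) | cnt != floor(cnt) | cnt < 1)
    if (length(badc))
      stop("malformed fragment counts: line ",
           paste(head(badc, 10L), collapse = ", "))
    as.integer(cnt)
  } else rep(1L, nrow(tab))

  known <- chrom %in% seqnames(genome)
  if (!all(known))
    message(sum(!known), " fragments on chromosomes absent from the genome ",
            "were dropped")
  chrom <- chrom[known]; start0 <- start0[known]; end0 <- end0[known]
  barcode <- barcode[known]; count <- count[known]
  if (!length(chrom)) return(emptyFragments())
  lens <- seqlengths(genome)[chrom]
  if (any(end0 > lens))
    stop("fragment end beyond chromosome length at line ",
         paste(head(which(known)[end0 > lens], 10L), collapse = ", "))
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), seqinfo = genome)
  mcols(gr)$barcode <- barcode
  mcols(gr)$count <- count
  gr <- GenomicRanges::sort(gr)
  if (collapse) gr <- collapseFragments(gr)
  gr
}

emptyFragments <- function(genome = NULL) {
  gr <- GRanges(seqinfo = genome)
  mcols(gr)$barcode <- character(0)
  mcols(gr)$count <- integer(0)
  gr
}

#' Collapse duplicate fragments
#'
#' Records sharing chromosome, interval and barcode become one record with
#' summed count.
#'
#' @param frags fragment \code{GRanges}.
#' @return collapsed, sorted \code{GRanges}.
#' @export
collapseFragments <- function(frags) {
  if (!length(frags)) return(frags)
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(frags)),
    start = start(frags), end = end(frags),
    barcode = mcols(frags)$barcode, count = as.numeric(mcols(frags)$count))
  agg <- dt[, list(count = sum(count)), by = c("chrom", "start", "end",
                                               "barcode")]
  data.table::setorderv(agg, c("chrom", "start", "end", "barcode"))
  gr <- GRanges(agg$chrom, IRanges(agg$start, agg$end),
                seqinfo = GenomeInfoDb::seqinfo(frags))
  mcols(gr)$barcode <- agg$barcode
  mcols(gr)$count <- as.integer(agg$count)
  gr
}

#' Write fragments as BED
#'
#' Columns: chrom, start, end (0-based half-open), barcode (\code{.} when
#' absent), count.
#'
#' @param frags fragment \code{GRanges}.
#' @param path output path.
#' @export
writeFragments <- function(frags, path) {
  bc <- mcols(frags)$barcode
  bc[is.na(bc)] <- "."
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(frags)),
    start = start(frags) - 1L, end = end(frags),
    barcode = bc, count = mcols(frags)$count)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert fragments to weighted cut sites
#'
#' Every fragment contributes two cut sites, one at each endpoint of its
#' half-open interval (BED start and BED end), both carrying the fragment
#' length and the fragment's count as weight. Identical
#' (chrom, pos, fraglen) triples are collapsed with summed weight; total
#' cut weight is twice the total fragment count.
#'
#' @param frags fragment \code{GRanges} with a \code{count} column.
#' @return a \code{\linkS4class{CutSites}} object.
#' @export
fragmentsToCuts <- function(frags) {
  if (!length(frags))
    return(new("CutSites", chrom = character(0), pos = numeric(0),
               fraglen = numeric(0), weight = numeric(0)))
  count <- mcols(frags)$count
  if (is.null(count)) count <- rep(1L, length(frags))
  chrom <- as.character(GenomeInfoDb::seqnames(frags))
  cutSites(chrom = c(chrom, chrom),
           pos = c(start(frags) - 1, end(frags)),
           fraglen = c(width(frags), width(frags)),
           weight = as.numeric(c(count, count)))
}

#' Construct cut sites
#'
#' Collapses identical (chrom, pos, fraglen) records with summed weight and
#' sorts by (chrom, pos, fraglen).
#'
#' @param chrom,pos,fraglen,weight parallel vectors (pos is 0-based).
#' @return a \code{\linkS4class{CutSites}}.
#' @export
cutSites <- function(chrom, pos, fraglen, weight = rep(1, length(pos))) {
  dt <- data.table::data.table(chrom = as.character(chrom),
                               pos = as.numeric(pos),
                               fraglen = as.numeric(fraglen),
                               weight = as.numeric(weight))
  agg <- dt[, list(weight = sum(weight)), by = c("chrom", "pos", "fraglen")]
  data.table::setorderv(agg, c("chrom", "pos", "fraglen"))
  new("CutSites", chrom = agg$chrom, pos = agg$pos, fraglen = agg$fraglen,
      weight = agg$weight)
}

#' Subset cut sites to one chromosome
#' @param cuts a \code{CutSites}.
#' @param chrom chromosome name.
#' @return a \code{CutSites}.
#' @export
cutsOnChrom <- function(cuts, chrom) {
  k <- cuts@chrom == chrom
  new("CutSites", chrom = cuts@chrom[k], pos = cuts@pos[k],
      fraglen = cuts@fraglen[k], weight = cuts@weight[k])
}

#' Write a deconvolved signal track as bedGraph
#'
#' Emits the exponentiated (cuts per bp) density of one target on the
#' output grid, 0-based half-open intervals of one grid pitch each.
#'
#' @param result a \code{\linkS4class{DeconvResult}} or a data.frame with
#'   columns chrom, start, end, value (already 0-based half-open).
#' @param path output path.
#' @param target \code{"pol"} or \code{"k27"} (ignored for data.frames).
#' @export
writeBedGraph <- function(result, path, target = c("pol", "k27")) {
  if (is.data.frame(result)) {
    df <- result
  } else {
    target <- match.arg(target)
    pitch <- result@config@gridPitch
    rows <- lapply(result@tracks, function(tr) {
      v <- if (target == "pol") tr@gridLogPol else tr@gridLogK27
      if (!length(tr@gridPos)) return(NULL)
      data.table::data.table(chrom = tr@chrom, start = tr@gridPos,
                             end = tr@gridPos + pitch, value = exp(v))
    })
    df <- data.table::rbindlist(rows)
  }
  if (nrow(df) && any(!is.finite(df$value)))
    stop("non-finite track values; refusing to write bedGraph")
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write classified peaks as BED6+1
#'
#' Name column carries the class label (\code{Pol2S5p}, \code{H3K27me3} or
#' \code{overlap}); column 7 holds the summit offset from the peak start for
#' Pol2S5p peaks and \code{-1} otherwise (H3K27me3 domains have no summit).
#'
#' @param peaks \code{GRanges} with metadata columns \code{target},
#'   \code{summit} (absolute 0-based position or \code{NA}) and
#'   \code{score}.
#' @param path output path.
#' @export
writePeaks <- function(peaks, path) {
  start0 <- start(peaks) - 1L
  summit <- mcols(peaks)$summit
  if (is.null(summit)) summit <- rep(NA_real_, length(peaks))
  off <- ifelse(is.na(summit), -1, summit - start0)
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = start0, end = end(peaks),
    name = as.character(mcols(peaks)$target),
    score = signif(mcols(peaks)$score, 6), strand = ".", summit = off)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak BED file
#'
#' @param path BED path with at least chrom, start, end; column 4 is taken
#'   as the class label and column 7 as the summit offset if present.
#' @param genome optional \code{Seqinfo}.
#' @return \code{GRanges} with \code{target}, \code{summit}, \code{score}.
#' @export
readPeaks <- function(path, genome = NULL) {
  tab <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                           colClasses = "character")
  if (nrow(tab) == 0L)
    return(GRanges(seqinfo = genome))
  start0 <- as.numeric(tab[[2L]])
  end0 <- as.numeric(tab[[3L]])
  gr <- GRanges(tab[[1L]], IRanges(start0 + 1, end0), seqinfo = genome)
  mcols(gr)$target <- if (ncol(tab) >= 4L) tab[[4L]] else NA_character_
  mcols(gr)$score <- if (ncol(tab) >= 5L)
    suppressWarnings(as.numeric(tab[[5L]])) else NA_real_
  summit <- rep(NA_real_, length(gr))
  if (ncol(tab) >= 7L) {
    off <- suppressWarnings(as.numeric(tab[[7L]]))
    summit <- ifelse(!is.na(off) & off >= 0, start0 + off, NA_real_)
  }
  mcols(gr)$summit <- summit
  GenomicRanges::sort(gr)
}
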