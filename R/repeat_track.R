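REPEAT_CLASSES <- c("LTR", "LINE", "DNA", "RollingCircle",
                    "SimpleLowComplexitySatellite", "OtherRepeat")

# RepeatMasker repClass values -> controlled vocabulary
RMSK_CLASS_MAP <- c(
  LTR = "LTR", LINE = "LINE", DNA = "DNA", RC = "RollingCircle",
  "Rolling-circle" = "RollingCircle",
  Simple_repeat = "SimpleLowComplexitySatellite",
  Low_complexity = "SimpleLowComplexitySatellite",
  Satellite = "SimpleLowComplexitySatellite"
)

map_repeat_class <- function(x) {
  out <- unname(RMSK_CLASS_MAP[x])
  ifelse(is.na(out),
         ifelse(x %in% REPEAT_CLASSES, x, "OtherRepeat"),
         out)
}

#' Build a repeat annotation track
#'
#' A labeled set of genomic intervals partitioning positions into repeat
#' classes. Accepts a data.frame (columns chrom, start, end, class;
#' 0-based half-open), a BED file path (4th column = class), or a UCSC
#' RepeatMasker table export (columns genoName, genoStart, genoEnd,
#' repClass). Repeat class names outside the controlled vocabulary are
#' mapped through the RepeatMasker dictionary (LTR, LINE, DNA,
#' RC/Rolling-circle, Simple_repeat/Low_complexity/Satellite) and anything
#' else becomes OtherRepeat.
#'
#' @param x data.frame or file path.
#' @return an object of class \code{repeat_track} wrapping a
#'   \code{GRanges} with metadata column \code{repeat_class}.
#' @export
repeat_track <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    first <- readLines(x, n = 1L)
    if (grepl("genoName", first)) {
      tab <- utils::read.table(x, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      df <- data.frame(chrom = tab$genoName, start = tab$genoStart,
                       end = tab$genoEnd, class = tab$repClass)
    } else {
      gr <- rtracklayer::import(x, format = "BED")
      df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr),
                       class = gr$name)
    }
  } else {
    df <- as.data.frame(x)
    names(df)[1:4] <- c("chrom", "start", "end", "class")
  }
  if (any(df$start >= df$end)) stopf("malformed repeat interval: start >= end")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    repeat_class = map_repeat_class(as.character(df$class)))
  structure(list(gr = gr), class = "repeat_track")
}

#' @export
print.repeat_track <- function(x, ...) {
  tab <- table(x$gr$repeat_class)
  cat(sprintf("Repeat track: %d intervals, %d bp\n",
              length(x$gr), sum(GenomicRanges::width(x$gr))))
  for (k in names(tab)) cat(sprintf("  %s: %d\n", k, tab[[k]]))
  invisible(x)
}

# GRanges of the track restricted to one chromosome
repeat_intervals <- function(track, chrom) {
  gr <- track$gr
  gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
}

#' Annotate positions with their repeat class
#'
#' Positions overlapping no interval are NonRepetitive. Overlapping
#' several classes resolves by the precedence order LTR > LINE > DNA >
#' RollingCircle > SimpleLowComplexitySatellite > OtherRepeat, so
#' transposable-element classes dominate nested annotations. With
#' \code{all_classes = TRUE} every overlapping class is returned per
#' position instead.
#'
#' @param positions integer vector of 0-based positions.
#' @param track a \code{repeat_track}.
#' @param chrom chromosome of the positions.
#' @param all_classes return a list of all overlapping classes instead of
#'   one label per position.
#' @return character vector of labels (or list when
#'   \code{all_classes = TRUE}).
#' @export
annotate_repeat_class <- function(positions, track, chrom = "chr1",
                                  all_classes = FALSE) {
  stopifnot(inherits(track, "repeat_track"))
  if (length(positions) == 0L)
    return(if (all_classes) list() else character(0))
  gr <- repeat_intervals(track, chrom)
  q <- GenomicRanges::GRanges(rep(chrom, length(positions)),
                              IRanges::IRanges(start = positions + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, gr)
  if (all_classes) {
    out <- rep(list(character(0)), length(positions))
    sp <- split(gr$repeat_class[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    out[as.integer(names(sp))] <- lapply(sp, unique)
    return(out)
  }
  rank <- match(gr$repeat_class[S4Vectors::subjectHits(hits)], REPEAT_CLASSES)
  best <- tapply(rank, S4Vectors::queryHits(hits), min)
  out <- rep("NonRepetitive", length(positions))
  out[as.integer(names(best))] <- REPEAT_CLASSES[best]
  out
}
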