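#' Construct a set of genomic segments
#'
#' Segments are the package's interval currency: runs of homozygosity,
#' shared loss-of-heterozygosity (LOH) regions, and ground-truth autozygous
#' tracts are all represented as a data frame of half-open intervals.
#' Coordinates are 0-based half-open internally (`start` inclusive, `end`
#' exclusive), the BED convention; use [display_coords()] /
#' [internal_coords()] to convert to and from the 1-based inclusive
#' coordinates printed in VCFs and publication tables.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open. Must satisfy
#'   `0 <= start < end`.
#' @param sample_id optional character vector: which sample each segment
#'   belongs to (`NA` for sample-less tracks such as shared-LOH output).
#' @param n_markers optional numeric vector: number of genotyped markers
#'   supporting each segment (`NA` when unknown).
#' @return A `data.frame` with columns `chrom`, `start`, `end`,
#'   `sample_id`, `n_markers`, sorted by `(chrom, start, end)`.
#' @examples
#' seg <- segments("chr6", 16893010, 18222277)  # Table-style 16,893,011-18,222,277
#' @export
segments <- function(chrom = character(), start = numeric(), end = numeric(),
                     sample_id = NA_character_, n_markers = NA_real_) {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 0 || length(start) == 0) n <- 0
  x <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    sample_id = rep_len(as.character(sample_id), n),
    n_markers = rep_len(as.numeric(n_markers), n),
    stringsAsFactors = FALSE
  )
  validate_segments(x)
  sort_segments(x)
}

#' Validate a segment data frame
#'
#' @param x data.frame as produced by [segments()].
#' @return `x`, invisibly, or an error.
#' @export
validate_segments <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop("segment chrom must be non-empty", call. = FALSE)
  if (any(x$start < 0))
    stop("segment start must be >= 0", call. = FALSE)
  if (any(x$start >= x$end))
    stop("segment start must be < end (0-based half-open)", call. = FALSE)
  invisible(x)
}

#' Sort segments by (chrom, start, end)
#' @param x segment data.frame.
#' @return sorted data.frame, row names dropped.
#' @export
sort_segments <- function(x) {
  if (nrow(x) == 0) return(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' All user-facing coordinates (VCF positions, publication tables) are
#' 1-based inclusive; all internal interval arithmetic is 0-based
#' half-open. These two functions are the single conversion point used
#' throughout the package: internal start = printed start - 1, internal
#' end = printed end.
#'
#' @param start,end coordinate vectors.
#' @return a list with numeric `start` and `end` in the other convention.
#' @examples
#' internal_coords(16893011, 18222277)  # -> start 16893010, end 18222277
#' @export
internal_coords <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  list(start = as.numeric(start) - 1, end = as.numeric(end))
}

#' @rdname internal_coords
#' @export
display_coords <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  list(start = as.numeric(start) + 1, end = as.numeric(end))
}

## GRanges bridge: interval algebra (intersection, subtraction, gap
## merging) is delegated to GenomicRanges; these converters keep the
## 0-based half-open <-> 1-based closed shift in one place.
segments_to_granges <- function(x) {
  validate_segments(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

granges_to_segments <- function(gr, sample_id = NA_character_) {
  if (length(gr) == 0) return(segments())
  segments(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    sample_id = sample_id
  )
}

#' Total length of a segment set in base pairs
#' @param x segment data.frame.
#' @return numeric scalar, sum of `end - start`.
#' @export
segment_span <- function(x) {
  validate_segments(x)
  if (nrow(x) == 0) return(0)
  sum(x$end - x$start)
}
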