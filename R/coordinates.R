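#' Genomic intervals with explicit coordinate conventions
#'
#' All intervals inside the package are stored 0-based half-open (BED
#' convention): a base at 1-based position p is covered iff
#' `start <= p - 1 < end`. Everything user-facing that mirrors published
#' tables (probe spans, SNP positions) is 1-based inclusive and converted
#' at the boundary by [interval_from_1based()] / [interval_to_1based()].
#'
#' @param chrom character vector of chromosome labels.
#' @param start,end integer vectors, 0-based half-open.
#' @param name optional interval names.
#' @return A `genomic_intervals` data frame with columns
#'   `name`, `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' genomic_intervals("chr12", 69742132, 69748012, name = "LYZ")
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  chrom <- as.character(chrom)
  n <- max(length(chrom), length(start), length(end), length(name))
  iv <- data.frame(
    name = rep_len(as.character(name), n),
    chrom = rep_len(chrom, n),
    start = rep_len(start, n),
    end = rep_len(end, n),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(iv$chrom)) || anyNA(iv$chrom)) {
    stop("interval chromosome labels must be non-empty")
  }
  if (any(iv$start < 0)) stop("interval start must be >= 0")
  if (any(iv$start >= iv$end)) {
    bad <- which(iv$start >= iv$end)[1]
    stop(sprintf("interval start >= end at row %d (%s:%s-%s)",
                 bad, iv$chrom[bad], iv$start[bad], iv$end[bad]))
  }
  class(iv) <- c("genomic_intervals", "data.frame")
  iv
}

#' Convert between 1-based inclusive and 0-based half-open intervals
#'
#' `interval_from_1based()` takes coordinates as printed in annotation
#' tables (first and last covered base, both inclusive) and returns the
#' internal representation; `interval_to_1based()` is its exact inverse.
#' The two maps are lossless and involutive on valid intervals.
#'
#' @param chrom chromosome labels.
#' @param start1,end1 1-based inclusive first/last covered base.
#' @param name optional names.
#' @return `interval_from_1based()`: a `genomic_intervals` object.
#'   `interval_to_1based()`: a data frame with `name`, `chrom`,
#'   `start1`, `end1`.
#' @examples
#' iv <- interval_from_1based("chr12", 69742133, 69748012, name = "LYZ")
#' interval_to_1based(iv)
#' @export
interval_from_1based <- function(chrom, start1, end1, name = NA_character_) {
  if (any(start1 < 1)) stop("1-based start must be >= 1")
  genomic_intervals(chrom, start1 - 1, end1, name = name)
}

#' @param intervals a `genomic_intervals` object.
#' @rdname interval_from_1based
#' @export
interval_to_1based <- function(intervals) {
  stopifnot(inherits(intervals, "genomic_intervals"))
  data.frame(
    name = intervals$name,
    chrom = intervals$chrom,
    start1 = intervals$start + 1,
    end1 = intervals$end,
    stringsAsFactors = FALSE
  )
}

#' Does an interval contain a 1-based position?
#'
#' Strand-agnostic containment of a point in half-open intervals.
#'
#' @param intervals a `genomic_intervals` object.
#' @param chrom chromosome of the query position.
#' @param pos1 1-based base position.
#' @return logical vector, one entry per interval.
#' @export
interval_contains <- function(intervals, chrom, pos1) {
  stopifnot(inherits(intervals, "genomic_intervals"), length(chrom) == 1,
            length(pos1) == 1)
  p0 <- pos1 - 1
  intervals$chrom == chrom & intervals$start <= p0 & p0 < intervals$end
}

#' Distance from a 1-based position to an interval
#'
#' Zero if the position lies inside the interval, otherwise the gap in
#' bases to the nearest interval edge. `Inf` across chromosomes.
#'
#' @inheritParams interval_contains
#' @return numeric vector of distances in bp.
#' @export
interval_distance <- function(intervals, chrom, pos1) {
  stopifnot(inherits(intervals, "genomic_intervals"))
  d1 <- interval_to_1based(intervals)
  out <- ifelse(
    d1$chrom != chrom, Inf,
    pmax(0, pmax(d1$start1 - pos1, pos1 - d1$end1))
  )
  as.numeric(out)
}
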