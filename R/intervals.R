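#' Genomic intervals
#'
#' All coordinates inside the package are 0-based half-open: an interval
#' `[start, end)` covers bases `start .. end - 1`. GTF and SAM/BAM input is
#' converted at the boundary. A set of intervals is represented as a
#' `data.frame` with numeric `start` and `end` columns (plus optional extra
#' columns that travel along).
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @return A one-row `data.frame` with columns `chrom`, `start`, `end`.
#' @examples
#' genome_interval("chr1", 100, 200)
#' @export
genome_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), nzchar(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start < end)) {
    stop("invalid interval: start (", start, ") must be < end (", end, ")")
  }
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Merge intervals with a gap tolerance
#'
#' Single-pass sort-and-sweep merge: two intervals are joined when they
#' overlap or when the gap between them is at most `gap_threshold` base
#' pairs. The gap between `[a, b)` and `[c, d)` with `b <= c` is `c - b`,
#' so a gap of exactly `gap_threshold` still merges and `gap_threshold + 1`
#' splits. This is the primitive behind bundle construction and MSB
#' inference.
#'
#' @param starts,ends Numeric vectors of 0-based half-open intervals
#'   (all on one chromosome).
#' @param gap_threshold Maximum gap (bp) that still joins two intervals.
#' @return A `data.frame` with columns `start`, `end` (merged, sorted) and
#'   `n_members` (how many input intervals each merged interval absorbed).
#' @examples
#' merge_intervals(c(100, 240), c(200, 300), gap_threshold = 50) # one interval
#' merge_intervals(c(100, 251), c(200, 300), gap_threshold = 50) # two
#' @export
merge_intervals <- function(starts, ends, gap_threshold = 50) {
  stopifnot(length(starts) == length(ends), gap_threshold >= 0)
  if (length(starts) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_members = integer(0)))
  }
  if (any(ends <= starts)) stop("invalid interval: end <= start")
  o <- order(starts, ends)
  s <- starts[o]; e <- ends[o]
  # sweep: a new merged interval opens when the gap to the running end
  # exceeds the threshold
  run_end <- cummax_end(e)
  new_group <- c(TRUE, s[-1L] - run_end[-length(run_end)] > gap_threshold)
  grp <- cumsum(new_group)
  data.frame(
    start = as.numeric(tapply(s, grp, min)),
    end = as.numeric(tapply(e, grp, max)),
    n_members = as.integer(tabulate(grp)),
    row.names = NULL
  )
}

# running maximum of interval ends in sorted order
cummax_end <- function(e) cummax(e)

#' Assign intervals to merged groups
#'
#' Same sweep as [merge_intervals()] but returns, for each input interval,
#' the index of the merged interval it belongs to (in sorted merged order).
#' @inheritParams merge_intervals
#' @return Integer vector of group indices aligned with the input.
#' @keywords internal
merge_group_ids <- function(starts, ends, gap_threshold = 50) {
  if (length(starts) == 0L) return(integer(0))
  o <- order(starts, ends)
  s <- starts[o]; e <- ends[o]
  run_end <- cummax(e)
  new_group <- c(TRUE, s[-1L] - run_end[-length(run_end)] > gap_threshold)
  grp <- cumsum(new_group)
  out <- integer(length(starts))
  out[o] <- grp
  out
}

# TRUE where [s1,e1) overlaps [s2,e2) by >= 1 bp (vectorised)
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# gap in bp between two half-open intervals; 0 if they overlap or touch
interval_gap <- function(s1, e1, s2, e2) pmax(0, pmax(s1, s2) - pmin(e1, e2))
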