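#' Coverage profile (run-length encoded counts along one chromosome)
#'
#' A coverage profile is the series of non-negative integer read counts
#' \eqn{Y = (y_1, \dots, y_n)} along a contiguous chromosome interval, stored
#' run-length encoded: each run covers `[start, end)` (0-based, half-open)
#' with one constant count. Runs must be sorted, non-overlapping and
#' contiguous; a gap between runs is an error, never silently zero-filled.
#'
#' @param chrom Chromosome name (length-1 character).
#' @param starts,ends Integer vectors of 0-based half-open run boundaries.
#' @param counts Integer vector of non-negative counts, one per run.
#' @return An object of class `coverage_profile` with fields `chrom`,
#'   `starts`, `ends`, `counts` and `n` (total number of covered bases).
#' @examples
#' coverage_profile("chr1", c(0L, 5L), c(5L, 8L), c(2L, 0L))
#' @export
coverage_profile <- function(chrom, starts, ends, counts) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) == 0L) {
    stop("coverage profile must contain at least one run")
  }
  if (length(starts) != length(ends) || length(starts) != length(counts)) {
    stop("starts, ends and counts must have equal length")
  }
  if (any(is.na(starts)) || any(is.na(ends)) || any(is.na(counts))) {
    stop("coverage profile fields must not contain NA")
  }
  if (any(counts != floor(counts)) || any(counts < 0)) {
    stop("counts must be non-negative integers")
  }
  counts <- as.integer(counts)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; counts <- counts[o]
  if (any(ends - starts < 1L)) stop("all run widths must be >= 1")
  if (length(starts) > 1L) {
    gap <- which(starts[-1L] != ends[-length(ends)])
    if (length(gap)) {
      if (starts[gap[1L] + 1L] < ends[gap[1L]]) {
        stop(sprintf("overlapping runs at run %d ([%d,%d) then [%d,%d))",
                     gap[1L] + 1L, starts[gap[1L]], ends[gap[1L]],
                     starts[gap[1L] + 1L], ends[gap[1L] + 1L]))
      }
      stop(sprintf(
        "gap between runs at run %d: previous run ends at %d, next starts at %d (gaps are not zero-filled; see fill_gaps)",
        gap[1L] + 1L, ends[gap[1L]], starts[gap[1L] + 1L]))
    }
  }
  structure(
    list(chrom = chrom, starts = starts, ends = ends, counts = counts,
         n = sum(ends - starts)),
    class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile: %s:[%d,%d), %d bases in %d runs, counts in [%d,%d]\n",
              x$chrom, x$starts[1L], x$ends[length(x$ends)], x$n,
              length(x$starts), min(x$counts), max(x$counts)))
  invisible(x)
}

# run weights (bases per run)
profile_weights <- function(profile) profile$ends - profile$starts

# expand to one value per base (small profiles / oracles only)
profile_expand <- function(profile) {
  rep(profile$counts, profile_weights(profile))
}

#' Build a coverage profile from a per-base count vector
#'
#' Adjacent equal counts are merged into runs.
#'
#' @param counts Integer vector, one count per base.
#' @param chrom Chromosome name.
#' @param start Genomic position of the first base.
#' @return A [coverage_profile()].
#' @export
profile_from_counts <- function(counts, chrom = "chr1", start = 0L) {
  r <- rle(as.integer(counts))
  ends <- start + cumsum(r$lengths)
  starts <- c(start, ends[-length(ends)])
  coverage_profile(chrom, starts, ends, r$values)
}

#' Insert zero-count runs into gaps of a gapped run list
#'
#' Companion to [read_bedgraph()]'s strictness: explicitly fills gaps between
#' runs with count-0 runs. Exposed to the CLI as `--fill-gaps`.
#'
#' @param chrom,starts,ends,counts Raw run fields (possibly gapped).
#' @return A valid [coverage_profile()].
#' @export
fill_gaps <- function(chrom, starts, ends, counts) {
  o <- order(starts)
  starts <- as.integer(starts)[o]; ends <- as.integer(ends)[o]
  counts <- as.integer(counts)[o]
  gs <- integer(0); ge <- integer(0)
  if (length(starts) > 1L) {
    i <- which(starts[-1L] > ends[-length(ends)])
    gs <- ends[i]; ge <- starts[i + 1L]
  }
  coverage_profile(chrom, c(starts, gs), c(ends, ge),
                   c(counts, rep(0L, length(gs))))
}

label_types <- c("noPeaks", "peaks", "peakStart", "peakEnd")

#' Labeled regions for supervised peak detection
#'
#' Expert annotations come in four types: `noPeaks` (region contains only
#' background; any overlapping predicted peak is a false positive), `peaks`
#' (at least one overlapping peak required, otherwise a false negative),
#' `peakStart` / `peakEnd` (exactly one predicted peak start / end must fall
#' in the region; more than one is a false positive, none is a false
#' negative).
#'
#' @param chrom Chromosome name.
#' @param starts,ends 0-based half-open label regions.
#' @param types Character vector drawn from
#'   `c("noPeaks", "peaks", "peakStart", "peakEnd")`.
#' @return An object of class `label_set`.
#' @export
label_set <- function(chrom, starts, ends, types) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  starts <- as.integer(starts); ends <- as.integer(ends)
  types <- as.character(types)
  if (length(starts) != length(ends) || length(starts) != length(types)) {
    stop("starts, ends and types must have equal length")
  }
  bad <- setdiff(unique(types), label_types)
  if (length(bad)) {
    stop(sprintf("unknown label type '%s'; legal types are: %s",
                 bad[1L], paste(label_types, collapse = ", ")))
  }
  if (any(starts >= ends)) stop("every label must satisfy start < end")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; types <- types[o]
  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)])) {
    i <- which(starts[-1L] < ends[-length(ends)])[1L]
    stop(sprintf("overlapping labels: [%d,%d) %s and [%d,%d) %s",
                 starts[i], ends[i], types[i],
                 starts[i + 1L], ends[i + 1L], types[i + 1L]))
  }
  structure(list(chrom = chrom, starts = starts, ends = ends, types = types),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: %s, %d labels (%s)\n", x$chrom, length(x$starts),
              paste(sprintf("%s=%d", names(table(x$types)), table(x$types)),
                    collapse = ", ")))
  invisible(x)
}

#' Predicted peaks
#'
#' @param chrom Chromosome name.
#' @param starts,ends 0-based half-open peak intervals; sorted and
#'   non-overlapping.
#' @param heights Segment mean on the model's parameter scale, one per peak.
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(chrom, starts = integer(0), ends = integer(0),
                     heights = numeric(0)) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  starts <- as.integer(starts); ends <- as.integer(ends)
  heights <- as.numeric(heights)
  if (length(starts) != length(ends) || length(starts) != length(heights)) {
    stop("starts, ends and heights must have equal length")
  }
  if (any(starts >= ends)) stop("every peak must satisfy start < end")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; heights <- heights[o]
  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)])) {
    stop("peaks must not overlap")
  }
  structure(list(chrom = chrom, starts = starts, ends = ends,
                 heights = heights),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %s, %d peaks\n", x$chrom, length(x$starts)))
  invisible(x)
}

n_peaks <- function(peaks) length(peaks$starts)
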