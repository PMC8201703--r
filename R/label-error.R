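# Scoring predicted peaks against expert labels.
#
# Each label contributes at most one error:
#   noPeaks:   false positive if any peak overlaps the region
#   peaks:     false negative if no peak overlaps the region
#   peakStart: c = number of predicted peak starts in the region;
#              false positive if c > 1, false negative if c == 0
#   peakEnd:   same with peak end coordinates
# Intervals are 0-based half-open; a peak's "end coordinate" for peakEnd
# membership is its last covered base (end - 1), so a peak ending exactly
# at a label boundary is unambiguous.

#' Count label errors of a peak prediction
#'
#' @param peaks A [peak_set()].
#' @param labels A [label_set()] on the same chromosome.
#' @return Object of class `error_count`: `fp`, `fn`, `total` and a
#'   per-label `breakdown` data frame with a verdict in
#'   `c("correct", "fp", "fn")`.
#' @export
count_errors <- function(peaks, labels) {
  stopifnot(inherits(peaks, "peak_set"), inherits(labels, "label_set"))
  if (n_peaks(peaks) > 0L && peaks$chrom != labels$chrom) {
    stop(sprintf("chromosome mismatch: peaks on %s, labels on %s",
                 peaks$chrom, labels$chrom))
  }
  verdict <- character(length(labels$starts))
  for (i in seq_along(labels$starts)) {
    s <- labels$starts[i]; e <- labels$ends[i]
    type <- labels$types[i]
    overlaps <- peaks$starts < e & peaks$ends > s
    verdict[i] <- switch(type,
      noPeaks = if (any(overlaps)) "fp" else "correct",
      peaks = if (any(overlaps)) "correct" else "fn",
      peakStart = {
        c_in <- sum(peaks$starts >= s & peaks$starts < e)
        if (c_in > 1L) "fp" else if (c_in == 0L) "fn" else "correct"
      },
      peakEnd = {
        c_in <- sum(peaks$ends - 1L >= s & peaks$ends - 1L < e)
        if (c_in > 1L) "fp" else if (c_in == 0L) "fn" else "correct"
      })
  }
  fp <- sum(verdict == "fp"); fn <- sum(verdict == "fn")
  structure(
    list(fp = fp, fn = fn, total = fp + fn,
         breakdown = data.frame(start = labels$starts, end = labels$ends,
                                type = labels$types, verdict = verdict,
                                stringsAsFactors = FALSE)),
    class = "error_count")
}

#' @export
print.error_count <- function(x, ...) {
  cat(sprintf("error_count: fp=%d fn=%d total=%d over %d labels\n",
              x$fp, x$fn, x$total, nrow(x$breakdown)))
  invisible(x)
}

#' Label accuracy over a set of problems
#'
#' `1 - sum(errors) / sum(label counts)`: the fraction of labels predicted
#' correctly, pooled over problems.
#'
#' @param errors List of `error_count` objects (or a single one).
#' @param label_sets List of the matching [label_set()]s.
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(errors, label_sets) {
  if (inherits(errors, "error_count")) errors <- list(errors)
  if (inherits(label_sets, "label_set")) label_sets <- list(label_sets)
  if (length(errors) != length(label_sets)) {
    stop("errors and label_sets must align")
  }
  total_err <- sum(vapply(errors, `[[`, 0, "total"))
  total_lab <- sum(vapply(label_sets, function(l) length(l$starts), 0L))
  if (total_lab == 0L) stop("no labels: accuracy undefined")
  1 - total_err / total_lab
}
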