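# Model-checking diagnostics.
#
# overdispersion_log2(): per-segment log2(empirical / theoretical variance);
#   a positive median means the counts are over-dispersed relative to the
#   noise model. For gaussian noise the theoretical variance is the pooled
#   mean squared residual over all segments of the same segmentation.
# nid(): normalized information distance between two base-wise peak
#   indicator partitions, 1 - I(A;B)/max(H(A), H(B)), in [0, 1].

#' Per-segment over-dispersion report
#'
#' For each segment of length >= 2 with positive empirical variance,
#' reports the segment mean, the unbiased sample variance of the (Anscombe
#' transformed, for gaussian) values, the noise model's theoretical
#' variance at that mean, and their log2 ratio. Excluded segments are
#' counted, never silently dropped.
#'
#' @param profile The [coverage_profile()] the segmentation was fitted on.
#' @param seg A `segmentation` on that profile.
#' @param noise A [noise_spec()] to diagnose against (defaults to the
#'   segmentation's own noise model).
#' @return Object of class `dispersion_report`: `table` (one row per
#'   eligible segment: `length`, `mu`, `emp_var`, `theo_var`, `log2_ratio`),
#'   `median_log2_ratio`, `n_excluded`.
#' @export
overdispersion_log2 <- function(profile, seg, noise = seg$noise) {
  stopifnot(inherits(profile, "coverage_profile"),
            inherits(seg, "segmentation"))
  y <- profile_expand(profile)
  if (noise$family == "gaussian") {
    y <- if (identical(noise$transform, "identity")) y else anscombe(y)
  }
  bounds <- c(0L, seg$changepoints, seg$n)
  seg_id <- findInterval(seq_along(y) - 1L, bounds[-c(1L, length(bounds))]) + 1L
  lens <- tabulate(seg_id, nbins = seg$K)
  mus <- as.numeric(tapply(y, seg_id, mean))
  evs <- as.numeric(tapply(y, seg_id, stats::var))
  if (noise$family == "gaussian") {
    # pooled MSE across all segments is the constant theoretical variance
    sigma2 <- sum((y - mus[seg_id])^2) / length(y)
    noise <- noise_spec("gaussian", sigma2 = max(sigma2, .Machine$double.eps))
  }
  eligible <- lens >= 2L & !is.na(evs) & evs > 0
  if (!any(eligible)) stop("no segment of length >= 2 with positive variance")
  tv <- theoretical_variance(noise, pmax(mus[eligible], 0))
  tab <- data.frame(length = lens[eligible], mu = mus[eligible],
                    emp_var = evs[eligible], theo_var = tv,
                    log2_ratio = log2(evs[eligible] / tv))
  structure(list(table = tab, median_log2_ratio = stats::median(tab$log2_ratio),
                 n_excluded = sum(!eligible), family = noise$family),
            class = "dispersion_report")
}

#' @export
print.dispersion_report <- function(x, ...) {
  cat(sprintf(
    "dispersion_report (%s): %d segments, median log2(emp/theo var) = %.3f (%d excluded)\n",
    x$family, nrow(x$table), x$median_log2_ratio, x$n_excluded))
  invisible(x)
}

#' Normalized information distance between two peak partitions
#'
#' Treats the two equal-length binary masks as partitions of the bases and
#' computes `1 - I(A;B) / max(H(A), H(B))` from the empirical 2x2 joint
#' distribution. 0 means the partitions carry the same information (a mask
#' and its complement included); 1 means none. When both masks are
#' constant (entropy 0) the distance is 0 for identical masks and 1
#' otherwise, by continuity.
#'
#' @param mask_a,mask_b Binary (0/1 or logical) vectors of equal length.
#' @return A number in `[0, 1]`.
#' @examples
#' nid(c(0, 0, 1, 1), c(1, 1, 0, 0))  # 0: same partition
#' @export
nid <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b)) stop("masks must have equal length")
  if (length(mask_a) < 1L) stop("masks must be non-empty")
  a <- as.integer(as.logical(mask_a)); b <- as.integer(as.logical(mask_b))
  n <- length(a)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(table(a) / n); hb <- ent(table(b) / n)
  hab <- ent(table(a, b) / n)
  mi <- ha + hb - hab
  hmax <- max(ha, hb)
  if (hmax == 0) return(if (all(a == b)) 0 else 1)
  v <- 1 - mi / hmax
  min(max(v, 0), 1)
}

#' Rasterize peaks to a binary base-wise mask
#'
#' @param peaks A [peak_set()].
#' @param region_start,region_end Half-open region covering all peaks.
#' @return Integer 0/1 vector of length `region_end - region_start`.
#' @export
peaks_to_mask <- function(peaks, region_start, region_end) {
  stopifnot(inherits(peaks, "peak_set"), region_start < region_end)
  if (n_peaks(peaks) > 0L &&
      (min(peaks$starts) < region_start || max(peaks$ends) > region_end)) {
    stop("region does not cover all peaks")
  }
  mask <- integer(region_end - region_start)
  for (i in seq_len(n_peaks(peaks))) {
    idx <- (peaks$starts[i] - region_start + 1L):(peaks$ends[i] - region_start)
    mask[idx] <- 1L
  }
  mask
}
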