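# Turning segmentations into peaks.
#
# An unconstrained segmentation can climb into a peak through several
# successive up changes (the Up* block) and descend through several down
# changes (Dw*). A post-processing rule picks one start from each Up* and
# one end from the following Dw*:
#   thinnest: last up change and first down change   [Start2:End1]
#   largest:  first up change and last down change   [Start1:End2]
#   maxjump:  the up and the down change with the largest mean-difference
# Up-Down segmentations need no rule: the Up-state segments are the peaks.

#' Group the changes of an unconstrained segmentation into Up*/Dw* blocks
#'
#' @param seg An unconstrained `segmentation`.
#' @return Object of class `change_blocks`: list of blocks, each with
#'   `direction` (`"Up"` or `"Dw"`), `positions` (genomic changepoint
#'   coordinates) and `jumps` (`theta_after - theta_before`).
#' @export
change_blocks <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  if (seg$model != "unconstrained") {
    stop("change_blocks applies to unconstrained segmentations")
  }
  if (length(seg$changepoints) == 0L) {
    return(structure(list(), class = "change_blocks"))
  }
  jumps <- diff(seg$theta)
  pos <- seg$profile_start + seg$changepoints
  dir <- ifelse(jumps > 0, "Up", "Dw")
  grp <- cumsum(c(TRUE, dir[-1L] != dir[-length(dir)]))
  blocks <- lapply(split(seq_along(jumps), grp), function(i) {
    list(direction = dir[i[1L]], positions = pos[i], jumps = jumps[i])
  })
  names(blocks) <- NULL
  structure(blocks, class = "change_blocks")
}

pick_change <- function(block, rule, first_for) {
  # choose one changepoint from a block under a rule; `first_for` says which
  # end ("start" or "end" of peak) the block provides
  i <- switch(rule,
    thinnest = if (first_for == "start") length(block$positions) else 1L,
    largest = if (first_for == "start") 1L else length(block$positions),
    maxjump = which.max(abs(block$jumps)))  # earliest wins ties
  block$positions[i]
}

#' Extract peaks from a segmentation
#'
#' For unconstrained segmentations, applies one of the three selection
#' rules to each Up*-block/Dw*-block adjacency. A peak needs an Up* block
#' immediately followed by a Dw* block: leading Dw* and trailing Up* blocks
#' form no peak. For Up-Down segmentations the rule is immaterial and the
#' Up-state segments are returned.
#'
#' @param seg A `segmentation`.
#' @param rule `"maxjump"`, `"thinnest"` or `"largest"`.
#' @return A [peak_set()]; height is the maximum `theta` inside each peak.
#' @export
apply_rule <- function(seg, rule = c("maxjump", "thinnest", "largest")) {
  stopifnot(inherits(seg, "segmentation"))
  rule <- match.arg(rule)
  if (seg$model == "updown") {
    up <- which(seg$states == 1L)
    bounds <- c(seg$profile_start, seg$profile_start + seg$changepoints,
                seg$profile_start + seg$n)
    return(peak_set(seg$chrom, bounds[up], bounds[up + 1L], seg$theta[up]))
  }
  blocks <- change_blocks(seg)
  starts <- integer(0); ends <- integer(0); heights <- numeric(0)
  if (length(blocks) >= 2L) {
    seg_bounds <- c(seg$profile_start, seg$profile_start + seg$changepoints,
                    seg$profile_start + seg$n)
    for (i in seq_len(length(blocks) - 1L)) {
      if (blocks[[i]]$direction == "Up" && blocks[[i + 1L]]$direction == "Dw") {
        s <- pick_change(blocks[[i]], rule, "start")
        e <- pick_change(blocks[[i + 1L]], rule, "end")
        starts <- c(starts, s); ends <- c(ends, e)
        inside <- seg_bounds[-length(seg_bounds)] < e & seg_bounds[-1L] > s
        heights <- c(heights, max(seg$theta[inside]))
      }
    }
  }
  peak_set(seg$chrom, starts, ends, heights)
}

#' Number of peaks in a segmentation
#'
#' Up-Down: number of Up-state segments. Unconstrained: number of Up*
#' blocks immediately followed by a Dw* block (the same quantity every
#' selection rule produces peaks for).
#'
#' @param seg A `segmentation`.
#' @return Non-negative integer.
#' @export
count_peaks <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  if (seg$model == "updown") return(sum(seg$states == 1L))
  blocks <- change_blocks(seg)
  if (length(blocks) < 2L) return(0L)
  dirs <- vapply(blocks, `[[`, "", "direction")
  sum(dirs[-length(dirs)] == "Up" & dirs[-1L] == "Dw")
}
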