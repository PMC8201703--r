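# Readers/writers for the plain-text genomic formats the tool touches:
# bedGraph (chrom, start, end, count) for coverage, BED4 for labels and
# peaks. Strict validation: malformed lines, gaps, overlaps and unknown
# label types are located errors, never silent coercions.

read_tsv4 <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("empty %s file: %s", what, path))
  if (any(grepl("^(track|browser)", lines))) {
    stop(sprintf("%s: track/browser lines are not supported; supply plain 4-column data", path))
  }
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1L]
    stop(sprintf("%s line %d: expected 4 tab-separated columns, found %d",
                 path, bad, nf[bad]))
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  for (col in 2:3) {
    v <- suppressWarnings(as.integer(m[, col]))
    if (any(is.na(v))) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("%s line %d: column %d ('%s') is not an integer",
                   path, bad, col, m[bad, col]))
    }
  }
  m
}

#' Read a bedGraph coverage file
#'
#' Reads a 4-column, headerless bedGraph file (chrom, start, end, count)
#' describing one chromosome's coverage. Runs must tile a contiguous
#' interval: gaps and overlaps are errors (use the CLI flag `--fill-gaps`,
#' or [fill_gaps()], to zero-fill gaps explicitly).
#'
#' @param path Path to a bedGraph file.
#' @return A [coverage_profile()].
#' @export
read_bedgraph <- function(path) {
  m <- read_tsv4(path, "bedGraph")
  counts <- suppressWarnings(as.numeric(m[, 4L]))
  if (any(is.na(counts)) || any(counts != floor(counts))) {
    bad <- which(is.na(counts) | counts != floor(counts))[1L]
    stop(sprintf("%s line %d: count '%s' is not an integer", path, bad, m[bad, 4L]))
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0)[1L]
    stop(sprintf("%s line %d: negative count %s", path, bad, m[bad, 4L]))
  }
  chroms <- unique(m[, 1L])
  if (length(chroms) > 1L) {
    stop(sprintf("%s: multiple chromosomes (%s); split the file per chromosome first",
                 path, paste(chroms, collapse = ", ")))
  }
  coverage_profile(chroms, as.integer(m[, 2L]), as.integer(m[, 3L]),
                   as.integer(counts))
}

#' Write a coverage profile as bedGraph
#'
#' @param profile A [coverage_profile()].
#' @param path Output path.
#' @return Invisibly, `path`. `read_bedgraph(write_bedgraph(p))` round-trips.
#' @export
write_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "coverage_profile"))
  writeLines(sprintf("%s\t%d\t%d\t%d", profile$chrom, profile$starts,
                     profile$ends, profile$counts), path)
  invisible(path)
}

#' Read a label BED file
#'
#' 4-column, headerless: chrom, start, end, label type. The four legal types
#' are `noPeaks`, `peaks`, `peakStart` and `peakEnd`.
#'
#' @param path Path to a BED4 label file.
#' @return A [label_set()].
#' @export
read_labels <- function(path) {
  m <- read_tsv4(path, "label")
  chroms <- unique(m[, 1L])
  if (length(chroms) > 1L) {
    stop(sprintf("%s: labels span multiple chromosomes (%s)", path,
                 paste(chroms, collapse = ", ")))
  }
  label_set(chroms, as.integer(m[, 2L]), as.integer(m[, 3L]), m[, 4L])
}

#' Write a label set as BED4
#' @param labels A [label_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_set"))
  writeLines(sprintf("%s\t%d\t%d\t%s", labels$chrom, labels$starts,
                     labels$ends, labels$types), path)
  invisible(path)
}

#' Write predicted peaks as BED4
#'
#' Columns: chrom, start, end, height (segment mean, 6 significant digits).
#' An empty peak set produces an empty file.
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  if (n_peaks(peaks) == 0L) {
    writeLines(character(0), path)
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%.6g", peaks$chrom, peaks$starts,
                       peaks$ends, peaks$heights), path)
  }
  invisible(path)
}

#' Read predicted peaks from BED
#'
#' Accepts BED3 (heights set to NA) or BED4 with a numeric height column.
#'
#' @param path Path to a BED file.
#' @return A [peak_set()].
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(peak_set("chrUnknown"))
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop(sprintf("%s line %d: expected at least 3 columns", path,
                 which(nf < 3L)[1L]))
  }
  chrom <- unique(vapply(parts, `[`, "", 1L))
  if (length(chrom) > 1L) stop(sprintf("%s: multiple chromosomes", path))
  starts <- as.integer(vapply(parts, `[`, "", 2L))
  ends <- as.integer(vapply(parts, `[`, "", 3L))
  heights <- ifelse(nf >= 4L,
                    suppressWarnings(as.numeric(vapply(parts, function(p)
                      if (length(p) >= 4L) p[4L] else NA_character_, ""))),
                    NA_real_)
  peak_set(chrom, starts, ends, heights)
}
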