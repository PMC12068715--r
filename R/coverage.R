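# Binned coverage tracks: the unit of all intensity statistics.

#' Construct a coverage track
#'
#' A coverage track pairs a window grid with per-window read counts and the
#' library size (total mapped reads) used for normalisation. Counts may cover
#' only part of the genome, so `library_size >= sum(counts)` is not required.
#'
#' @param grid window grid (`GRanges`) from [make_windows()].
#' @param counts non-negative numeric vector, one value per window.
#' @param library_size total mapped reads (> 0). Defaults to `sum(counts)`.
#' @param sample,mark,replicate labels carried through reports.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(grid, counts, library_size = sum(counts),
                           sample = "sample", mark = "mark", replicate = 1L) {
  stopifnot(is(grid, "GRanges"), length(counts) == length(grid))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (library_size <= 0) stop("library_size must be > 0")
  structure(list(grid = grid, counts = as.numeric(counts),
                 library_size = as.numeric(library_size),
                 sample = sample, mark = mark, replicate = replicate),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %s / %s (rep %s)\n", x$sample, x$mark,
              x$replicate))
  cat(sprintf("  %d windows, %s total counts, library %s\n",
              length(x$grid), format(sum(x$counts), big.mark = ","),
              format(x$library_size, big.mark = ",")))
  invisible(x)
}

#' Make a coverage track from reads
#'
#' @param reads `GRanges` of reads.
#' @param grid window grid.
#' @inheritParams coverage_track
#' @return a `coverage_track`.
#' @export
coverage_from_reads <- function(reads, grid, library_size = length(reads),
                                sample = "sample", mark = "mark",
                                replicate = 1L) {
  coverage_track(grid, count_in_windows(reads, grid), library_size,
                 sample, mark, replicate)
}

#' Read a coverage track from a bedGraph file
#'
#' The bedGraph intervals must exactly match the supplied grid.
#'
#' @param path bedGraph path.
#' @param grid window grid the track is expected to live on.
#' @param library_size total mapped reads; defaults to the sum of scores.
#' @inheritParams coverage_track
#' @return a `coverage_track`.
#' @export
read_coverage_track <- function(path, grid, library_size = NULL,
                                sample = "sample", mark = "mark",
                                replicate = 1L) {
  bg <- read_bedgraph(path)
  ov <- findOverlaps(grid, bg, type = "equal")
  if (length(ov) != length(grid))
    stop("bedGraph does not match the window grid: ", path)
  counts <- numeric(length(grid))
  counts[queryHits(ov)] <- bg$score[subjectHits(ov)]
  if (is.null(library_size)) library_size <- sum(counts)
  coverage_track(grid, counts, library_size, sample, mark, replicate)
}

#' Write a coverage track to bedGraph
#' @param track a `coverage_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_track <- function(track, path) {
  gr <- track$grid
  mcols(gr) <- NULL
  gr$score <- track$counts
  write_bedgraph(gr, path)
}

same_grid <- function(a, b) {
  length(a$grid) == length(b$grid) &&
    all(as.character(seqnames(a$grid)) == as.character(seqnames(b$grid))) &&
    all(start(a$grid) == start(b$grid)) && all(end(a$grid) == end(b$grid))
}
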