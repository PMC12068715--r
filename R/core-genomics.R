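#' @import methods
#' @importFrom stats p.adjust cor.test wilcox.test fisher.test rnbinom rpois
#'   rbinom runif setNames complete.cases median quantile sd var phyper dhyper
#'   pnorm pf prcomp cor density
#' @importFrom utils read.table write.table modifyList head tail
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   mcols<- strand<- reduce findOverlaps countOverlaps intersect setdiff
#'   union slidingWindows resize shift sort tileGenome
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors queryHits subjectHits DataFrame Rle
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   seqinfo Seqinfo
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   DNAString reverseComplement letterFrequency subseq
NULL

# ---------------------------------------------------------------------------
# Coordinate helpers
# ---------------------------------------------------------------------------

#' Build a genomic interval from megabase coordinates
#'
#' Published centromere coordinates are printed as megabase positions rounded
#' to two decimals (e.g. a domain "between 45.67 and 46.71 Mb"). This helper
#' interprets such a pair as the base-pair interval (start_mb*1e6, end_mb*1e6]
#' so that the interval width equals (end_mb - start_mb) Mb exactly.
#'
#' @param chrom chromosome name.
#' @param start_mb,end_mb interval bounds in Mb, start < end.
#' @return a `GRanges` of length 1.
#' @examples
#' mb_interval("Chr09", 45.67, 46.71)  # width 1.04 Mb
#' @export
mb_interval <- function(chrom, start_mb, end_mb) {
  stopifnot(is.character(chrom), all(start_mb < end_mb))
  GRanges(chrom, IRanges(round(start_mb * 1e6) + 1, round(end_mb * 1e6)))
}

#' Interval width in megabases
#'
#' @param gr a `GRanges`.
#' @return total width of `gr` in Mb.
#' @export
width_mb <- function(gr) sum(as.numeric(width(gr))) / 1e6

# ---------------------------------------------------------------------------
# FASTA
# ---------------------------------------------------------------------------

#' Read a FASTA file
#'
#' Sequences are uppercased and any character outside {A,C,G,T,N} is replaced
#' by N (with a warning). Duplicate record ids are an error.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop("duplicate FASTA record ids: ", paste(dup, collapse = ", "))
  if (any(width(seqs) == 0L)) stop("empty FASTA record in ", path)
  chr <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad)) {
    warning("non-ACGTN characters mapped to N in record(s): ",
            paste(names(seqs)[bad], collapse = ", "))
    chr[bad] <- gsub("[^ACGTN]", "N", chr[bad])
  }
  out <- DNAStringSet(chr)
  names(out) <- names(seqs)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a named `DNAStringSet` (or named character vector).
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# BED / bedGraph (0-based half-open on disk; GRanges in memory)
# ---------------------------------------------------------------------------

#' Read a BED file as GRanges
#' @param path path to a BED3/BED6 file.
#' @return a `GRanges` (with name/score/strand columns when present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  rtracklayer::import(path, format = "BED")
}

#' Write GRanges to BED
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(sort_intervals(gr), path, format = "BED")
  invisible(path)
}

#' Read a 4-column bedGraph as GRanges with a `score` column
#' @param path path to a bedGraph file.
#' @return a `GRanges` with numeric `score`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a scored GRanges to bedGraph
#' @param gr a `GRanges` with a numeric `score` metadata column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(gr, path) {
  stopifnot(!is.null(gr$score))
  rtracklayer::export(sort_intervals(gr), path, format = "bedGraph")
  invisible(path)
}

#' Deterministic interval ordering (chrom lexicographic, then start)
#' @param gr a `GRanges`.
#' @return `gr` reordered.
#' @export
sort_intervals <- function(gr) {
  gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
}

# ---------------------------------------------------------------------------
# Windowing
# ---------------------------------------------------------------------------

#' Tile chromosomes into windows
#'
#' Windows start at the chromosome origin and advance by `step`; the trailing
#' partial window is retained (truncated at the chromosome end), so for
#' `step == width` the windows tile the chromosome exactly and the count per
#' chromosome is `ceiling(length / width)`.
#'
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param width window width in bp.
#' @param step step in bp; defaults to `width` (non-overlapping).
#' @return a `GRanges` window grid carrying `seqlengths`.
#' @export
make_windows <- function(chrom_sizes, width, step = width) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be > 0")
  if (width <= 0 || step <= 0) stop("width and step must be > 0")
  if (step > width) stop("step must be <= width")
  si <- Seqinfo(names(chrom_sizes), as.integer(chrom_sizes))
  full <- GRanges(names(chrom_sizes), IRanges(1L, as.integer(chrom_sizes)),
                  seqinfo = si)
  win <- unlist(slidingWindows(full, width = as.integer(width),
                               step = as.integer(step)))
  names(win) <- NULL
  win
}

#' Assign reads or intervals to windows by midpoint
#'
#' Each input interval contributes one count to the unique window containing
#' its midpoint, avoiding double counting across window boundaries.
#'
#' @param reads a `GRanges` of reads/intervals.
#' @param grid a window grid from [make_windows()].
#' @return integer vector of counts, one per window.
#' @export
count_in_windows <- function(reads, grid) {
  if (length(reads) == 0L) return(integer(length(grid)))
  known <- as.character(seqnames(reads)) %in% seqlevels(grid)
  if (!all(known))
    stop("intervals on unknown chrom: ",
         paste(unique(as.character(seqnames(reads))[!known]), collapse = ", "))
  mid <- (start(reads) + end(reads)) %/% 2L
  mp <- GRanges(seqnames(reads), IRanges(mid, mid))
  countOverlaps(grid, mp)
}

# ---------------------------------------------------------------------------
# Interval algebra (half-open semantics on disk; closed GRanges in memory)
# ---------------------------------------------------------------------------

#' Interval set algebra
#'
#' Thin, named wrappers over the GenomicRanges set operations; outputs are
#' always sorted and disjoint. `interval_merge` joins overlapping or directly
#' adjacent intervals.
#'
#' @param a,b `GRanges` interval sets (ignored strand).
#' @return a sorted, disjoint `GRanges`.
#' @name interval_algebra
NULL

#' @rdname interval_algebra
#' @export
interval_intersect <- function(a, b)
  sort_intervals(GenomicRanges::intersect(unstrand(a), unstrand(b)))

#' @rdname interval_algebra
#' @export
interval_subtract <- function(a, b)
  sort_intervals(GenomicRanges::setdiff(unstrand(a), unstrand(b)))

#' @rdname interval_algebra
#' @export
interval_union <- function(a, b)
  sort_intervals(GenomicRanges::union(unstrand(a), unstrand(b)))

#' @rdname interval_algebra
#' @export
interval_merge <- function(a)
  sort_intervals(reduce(unstrand(a)))

unstrand <- function(gr) {
  strand(gr) <- "*"
  mcols(gr) <- NULL
  names(gr) <- NULL
  gr
}

#' Count hits overlapping features with flanks
#'
#' A hit counts toward a feature when it overlaps the feature extended by
#' `flank` bp on both sides (clipped at the chromosome origin).
#'
#' @param features a `GRanges` of features (e.g. genes); names or a `name`
#'   column are used as feature ids when present.
#' @param hits a `GRanges` of hits (e.g. differential windows).
#' @param flank extension in bp, >= 0.
#' @return a `data.frame` with columns `feature`, `n_hits`, `hit_ids`
#'   (comma-separated indices into `hits`).
#' @export
annotate_overlaps <- function(features, hits, flank = 0L) {
  stopifnot(flank >= 0)
  ids <- feature_ids(features)
  ext <- features
  start(ext) <- pmax(1L, start(ext) - as.integer(flank))
  end(ext) <- end(ext) + as.integer(flank)
  ov <- findOverlaps(ext, hits)
  tab <- tabulate(queryHits(ov), nbins = length(features))
  hid <- vapply(seq_along(features), function(i) {
    paste(subjectHits(ov)[queryHits(ov) == i], collapse = ",")
  }, character(1))
  data.frame(feature = ids, n_hits = tab, hit_ids = hid,
             stringsAsFactors = FALSE)
}

feature_ids <- function(gr) {
  if (!is.null(names(gr)) && all(nzchar(names(gr)))) return(names(gr))
  if (!is.null(gr$name)) return(as.character(gr$name))
  paste0("feature_", seq_along(gr))
}
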