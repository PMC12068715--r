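# CENH3 domain calling, parent/derived comparison, R1/R2 partition.
#
# The functional centromere is operationally the region of CENH3 ChIP
# enrichment: maximal runs of bins whose ChIP/Input fold change exceeds a
# threshold (default 4), merged across small gaps and filtered by width.

#' Per-bin ChIP/Input fold-change track
#'
#' FC_w = ((chip_w + pc) / chip library) / ((input_w + pc) / input library).
#' The pseudocount keeps the ratio finite in zero-count input bins.
#'
#' @param chip,input `coverage_track`s on the same grid.
#' @param pseudocount added to both counts (default 1 read).
#' @return the grid `GRanges` with a numeric `fc` metadata column.
#' @export
compute_bin_enrichment <- function(chip, input, pseudocount = 1) {
  if (!same_grid(chip, input)) stop("chip and input are on different grids")
  fc <- ((chip$counts + pseudocount) / chip$library_size) /
        ((input$counts + pseudocount) / input$library_size)
  fc[chip$counts == 0 & input$counts == 0] <- 1  # no evidence either way
  if (!all(is.finite(fc)))
    stop("zero-count input bins require a positive pseudocount")
  gr <- chip$grid
  mcols(gr) <- NULL
  gr$fc <- fc
  gr
}

#' Call enrichment domains from a fold-change track
#'
#' Domains are maximal runs of bins with `fc > threshold`; runs separated by
#' gaps of at most `merge_gap` bp are merged, and merged domains narrower
#' than `min_width` bp are dropped. Defaults reflect megabase-scale
#' centromeres on a 5-10 kb grid.
#'
#' @param fc_track output of [compute_bin_enrichment()].
#' @param threshold fold-change cutoff (exclusive), default 4.
#' @param min_width minimum domain width in bp.
#' @param merge_gap maximum gap bridged when merging runs, in bp.
#' @param sample label stored on the result.
#' @return a `GRanges` of domains with `mean_fc`, `peak_fc`, `n_bins`,
#'   `sample` metadata columns.
#' @export
call_enrichment_domains <- function(fc_track, threshold = 4,
                                    min_width = 50e3, merge_gap = 100e3,
                                    sample = "sample") {
  stopifnot(threshold > 0)
  hot <- fc_track[fc_track$fc > threshold]
  if (length(hot) == 0L)
    return(GRanges(mean_fc = numeric(), peak_fc = numeric(),
                   n_bins = integer(), sample = character()))
  dom <- reduce(unstrand(hot), min.gapwidth = merge_gap + 1)
  dom <- dom[width(dom) >= min_width]
  if (length(dom) == 0L)
    return(GRanges(mean_fc = numeric(), peak_fc = numeric(),
                   n_bins = integer(), sample = character()))
  ov <- findOverlaps(dom, hot)
  dom$mean_fc <- as.numeric(tapply(hot$fc[subjectHits(ov)], queryHits(ov), mean))
  dom$peak_fc <- as.numeric(tapply(hot$fc[subjectHits(ov)], queryHits(ov), max))
  dom$n_bins <- as.integer(table(factor(queryHits(ov), seq_along(dom))))
  dom$sample <- sample
  sort_intervals(dom)
}

#' Compare a parental and a derived centromere domain
#'
#' Quantifies the size change and on which chromosome-arm side the lost
#' sequence lies. Loss left/right of the derived (retained) domain is mapped
#' to short/long arm by `left_is_short_arm` (whether increasing coordinates
#' run from the short arm through the centromere into the long arm).
#' A direction label is assigned when at least `side_fraction` of the lost
#' bp falls on one side.
#'
#' @param parent,derived length-1 `GRanges` on the same chromosome.
#' @param left_is_short_arm logical orientation flag (see above).
#' @param side_fraction fraction of lost bp on one side required for a
#'   one-sided direction label (default 0.8).
#' @return a list of class `domain_comparison` with fields `size_delta`,
#'   `retained_fraction`, `lost_short_arm`, `lost_long_arm`, `direction`.
#' @export
compare_domains <- function(parent, derived, left_is_short_arm = TRUE,
                            side_fraction = 0.8) {
  stopifnot(length(parent) == 1L, length(derived) == 1L)
  if (as.character(seqnames(parent)) != as.character(seqnames(derived)))
    stop("parent and derived domains are on different chromosomes")
  p <- unstrand(parent); d <- unstrand(derived)
  retained <- GenomicRanges::intersect(p, d)
  ret_bp <- sum(width(retained))
  lost <- GenomicRanges::setdiff(p, d)
  if (ret_bp == 0L) {
    left_bp <- sum(width(lost)); right_bp <- 0L
    direction <- "both"
  } else {
    left_bp <- sum(width(lost)[end(lost) < min(start(retained))])
    right_bp <- sum(width(lost)[start(lost) > max(end(retained))])
    tot <- left_bp + right_bp
    direction <- if (tot == 0) "none"
      else if (left_bp / tot >= side_fraction) "left"
      else if (right_bp / tot >= side_fraction) "right"
      else "both"
  }
  to_arm <- function(side) {
    if (side %in% c("none", "both")) return(side)
    if (xor(side == "left", left_is_short_arm)) "long-arm" else "short-arm"
  }
  short_bp <- if (left_is_short_arm) left_bp else right_bp
  long_bp <- if (left_is_short_arm) right_bp else left_bp
  structure(list(
    parent = p, derived = d,
    size_delta = sum(width(p)) - sum(width(d)),
    retained_fraction = ret_bp / sum(width(p)),
    lost_short_arm = short_bp, lost_long_arm = long_bp,
    direction = to_arm(direction)), class = "domain_comparison")
}

#' @export
print.domain_comparison <- function(x, ...) {
  cat(sprintf("domain comparison: delta %.2f Mb, retained %.2f, loss %s\n",
              x$size_delta / 1e6, x$retained_fraction, x$direction))
  invisible(x)
}

#' Partition a parental centromere into variable (R1) and stable (R2) regions
#'
#' R2 is the part of the parental centromere where CENH3 binding is retained
#' in every derived sample (parent intersected with all derived domains);
#' R1 is the remainder, where binding was lost in at least one derived
#' sample. By construction R1 and R2 are disjoint and their union is the
#' parent domain.
#'
#' @param parent parental centromere (`GRanges`).
#' @param derived_list list of derived-domain `GRanges` (>= 1).
#' @return a list of class `centromere_partition` with `R1`, `R2` (`GRanges`)
#'   and `r1_bp`, `r2_bp` sizes.
#' @export
partition_variable_stable <- function(parent, derived_list) {
  stopifnot(length(derived_list) >= 1L)
  p <- reduce(unstrand(parent))
  r2 <- p
  for (d in derived_list) r2 <- GenomicRanges::intersect(r2, unstrand(d))
  if (sum(width(r2)) == 0L)
    warning("no region retained in all derived samples; R2 is empty")
  r1 <- GenomicRanges::setdiff(p, r2)
  structure(list(R1 = sort_intervals(r1), R2 = sort_intervals(r2),
                 r1_bp = sum(width(r1)), r2_bp = sum(width(r2)),
                 parent = p),
            class = "centromere_partition")
}

#' @export
print.centromere_partition <- function(x, ...) {
  cat(sprintf("centromere partition: R1 %.2f Mb (variable), R2 %.2f Mb (stable)\n",
              x$r1_bp / 1e6, x$r2_bp / 1e6))
  invisible(x)
}
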