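# Non-B-form DNA: motif scanners for seven classes, windowed densities,
# permutation enrichment, and windowed duplex free-energy scores.
#
# Class rules (config-exposed via `params`):
#   APR  >= 3 A-tracts (each a maximal run of 3-9 A's or 3-9 T's, not mixed),
#        adjacent tracts separated by spacers of 4-9 bp
#   DR   unit 10-50 bp repeated >= 2x in tandem, exact match
#   GQ   G{3,}(N{1,7}G{3,}){3,}, both strands
#   IR   arms >= 10 bp reverse-complement of each other, loop <= 100 bp
#   MR   arms >= 10 bp reversed (not complemented), loop <= 100 bp
#   STR  unit 2-9 bp in tandem, span >= 20 bp
#   Z    alternating purine/pyrimidine of GC/CA(TG) steps, >= 12 bp
# Hits are maximal (no reported hit is contained in another of the same
# class); N is excluded from all matches. Homopolymer runs never qualify in
# any class (repeat units and mirror arms must contain >= 2 distinct bases;
# mononucleotide A/T runs are the building blocks of APRs, not motifs in
# themselves), and G-quadruplex G-runs are matched possessively so a run
# cannot be split between a loop and a stem.

nonb_classes <- c("APR", "DR", "GQ", "IR", "MR", "STR", "Z")

default_motif_params <- function(class) {
  switch(class,
    APR = list(tract_min = 3L, tract_max = 9L, spacer_min = 4L,
               spacer_max = 9L, min_tracts = 3L),
    DR  = list(unit_min = 10L, unit_max = 50L),
    GQ  = list(g_run = 3L, loop_max = 7L, n_runs = 4L, both_strands = TRUE),
    IR  = list(arm_min = 10L, arm_max = 100L, loop_max = 100L),
    MR  = list(arm_min = 10L, arm_max = 100L, loop_max = 100L),
    STR = list(unit_min = 2L, unit_max = 9L, span_min = 20L),
    Z   = list(len_min = 12L),
    stop("unknown motif class: ", class))
}

seq_to_string <- function(seq) {
  if (is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    return(list(chrom = names(seq)[1], s = as.character(seq[[1]])))
  }
  if (is(seq, "DNAString")) return(list(chrom = "seq", s = as.character(seq)))
  stopifnot(is.character(seq), length(seq) == 1L)
  list(chrom = if (is.null(names(seq))) "seq" else names(seq),
       s = toupper(seq))
}

hits_granges <- function(chrom, starts, ends, class, strand = "+") {
  if (!length(starts))
    return(GRanges(class = character(), strand_hit = character()))
  gr <- GRanges(chrom, IRanges(starts, ends), class = class,
                strand_hit = strand)
  gr
}

# drop hits contained in another hit of the same set (left-greedy keep)
drop_contained <- function(gr) {
  if (length(gr) < 2L) return(gr)
  gr <- gr[order(start(gr), -end(gr))]
  # after sorting, hit i is contained in an earlier hit iff its end does not
  # exceed the running maximum end (earlier hits start at or before it)
  ends <- end(gr)
  maxend <- cummax(c(0L, ends[-length(ends)]))
  gr[ends > maxend]
}

comp_chars <- function(x) chartr("ACGTN", "TGCAN", x)

# ---------------------------------------------------------------------------
# per-class scanners
# ---------------------------------------------------------------------------

scan_apr <- function(chrom, s, p) {
  r <- rle(strsplit(s, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tract <- (r$values %in% c("A", "T")) &
    r$lengths >= p$tract_min & r$lengths <= p$tract_max
  ts <- starts[tract]; te <- ends[tract]
  if (length(ts) < p$min_tracts) return(hits_granges(chrom, integer(), integer(), "APR"))
  gap <- ts[-1] - te[-length(te)] - 1L
  linked <- gap >= p$spacer_min & gap <= p$spacer_max
  # maximal runs of linked tracts
  hs <- he <- integer()
  i <- 1L
  while (i <= length(ts)) {
    j <- i
    while (j < length(ts) && linked[j]) j <- j + 1L
    if (j - i + 1L >= p$min_tracts) {
      hs <- c(hs, ts[i]); he <- c(he, te[j])
    }
    i <- j + 1L
  }
  hits_granges(chrom, hs, he, "APR")
}

# maximal periodic regions for a set of unit lengths; used by DR and STR.
# For unit u, a region [a, b] with b - a + 1 >= 2u where s has period u.
# Homopolymeric regions (a single repeated base) never qualify.
periodic_regions <- function(chars, units, min_span) {
  n <- length(chars)
  out <- list()
  isn <- chars == "N"
  for (u in units) {
    if (n < 2 * u) next
    eq <- chars[seq_len(n - u)] == chars[seq_len(n - u) + u]
    eq[isn[seq_len(n - u)] | isn[seq_len(n - u) + u]] <- FALSE
    r <- rle(eq)
    ce <- cumsum(r$lengths)
    cs <- ce - r$lengths + 1L
    run <- r$values & r$lengths >= u
    span <- r$lengths[run] + u
    a <- cs[run]; b <- ce[run] + u
    keepu <- span >= max(min_span, 2L * u)
    if (any(keepu)) {
      a <- a[keepu]; b <- b[keepu]
      poly <- vapply(seq_along(a), function(i)
        length(unique(chars[a[i]:b[i]])) < 2L, logical(1))
      if (any(!poly))
        out[[length(out) + 1L]] <- cbind(a[!poly], b[!poly])
    }
  }
  if (!length(out)) return(cbind(integer(), integer()))
  do.call(rbind, out)
}

scan_dr <- function(chrom, s, p) {
  chars <- strsplit(s, "")[[1]]
  reg <- periodic_regions(chars, p$unit_min:p$unit_max, 2L * p$unit_min)
  drop_contained(hits_granges(chrom, reg[, 1], reg[, 2], "DR"))
}

scan_str <- function(chrom, s, p) {
  chars <- strsplit(s, "")[[1]]
  reg <- periodic_regions(chars, p$unit_min:p$unit_max, p$span_min)
  if (!nrow(reg)) return(hits_granges(chrom, integer(), integer(), "STR"))
  drop_contained(hits_granges(chrom, reg[, 1], reg[, 2], "STR"))
}

scan_gq_strand <- function(chrom, s, p, pattern_char, strand) {
  # possessive run quantifiers: a maximal G-run cannot be split between a
  # loop and a stem by backtracking (so e.g. poly-G/poly-C never matches)
  pat <- sprintf("%s{%d,}+(?:[ACGT]{1,%d}?%s{%d,}+){%d,}",
                 pattern_char, p$g_run, p$loop_max, pattern_char, p$g_run,
                 p$n_runs - 1L)
  hs <- he <- integer()
  from <- 1L
  n <- nchar(s)
  while (from <= n) {
    m <- regexpr(pat, substring(s, from), perl = TRUE)
    if (m == -1L) break
    a <- from + as.integer(m) - 1L
    b <- a + attr(m, "match.length") - 1L
    hs <- c(hs, a); he <- c(he, b)
    from <- a + 1L  # allow overlapping maximal hits
  }
  drop_contained(hits_granges(chrom, hs, he, "GQ", strand))
}

scan_gq <- function(chrom, s, p) {
  plus <- scan_gq_strand(chrom, s, p, "G", "+")
  if (!isTRUE(p$both_strands)) return(plus)
  minus <- scan_gq_strand(chrom, s, p, "C", "-")
  drop_contained(c(plus, minus))
}

# IR / MR: seed outer k-mers, extend arms inward.
# pair rule: IR needs s[i + t] == comp(s[e - t]); MR needs s[i + t] == s[e - t].
scan_armed <- function(chrom, s, p, class) {
  k <- min(10L, p$arm_min)
  n <- nchar(s)
  if (n < 2L * p$arm_min) return(hits_granges(chrom, integer(), integer(), class))
  chars <- strsplit(s, "")[[1]]
  target <- if (class == "IR") comp_chars(chars) else chars
  starts <- seq_len(n - k + 1L)
  km <- substring(s, starts, starts + k - 1L)
  pos_by_kmer <- list2env(split(starts, km), hash = TRUE)
  # partner key of position i = reverse((complemented) k-mer at i), computed
  # in bulk from the reversed (complemented) sequence
  tr <- paste(rev(target), collapse = "")
  keys <- substring(tr, n - starts - k + 2L, n - starts + 1L)
  max_span <- 2L * p$arm_max + p$loop_max
  hs <- he <- integer()
  for (i in seq_len(n - 2L * p$arm_min + 1L)) {
    if (grepl("N", keys[i], fixed = TRUE)) next
    cand <- get0(keys[i], envir = pos_by_kmer, inherits = FALSE)
    if (is.null(cand)) next
    # candidate arm2 outer k-mer starts at j; outer end e = j + k - 1
    e <- cand + k - 1L
    e <- e[e >= i + 2L * p$arm_min - 1L & e <= i + max_span - 1L]
    for (ee in e) {
      span <- ee - i + 1L
      amax <- min(p$arm_max, span %/% 2L)
      a <- 0L
      while (a < amax && chars[i + a] != "N" &&
             chars[i + a] == target[ee - a]) a <- a + 1L
      if (a < p$arm_min) next
      loop <- span - 2L * a
      if (loop > p$loop_max) next
      if (length(unique(chars[i:(i + a - 1L)])) < 2L) next  # homopolymer arm
      hs <- c(hs, i); he <- c(he, ee)
    }
  }
  drop_contained(hits_granges(chrom, hs, he, class))
}

scan_z <- function(chrom, s, p) {
  n <- nchar(s)
  if (n < p$len_min) return(hits_granges(chrom, integer(), integer(), "Z"))
  chars <- strsplit(s, "")[[1]]
  pair <- paste0(chars[-n], chars[-1])
  ok <- pair %in% c("GC", "CG", "CA", "AC", "GT", "TG")
  r <- rle(ok)
  ce <- cumsum(r$lengths); cs <- ce - r$lengths + 1L
  run <- r$values & (r$lengths + 1L) >= p$len_min
  hits_granges(chrom, cs[run], ce[run] + 1L, "Z")
}

#' Scan a sequence for non-B-form DNA motifs
#'
#' @param seq a length-1 `DNAStringSet`, `DNAString`, or character string.
#' @param class one of `"APR"`, `"DR"`, `"GQ"`, `"IR"`, `"MR"`, `"STR"`,
#'   `"Z"`, or `"all"`.
#' @param params named list overriding the class defaults (see source for
#'   the rule parameters of each class).
#' @return a `GRanges` of maximal hits with `class` and `strand_hit`
#'   metadata columns.
#' @export
scan_motifs <- function(seq, class = "all", params = list()) {
  if (identical(class, "all")) {
    out <- lapply(nonb_classes, function(cl) scan_motifs(seq, cl, params))
    return(sort_intervals(do.call(c, out)))
  }
  class <- match.arg(class, nonb_classes)
  p <- modifyList(default_motif_params(class), params)
  x <- seq_to_string(seq)
  gr <- switch(class,
    APR = scan_apr(x$chrom, x$s, p),
    DR  = scan_dr(x$chrom, x$s, p),
    GQ  = scan_gq(x$chrom, x$s, p),
    IR  = scan_armed(x$chrom, x$s, p, "IR"),
    MR  = scan_armed(x$chrom, x$s, p, "MR"),
    STR = scan_str(x$chrom, x$s, p),
    Z   = scan_z(x$chrom, x$s, p))
  sort_intervals(gr)
}

# ---------------------------------------------------------------------------
# densities and permutation enrichment
# ---------------------------------------------------------------------------

#' Windowed motif density
#'
#' Count density assigns each hit to the window containing its midpoint;
#' coverage is the fraction of window bp covered by (merged) hits.
#'
#' @param hits a `GRanges` of motif hits.
#' @param grid a window grid (e.g. 200-kb windows from [make_windows()]).
#' @return `data.frame` with `window`, `count`, `coverage`.
#' @export
motif_density <- function(hits, grid) {
  count <- count_in_windows(hits, grid)
  merged <- reduce(unstrand(hits))
  cov_bp <- numeric(length(grid))
  ov <- findOverlaps(grid, merged)
  if (length(ov)) {
    w <- width(GenomicRanges::pintersect(grid[queryHits(ov)],
                                         merged[subjectHits(ov)]))
    agg <- tapply(w, queryHits(ov), sum)
    cov_bp[as.integer(names(agg))] <- as.numeric(agg)
  }
  data.frame(window = seq_along(grid), count = count,
             coverage = cov_bp / width(grid))
}

#' Permutation test of centromeric density enrichment
#'
#' Observed statistic is the mean density over centromeric windows; the null
#' draws the same number of windows without replacement from the
#' non-centromeric pool. One-sided p with the add-one correction:
#' p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param densities numeric per-window densities.
#' @param cen_windows integer indices of centromeric windows.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `observed`, `null_mean`, `p_value`.
#' @export
permutation_enrichment <- function(densities, cen_windows, n_perm = 1000L,
                                   seed = 1L) {
  stopifnot(length(cen_windows) >= 1L)
  pool <- setdiff(seq_along(densities), cen_windows)
  if (length(pool) <= length(cen_windows))
    stop("non-centromeric pool must be larger than the centromeric set")
  obs <- mean(densities[cen_windows])
  set.seed(sub_seed(seed, 17L))
  nullv <- vapply(seq_len(n_perm), function(i)
    mean(densities[sample(pool, length(cen_windows))]), numeric(1))
  p <- (1 + sum(nullv >= obs - 1e-12)) / (n_perm + 1)
  list(observed = obs, null_mean = mean(nullv), p_value = p)
}

# ---------------------------------------------------------------------------
# windowed duplex free energy
# ---------------------------------------------------------------------------

# unified nearest-neighbor duplex dG37 (kcal/mol) per dinucleotide stack,
# plus terminal initiation penalties (G/C 0.98, A/T 1.03)
nn_dg37 <- c(AA = -1.00, TT = -1.00, AT = -0.88, TA = -0.58,
             CA = -1.45, TG = -1.45, GT = -1.44, AC = -1.44,
             CT = -1.28, AG = -1.28, GA = -1.30, TC = -1.30,
             CG = -2.17, GC = -2.24, GG = -1.84, CC = -1.84)
nn_init <- c(A = 1.03, T = 1.03, C = 0.98, G = 0.98, N = 0)

nn_duplex_energy <- function(chars) {
  n <- length(chars)
  if (n < 2L) return(0)
  st <- nn_dg37[paste0(chars[-n], chars[-1])]
  sum(st, na.rm = TRUE) + nn_init[chars[1]] + nn_init[chars[n]]
}

# windowed stack sums in O(n) via cumulative sums (N stacks contribute 0)
nn_window_energies <- function(chars, starts, ends) {
  n <- length(chars)
  st <- nn_dg37[paste0(chars[-n], chars[-1])]
  st[is.na(st)] <- 0
  cs <- c(0, cumsum(st))
  # stacks of window [s, e] are positions s..e-1 of st
  cs[ends] - cs[starts] + nn_init[chars[starts]] + nn_init[chars[ends]]
}

#' Windowed DNA stability scores
#'
#' Scores each sliding window (default 300 nt, 150-nt step) with the unified
#' nearest-neighbor duplex free energy (sum of dinucleotide stack
#' free-energy terms plus initiation), in kcal/mol; more negative = more
#' stable. Stacks containing N are skipped. The `"external"` engine reads
#' precomputed scores from a TSV (`chrom`, `start`, `end`, `energy`),
#' allowing drop-in use of a dedicated folding program's output.
#'
#' @param seq a length-1 `DNAStringSet` (or character string).
#' @param width window width in nt.
#' @param step step in nt (<= width).
#' @param engine `"nn-duplex"` (default) or `"external"`.
#' @param external_path TSV path when `engine = "external"`.
#' @return `data.frame` with `chrom`, `start`, `end`, `energy`.
#' @export
window_free_energy <- function(seq, width = 300L, step = 150L,
                               engine = c("nn-duplex", "external"),
                               external_path = NULL) {
  engine <- match.arg(engine)
  if (engine == "external") {
    stopifnot(!is.null(external_path), file.exists(external_path))
    df <- read.table(external_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "end", "energy") %in% names(df)))
    return(df)
  }
  stopifnot(width > 0, step > 0, step <= width)
  x <- seq_to_string(seq)
  n <- nchar(x$s)
  chars <- strsplit(x$s, "")[[1]]
  starts <- seq(1L, max(1L, n - width + 1L), by = step)
  if (max(starts) + width - 1L < n) starts <- c(starts, max(starts) + step)
  ends <- pmin(starts + width - 1L, n)
  energy <- unname(nn_window_energies(chars, starts, ends))
  data.frame(chrom = x$chrom, start = starts, end = ends, energy = energy,
             stringsAsFactors = FALSE)
}

#' Compare windowed stability scores between regions
#'
#' Assigns energy windows to regions by midpoint and reports per-region
#' means/medians plus pairwise two-sided Wilcoxon rank-sum p-values.
#'
#' @param windows output of [window_free_energy()].
#' @param regions named list of `GRanges` (e.g. `list(R1 =, R2 =, noncen =)`).
#' @return list with `summary` (per-region `data.frame`) and `pairwise`
#'   (`data.frame` of region pairs with `p_value`).
#' @export
compare_region_energy <- function(windows, regions) {
  mid <- (windows$start + windows$end) %/% 2L
  mp <- GRanges(windows$chrom, IRanges(mid, mid))
  vals <- lapply(regions, function(r) windows$energy[overlapsAny(mp, r)])
  short <- names(regions)[vapply(vals, length, integer(1)) < 3L]
  if (length(short))
    stop("regions with fewer than 3 windows: ", paste(short, collapse = ", "))
  summ <- data.frame(region = names(regions),
                     n = vapply(vals, length, integer(1)),
                     mean = vapply(vals, mean, numeric(1)),
                     median = vapply(vals, median, numeric(1)))
  prs <- utils::combn(names(regions), 2)
  pw <- data.frame(region_a = prs[1, ], region_b = prs[2, ],
                   p_value = apply(prs, 2, function(ab) {
                     p <- suppressWarnings(wilcox.test(vals[[ab[1]]],
                       vals[[ab[2]]], exact = FALSE))$p.value
                     if (is.nan(p)) 1 else p  # fully tied samples
                   }))
  list(summary = summ, pairwise = pw)
}
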