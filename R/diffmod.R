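# Region- and window-level differential statistics for histone marks and
# chromatin accessibility.

#' Normalized intensity of a region
#'
#' Raw count is the sum over windows whose midpoint lies in the region;
#' normalized intensity is the raw count divided by the library size (total
#' read count), the same normalisation used for all region fold changes.
#'
#' @param track a `coverage_track`.
#' @param region a `GRanges` (one or more intervals).
#' @return a list of class `intensity_record` with `raw`, `library_size`,
#'   `normalized`, `sample`, `mark`.
#' @export
region_intensity <- function(track, region) {
  if (length(region) == 0L) stop("empty region")
  mid <- (start(track$grid) + end(track$grid)) %/% 2L
  mp <- GRanges(seqnames(track$grid), IRanges(mid, mid))
  raw <- sum(track$counts[overlapsAny(mp, region)])
  structure(list(raw = raw, library_size = track$library_size,
                 normalized = raw / track$library_size,
                 sample = track$sample, mark = track$mark),
            class = "intensity_record")
}

# two-sided Fisher exact p for the 2x2 table [[a, la - a], [b, lb - b]],
# computed as the sum of hypergeometric point probabilities <= that of the
# observed table
fisher_2x2_p <- function(a, b, la, lb) {
  k <- a + b
  lo <- max(0, k - lb)
  hi <- min(k, la)
  x <- lo:hi
  d <- dhyper(x, la, lb, k)
  sum(d[d <= d[a - lo + 1] * (1 + 1e-7)])
}

#' Region fold change with Fisher's exact test
#'
#' Fold change of library-normalized intensities (a over b); significance
#' from the two-sided Fisher exact test on the 2x2 table of in-region versus
#' out-of-region read counts.
#'
#' @param a,b `intensity_record`s (see [region_intensity()]).
#' @param pseudocount added to a zero raw count before forming the ratio.
#' @return list with `fold_change` and `p_value`.
#' @export
region_fold_change_test <- function(a, b, pseudocount = 0.5) {
  stopifnot(a$library_size > 0, b$library_size > 0)
  ra <- if (a$raw == 0 || b$raw == 0) a$raw + pseudocount else a$raw
  rb <- if (a$raw == 0 || b$raw == 0) b$raw + pseudocount else b$raw
  fc <- (ra / a$library_size) / (rb / b$library_size)
  p <- fisher_2x2_p(a$raw, b$raw, a$library_size, b$library_size)
  list(fold_change = fc, p_value = min(1, p))
}

# method-of-moments common dispersion across replicate tracks (counts are
# rescaled to a common library before computing per-window moments).
# Ratio-of-means estimator: with E[s^2] = mu + phi mu^2 and
# E[mbar^2 - s^2/n] = mu^2, phi = sum(s^2 - mbar) / sum(mbar^2 - s^2/n)
# is unbiased at the ratio level, unlike the mean of per-window ratios
# (whose 1/mbar^2 plug-in is biased at few replicates).
estimate_dispersion <- function(track_groups) {
  num <- den <- 0
  for (tracks in track_groups) {
    n <- length(tracks)
    if (n < 2L) next
    libs <- vapply(tracks, function(t) t$library_size, numeric(1))
    ref <- mean(libs)
    y <- vapply(tracks, function(t) t$counts * (ref / t$library_size),
                numeric(length(tracks[[1]]$counts)))
    mu <- rowMeans(y)
    v <- apply(y, 1, var)
    ok <- mu > 1
    num <- num + sum(v[ok] - mu[ok])
    den <- den + sum(mu[ok]^2 - v[ok] / n)
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

#' Call differential modification windows (DMWs)
#'
#' Per-window test of derived versus parent counts. With replicates the
#' default (`"nb"`) refers the ratio of normalized replicate-mean counts to
#' an F distribution obtained from a Gamma approximation of the
#' negative-binomial means, using a method-of-moments common dispersion
#' estimated across replicates (the mean of `R` NB counts with mean `mu`
#' and dispersion `phi` is well approximated by a Gamma with shape
#' `R mu / (1 + phi mu)`, so the null ratio is F-distributed — this keeps
#' far-tail p-values calibrated where a normal approximation is not).
#' `method = "fisher"` pools replicate counts and applies the exact
#' hypergeometric test (appropriate when counts are Poisson).
#' P-values are BH-adjusted across all windows of the contrast and a window
#' is called iff its fold change exceeds `fc_threshold` (in either
#' direction) and its adjusted p-value is below `alpha`.
#'
#' Normalization: `"median-ratio"` (default) rescales each track by the
#' median ratio to a per-window geometric-mean reference, which is robust
#' when a sizeable genome fraction is truly elevated; `"library"` divides
#' by total library size.
#'
#' @param parent_tracks,derived_tracks lists of replicate `coverage_track`s
#'   on a shared grid.
#' @param fc_threshold fold-change cutoff (default 1.5, exclusive).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param method "nb" (default with >= 2 replicates), "fisher", or "auto".
#' @param pseudocount added to mean counts before forming fold changes.
#' @param normalization "median-ratio" (default) or "library".
#' @return a list of class `dmw_result`: `windows` (grid `GRanges` with
#'   `log2fc`, `p`, `padj`, `called`, `direction`), `dmws` (called subset),
#'   `dispersion`, `method`.
#' @export
call_dmws <- function(parent_tracks, derived_tracks, fc_threshold = 1.5,
                      alpha = 0.05, method = c("auto", "nb", "fisher"),
                      pseudocount = 0.5,
                      normalization = c("median-ratio", "library")) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  stopifnot(length(parent_tracks) >= 1L, length(derived_tracks) >= 1L)
  for (t in c(parent_tracks, derived_tracks))
    if (!same_grid(t, parent_tracks[[1]])) stop("tracks are on different grids")
  grid <- parent_tracks[[1]]$grid
  nw <- length(grid)
  if (method == "auto")
    method <- if (length(parent_tracks) >= 2L && length(derived_tracks) >= 2L)
      "nb" else "fisher"

  all_tracks <- c(parent_tracks, derived_tracks)
  libs <- vapply(all_tracks, function(t) t$library_size, numeric(1))
  y <- vapply(all_tracks, `[[`, numeric(nw), "counts")
  np <- length(parent_tracks)
  nd <- length(derived_tracks)

  median_ratio_sizes <- function(use) {
    yy <- y[use, , drop = FALSE]
    pos <- rowSums(yy > 0) == ncol(yy)
    if (sum(pos) < 10) return(libs / mean(libs) * mean(libs))
    ref <- exp(rowMeans(log(yy[pos, , drop = FALSE])))
    sizes <- apply(yy[pos, , drop = FALSE] / ref, 2, median)
    sizes / mean(sizes) * mean(libs)  # comparable scale to libraries
  }

  compute_stats <- function(sizes) {
    sp <- sizes[seq_len(np)]
    sd_ <- sizes[np + seq_len(nd)]
    norm_mean <- function(tracks, s) {
      m <- vapply(seq_along(tracks), function(i) tracks[[i]]$counts / s[i],
                  numeric(nw))
      rowMeans(m)
    }
    mp <- norm_mean(parent_tracks, sp)
    md <- norm_mean(derived_tracks, sd_)
    lp <- mean(sp); ld <- mean(sd_)
    fc <- (md + pseudocount / ld) / (mp + pseudocount / lp)
    if (method == "fisher") {
      A <- round(rowSums(y[, np + seq_len(nd), drop = FALSE]))
      B <- round(rowSums(y[, seq_len(np), drop = FALSE]))
      la <- sum(libs[np + seq_len(nd)]); lb <- sum(libs[seq_len(np)])
      p <- vapply(seq_len(nw), function(i) fisher_2x2_p(A[i], B[i], la, lb),
                  numeric(1))
      phi <- 0
    } else {
      phi <- estimate_dispersion(list(parent_tracks, derived_tracks))
      # common rate under H0, on the normalized scale
      mu0 <- (mp * np * lp + md * nd * ld) / (np * lp + nd * ld)
      mu0p <- pmax(mu0 * lp, pseudocount)  # expected counts per condition
      mu0d <- pmax(mu0 * ld, pseudocount)
      kp <- np * mu0p / (1 + phi * mu0p)   # Gamma shape of the replicate mean
      kd <- nd * mu0d / (1 + phi * mu0d)
      pf_lo <- pf(fc, 2 * kd, 2 * kp)
      p <- 2 * pmin(pf_lo, 1 - pf_lo)
    }
    list(fc = fc, p = p, phi = phi)
  }

  if (normalization == "median-ratio") {
    # median-ratio sizes, then recentre the between-condition scale at the
    # mode of the log fold-change distribution: the null windows form the
    # modal peak, so a one-sided block of truly changed windows (unlike
    # with a plain median) cannot shift the normalization
    sizes <- median_ratio_sizes(rep(TRUE, nw))
    st <- compute_stats(sizes)
    lfc <- log(st$fc[is.finite(log(st$fc))])
    if (length(lfc) >= 50) {
      dens <- density(lfc, n = 1024)
      mode_shift <- dens$x[which.max(dens$y)]
      sizes[np + seq_len(nd)] <- sizes[np + seq_len(nd)] * exp(mode_shift)
      st <- compute_stats(sizes)
      # final pass: with the fold changes centred, windows with p > 0.1 are
      # a symmetric sample of the null, so their median ratio is unbiased
      null_win <- st$p > 0.1
      if (sum(null_win) >= max(50, nw / 5))
        st <- compute_stats(median_ratio_sizes(null_win))
    }
  } else {
    st <- compute_stats(libs)
  }
  fc <- st$fc
  p <- st$p
  phi <- st$phi
  log2fc <- log2(fc)
  padj <- p.adjust(pmin(1, p), method = "BH")
  called <- (fc > fc_threshold | fc < 1 / fc_threshold) & padj < alpha
  direction <- ifelse(log2fc > 0, "up", "down")
  win <- grid
  mcols(win) <- DataFrame(log2fc = log2fc, p = pmin(1, p), padj = padj,
                          called = called, direction = direction)
  structure(list(windows = win, dmws = win[called], dispersion = phi,
                 method = method),
            class = "dmw_result")
}

#' @export
print.dmw_result <- function(x, ...) {
  cat(sprintf("dmw_result: %d/%d windows called (%s test, dispersion %.3g)\n",
              length(x$dmws), length(x$windows), x$method, x$dispersion))
  invisible(x)
}

#' Pericentromere intensity profile
#'
#' Normalized intensity in 1-Mb boxes over the flanking regions on each side
#' of a centromere, ordered by signed distance from the centromere edge
#' (negative indices = left/upstream side). Boxes clipped at the chromosome
#' ends are flagged.
#'
#' @param track a `coverage_track`.
#' @param centromere the centromere (`GRanges`, length 1).
#' @param flank flank extent per side in bp (default 5 Mb).
#' @param box box width in bp (default 1 Mb).
#' @return a `data.frame` with `box_index`, `start`, `end`, `intensity`,
#'   `clipped`.
#' @export
pericentromere_profile <- function(track, centromere, flank = 5e6, box = 1e6) {
  stopifnot(length(centromere) == 1L)
  chrom <- as.character(seqnames(centromere))
  chrom_len <- seqlengths(track$grid)[chrom]
  if (is.na(chrom_len)) chrom_len <- max(end(track$grid))
  cs <- start(centromere); ce <- end(centromere)
  nbox <- as.integer(ceiling(flank / box))
  rows <- list()
  for (i in seq_len(nbox)) {
    # left (negative index): box i spans [cs - i*box, cs - (i-1)*box)
    s <- cs - i * box; e <- cs - (i - 1) * box - 1
    clipped <- s < 1
    if (e >= 1) {
      s <- max(1, s)
      rows[[length(rows) + 1L]] <- data.frame(box_index = -i, start = s, end = e,
                                              clipped = clipped)
    }
    # right (positive index)
    s2 <- ce + (i - 1) * box + 1; e2 <- ce + i * box
    clipped2 <- e2 > chrom_len
    if (s2 <= chrom_len) {
      e2 <- min(chrom_len, e2)
      rows[[length(rows) + 1L]] <- data.frame(box_index = i, start = s2, end = e2,
                                              clipped = clipped2)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$box_index), , drop = FALSE]
  df$intensity <- vapply(seq_len(nrow(df)), function(i) {
    region_intensity(track, GRanges(chrom, IRanges(df$start[i], df$end[i])))$normalized
  }, numeric(1))
  rownames(df) <- NULL
  df[, c("box_index", "start", "end", "intensity", "clipped")]
}

#' Arm symmetry test of pericentromeric changes
#'
#' Two-sided Wilcoxon rank-sum test comparing per-window change values
#' (derived minus parent normalized intensity) between the long-arm and
#' short-arm flanks.
#'
#' @param changes_long,changes_short numeric vectors of per-window changes.
#' @return list with `W` and `p_value` (`NA` with a warning when either
#'   side has fewer than 3 windows).
#' @export
arm_symmetry_test <- function(changes_long, changes_short) {
  if (length(changes_long) < 3L || length(changes_short) < 3L) {
    warning("fewer than 3 windows on one side; p unavailable")
    return(list(W = NA_real_, p_value = NA_real_))
  }
  wt <- suppressWarnings(wilcox.test(changes_long, changes_short,
                                     exact = FALSE, correct = TRUE))
  p <- if (is.nan(wt$p.value)) 1 else wt$p.value  # fully tied samples
  list(W = unname(wt$statistic), p_value = p)
}

#' Correlation between accessibility changes and mark changes
#'
#' Pearson correlation of per-window changes (e.g. DNase-seq delta versus a
#' histone-mark delta) over a region's windows.
#'
#' @param delta_accessibility,delta_mark equal-length numeric vectors.
#' @return list with `r`, `p_value`, and `degenerate` flag (zero variance).
#' @export
change_correlation <- function(delta_accessibility, delta_mark) {
  stopifnot(length(delta_accessibility) == length(delta_mark))
  if (length(delta_mark) < 3L) stop("need at least 3 windows")
  if (sd(delta_accessibility) == 0 || sd(delta_mark) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, degenerate = TRUE))
  }
  ct <- cor.test(delta_accessibility, delta_mark, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, degenerate = FALSE)
}
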