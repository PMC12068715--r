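# Hi-C: contact-matrix container, balancing, comparative maps, A/B
# compartments (PC1 of the O/E correlation matrix) and insulation-score TADs.

#' Construct a contact matrix
#'
#' @param counts square symmetric numeric matrix of contact counts.
#' @param resolution bin size in bp.
#' @param chrom segment name.
#' @param start_bp genomic start of bin 1 (0-based offset of the segment).
#' @param balancing one of "raw", "depth-normalized", "KR-balanced".
#' @param masked integer indices of masked bins.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, resolution, chrom = "seg", start_bp = 0,
                           balancing = "raw", masked = integer()) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts))
  if (any(counts < 0)) stop("contact counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8)
    stop("contact matrix is not symmetric")
  counts <- (counts + t(counts)) / 2
  structure(list(counts = counts, resolution = resolution, chrom = chrom,
                 start_bp = start_bp, balancing = balancing,
                 masked = as.integer(masked)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins @ %s bp (%s), %d masked\n",
              nrow(x$counts), format(x$resolution, big.mark = ","),
              x$balancing, length(x$masked)))
  invisible(x)
}

#' Read a contact matrix from triplet TSV (bin_i, bin_j, count)
#' @param path TSV path with header `bin_i`, `bin_j`, `count` (1-based bins).
#' @param n_bins matrix dimension; default inferred from the largest index.
#' @inheritParams contact_matrix
#' @return a `contact_matrix`.
#' @export
read_contact_matrix <- function(path, resolution, n_bins = NULL,
                                chrom = "seg", start_bp = 0) {
  df <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("bin_i", "bin_j", "count") %in% names(df)))
  if (is.null(n_bins)) n_bins <- max(df$bin_i, df$bin_j)
  m <- matrix(0, n_bins, n_bins)
  m[cbind(df$bin_i, df$bin_j)] <- df$count
  m[cbind(df$bin_j, df$bin_i)] <- df$count
  contact_matrix(m, resolution, chrom, start_bp)
}

#' Write a contact matrix as triplet TSV (upper triangle, non-zero)
#' @param m a `contact_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path) {
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  df <- data.frame(bin_i = idx[, 1], bin_j = idx[, 2],
                   count = m$counts[idx])
  df <- df[order(df$bin_i, df$bin_j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Balance a contact matrix
#'
#' `method = "depth"` divides by total contacts and multiplies by 1e6
#' (contacts per million). `method = "KR"` computes the Knight-Ruiz
#' symmetric scaling D M D whose unmasked row sums are equal (coefficient
#' of variation below `tol`), via the fixed-point iteration
#' x <- x * sqrt(mean(r) / r), r = x * (M x). Bins with zero marginals are
#' masked first.
#'
#' @param m a `contact_matrix`.
#' @param method "KR" or "depth".
#' @param tol convergence tolerance on the row-sum coefficient of variation.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return a balanced `contact_matrix`.
#' @export
balance_matrix <- function(m, method = c("KR", "depth"), tol = 1e-6,
                           max_iter = 3000L) {
  method <- match.arg(method)
  if (method == "depth") {
    out <- m
    out$counts <- m$counts / sum(m$counts) * 1e6
    out$balancing <- "depth-normalized"
    return(out)
  }
  if (m$balancing == "KR-balanced") stop("matrix is already KR-balanced")
  marg <- rowSums(m$counts)
  masked <- union(m$masked, which(marg == 0))
  keep <- setdiff(seq_len(nrow(m$counts)), masked)
  M <- m$counts[keep, keep, drop = FALSE]
  x <- rep(1, length(keep))
  cv <- Inf
  for (it in seq_len(max_iter)) {
    r <- x * as.vector(M %*% x)
    cv <- sd(r) / mean(r)
    if (is.na(cv) || cv < tol) break
    x <- x * sqrt(mean(r) / r)
  }
  if (is.na(cv) || cv >= tol)
    stop(sprintf("KR balancing did not converge: CV %.3g after %d iterations",
                 cv, max_iter))
  B <- M * outer(x, x)
  B <- B / mean(rowSums(B))  # unit row sums on unmasked bins
  out <- m
  out$counts[] <- 0
  out$counts[keep, keep] <- B
  out$balancing <- "KR-balanced"
  out$masked <- sort(masked)
  out
}

#' Log2 difference map between two contact matrices
#'
#' @param a,b `contact_matrix` objects on the same segment and resolution
#'   (both balanced the same way).
#' @param pseudocount added to both matrices before the ratio.
#' @return signed matrix log2((a + pc) / (b + pc)); antisymmetric under
#'   operand swap.
#' @export
difference_map <- function(a, b, pseudocount = 1e-6) {
  if (!all(dim(a$counts) == dim(b$counts)))
    stop("matrix dimensions differ")
  if (a$resolution != b$resolution) stop("resolutions differ")
  log2((a$counts + pseudocount) / (b$counts + pseudocount))
}

# observed/expected by per-diagonal mean division (unmasked bins only)
obs_over_exp <- function(counts, masked = integer()) {
  n <- nrow(counts)
  keep <- setdiff(seq_len(n), masked)
  M <- counts[keep, keep, drop = FALSE]
  k <- nrow(M)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  expd <- vapply(0:(k - 1), function(dd) mean(M[d == dd]), numeric(1))
  E <- matrix(expd[d + 1], k, k)
  oe <- M / E
  oe[!is.finite(oe)] <- 0
  list(oe = oe, keep = keep)
}

#' A/B compartments from PC1 of the O/E correlation matrix
#'
#' Observed/expected normalisation by per-diagonal means, Pearson
#' correlation matrix, then the first principal component (leading
#' eigenvector). The sign is oriented so PC1 correlates positively with
#' `orientation_track` (e.g. gene density, so that A = gene-rich); positive
#' PC1 bins are labelled A, negative B.
#'
#' @param m a balanced `contact_matrix` with >= 20 unmasked bins.
#' @param orientation_track per-bin numeric anchor, or `NULL` (sign then
#'   fixed by making the largest-magnitude loading positive).
#' @return a list of class `compartment_track`: `pc1` (NA at masked bins),
#'   `labels` ("A"/"B"/NA), `var_explained`, `resolution`, `start_bp`,
#'   `chrom`, `masked`.
#' @export
compartment_pc1 <- function(m, orientation_track = NULL) {
  marg <- rowSums(m$counts)
  masked <- union(m$masked, which(marg == 0))
  n <- nrow(m$counts)
  if (n - length(masked) < 20) stop("need >= 20 unmasked bins")
  ooe <- obs_over_exp(m$counts, masked)
  cc <- suppressWarnings(cor(ooe$oe))
  cc[!is.finite(cc)] <- 0
  eg <- eigen(cc, symmetric = TRUE)
  if (eg$values[1] <= 0) stop("degenerate correlation matrix")
  v <- eg$vectors[, 1]
  pc1 <- rep(NA_real_, n)
  pc1[ooe$keep] <- v
  if (!is.null(orientation_track)) {
    stopifnot(length(orientation_track) == n)
    s <- suppressWarnings(cor(pc1[ooe$keep], orientation_track[ooe$keep]))
    if (!is.na(s) && s < 0) pc1 <- -pc1
  } else if (v[which.max(abs(v))] < 0) {
    pc1 <- -pc1
  }
  labels <- ifelse(is.na(pc1), NA_character_, ifelse(pc1 > 0, "A", "B"))
  structure(list(pc1 = pc1, labels = labels,
                 var_explained = eg$values[1] / sum(pmax(eg$values, 0)),
                 resolution = m$resolution, start_bp = m$start_bp,
                 chrom = m$chrom, masked = sort(masked)),
            class = "compartment_track")
}

bins_in_region <- function(track, region) {
  n <- length(track$pc1)
  mid <- track$start_bp + (seq_len(n) - 0.5) * track$resolution
  which(vapply(mid, function(x)
    any(x >= start(region) & x <= end(region)), logical(1)))
}

#' Ratio of PC1 magnitudes between samples
#'
#' @param mean_self,mean_other mean PC1 values of the same region in two
#'   samples (same sign expected).
#' @return |mean_other| / |mean_self|, rounded to 2 decimals.
#' @export
pc1_magnitude_ratio <- function(mean_self, mean_other) {
  round(abs(mean_other) / abs(mean_self), 2)
}

#' Per-region PC1 statistics for two samples
#'
#' @param track,other `compartment_track`s of the two samples on the same
#'   segment.
#' @param regions named list of `GRanges` regions (genomic coordinates).
#' @return `data.frame` with per-region mean PC1 in each sample, the
#'   magnitude ratio |other|/|self| (2 decimals), and a Wilcoxon p across
#'   bins.
#' @export
region_pc1_stats <- function(track, other, regions) {
  stopifnot(track$resolution == other$resolution)
  rows <- lapply(names(regions), function(nm) {
    idx <- bins_in_region(track, regions[[nm]])
    if (!length(idx)) stop("region maps to no bins: ", nm)
    a <- track$pc1[idx]; b <- other$pc1[idx]
    ok <- !is.na(a) & !is.na(b)
    p <- if (sum(ok) >= 3 && !all(a[ok] == b[ok]))
      suppressWarnings(wilcox.test(a[ok], b[ok], exact = FALSE))$p.value else
      if (all(a[ok] == b[ok])) 1 else NA_real_
    data.frame(region = nm, n_bins = sum(ok),
               mean_pc1_self = mean(a[ok]), mean_pc1_other = mean(b[ok]),
               magnitude_ratio = pc1_magnitude_ratio(mean(a[ok]), mean(b[ok])),
               p_value = p)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# TADs
# ---------------------------------------------------------------------------

#' Call TADs from insulation-score minima
#'
#' Per-bin insulation is the mean of contacts in a `window`-bin square
#' crossing the diagonal, reported as log2 of the ratio to its chromosome
#' mean. Boundaries are local minima whose prominence (flanking maxima
#' minus the minimum) is at least `delta` and whose cross-boundary
#' contacts are depleted relative to within-block contacts by a one-sided
#' rank test on O/E values (BH-adjusted across candidates, cutoff
#' `alpha`). Domains span consecutive boundaries.
#'
#' @param m a balanced `contact_matrix`.
#' @param window insulation window in bins.
#' @param delta minimum prominence of a boundary minimum (log2 units).
#' @param alpha BH-adjusted p cutoff for the boundary rank test.
#' @return a list of class `tad_set`: `boundaries` (bin indices),
#'   `domains` (`data.frame` of bin spans), `insulation`, `resolution`,
#'   `start_bp`, `chrom`, `params`.
#' @export
find_tads <- function(m, window = 10L, delta = 0.1, alpha = 0.01) {
  n <- nrow(m$counts)
  if (n < 2L * window + 1L) stop("matrix smaller than the insulation window")
  ooe <- obs_over_exp(m$counts, m$masked)
  C <- m$counts[ooe$keep, ooe$keep, drop = FALSE]
  k <- nrow(C)
  ins <- rep(NA_real_, k)
  for (i in (window + 1L):(k - window)) {
    ins[i] <- mean(C[(i - window):(i - 1L), (i + 1L):(i + window)])
  }
  ins_norm <- log2(ins / mean(ins, na.rm = TRUE))
  # candidate minima with prominence >= delta
  cand <- integer()
  for (i in which(!is.na(ins_norm))) {
    if (i <= window + 1L || i >= k - window) next
    nb <- ins_norm[c(i - 1L, i + 1L)]
    if (any(is.na(nb)) || any(nb < ins_norm[i])) next
    if (ins_norm[i - 1L] == ins_norm[i] && ins_norm[i + 1L] == ins_norm[i]) next
    left <- ins_norm[max(1L, i - window):(i - 1L)]
    right <- ins_norm[(i + 1L):min(k, i + window)]
    prom <- min(max(left, na.rm = TRUE), max(right, na.rm = TRUE)) - ins_norm[i]
    if (is.finite(prom) && prom >= delta) cand <- c(cand, i)
  }
  # rank test: cross-boundary O/E depleted vs within-block O/E
  keep_cand <- logical(length(cand))
  pvals <- rep(NA_real_, length(cand))
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    li <- (i - window):(i - 1L); ri <- (i + 1L):(i + window)
    cross <- as.vector(ooe$oe[li, ri])
    within <- c(ooe$oe[li, li][upper.tri(diag(length(li)))],
                ooe$oe[ri, ri][upper.tri(diag(length(ri)))])
    pvals[ci] <- suppressWarnings(
      wilcox.test(cross, within, alternative = "less", exact = FALSE))$p.value
  }
  padj <- p.adjust(pvals, "BH")
  bnd_keep <- cand[!is.na(padj) & padj < alpha]
  boundaries <- sort(ooe$keep[bnd_keep])  # back to original bin indexing
  edges <- unique(c(1L, boundaries, n))
  domains <- data.frame(start_bin = head(edges, -1), end_bin = tail(edges, -1))
  insulation <- rep(NA_real_, n)
  insulation[ooe$keep] <- ins_norm
  structure(list(boundaries = boundaries, domains = domains,
                 insulation = insulation, resolution = m$resolution,
                 start_bp = m$start_bp, chrom = m$chrom,
                 params = list(window = window, delta = delta, alpha = alpha)),
            class = "tad_set")
}

#' @export
print.tad_set <- function(x, ...) {
  cat(sprintf("tad_set: %d domains, %d boundaries @ %s bp\n",
              nrow(x$domains), length(x$boundaries),
              format(x$resolution, big.mark = ",")))
  invisible(x)
}

boundary_interval <- function(tads, bin) {
  GRanges(tads$chrom,
          IRanges(tads$start_bp + (bin - 1) * tads$resolution + 1,
                  tads$start_bp + bin * tads$resolution))
}

#' Compare TAD boundaries between two samples
#'
#' Boundaries are matched greedily within `slack` bins; unmatched
#' boundaries of `tads_a` are "lost", of `tads_b` "gained". Gained
#' boundaries are annotated with overlapping features (e.g. DMW
#' intervals).
#'
#' @param tads_a,tads_b `tad_set`s on the same segment/resolution.
#' @param features optional `GRanges` of annotation features.
#' @param slack matching slack in bins.
#' @return list with `shared` (`data.frame` of matched pairs), `lost`,
#'   `gained` (bin indices), and `gained_features` (`data.frame` of gained
#'   boundaries with overlapping-feature counts).
#' @export
compare_boundaries <- function(tads_a, tads_b, features = NULL, slack = 2L) {
  if (tads_a$resolution != tads_b$resolution) stop("resolution mismatch")
  a <- tads_a$boundaries; b <- tads_b$boundaries
  used_b <- logical(length(b))
  pairs <- list()
  for (x in a) {
    d <- abs(b - x)
    d[used_b] <- Inf
    if (length(d) && min(d) <= slack) {
      j <- which.min(d)
      used_b[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(bin_a = x, bin_b = b[j])
    }
  }
  shared <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(bin_a = integer(), bin_b = integer())
  lost <- setdiff(a, shared$bin_a)
  gained <- b[!used_b]
  gf <- data.frame(bin = as.integer(gained),
                   n_features = integer(length(gained)),
                   feature_ids = character(length(gained)))
  if (!is.null(features) && length(gained)) {
    for (i in seq_along(gained)) {
      iv <- boundary_interval(tads_b, gained[i])
      ov <- findOverlaps(iv, features)
      gf$n_features[i] <- length(ov)
      gf$feature_ids[i] <- paste(subjectHits(ov), collapse = ",")
    }
  }
  list(shared = shared, lost = lost, gained = gained, gained_features = gf)
}
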