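suppressPackageStartupMessages(library(GenomicRanges))

# Independent oracles used across the suite. These re-derive expected
# results by a different route than the implementation under test
# (per-base boolean arrays, rule predicates on enumerated substrings,
# alternating Sinkhorn scaling) and are deliberately slow and simple.

random_seq <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# --- per-base interval-set oracle (toy chrom of known length) --------------

bool_mask <- function(gr, chrom, len) {
  m <- rep(FALSE, len)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  for (i in seq_along(gr))
    m[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
  m
}

mask_to_granges <- function(mask, chrom) {
  r <- rle(mask)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s[r$values], e[r$values]))
}

random_interval_set <- function(chrom, len, n) {
  s <- sample.int(len, n, replace = TRUE)
  w <- sample.int(max(2L, len %/% 10L), n, replace = TRUE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, pmin(len, s + w)))
}

# --- motif-rule oracles ----------------------------------------------------

rev_string <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
revcomp_string <- function(x) rev_string(chartr("ACGTN", "TGCAN", x))

is_homopolymer <- function(x) length(unique(strsplit(x, "")[[1]])) < 2L

# tandem repeat of some unit length in `units`, exact, >= 2 copies,
# span >= span_min, non-homopolymeric
is_tandem <- function(x, units, span_min) {
  n <- nchar(x)
  if (n < span_min || is_homopolymer(x) || grepl("N", x)) return(FALSE)
  for (u in units) {
    if (n < 2 * u) next
    if (substr(x, 1L, n - u) == substr(x, u + 1L, n)) return(TRUE)
  }
  FALSE
}

# armed structure: exists arm length a >= arm_min with loop = n - 2a in
# [0, loop_max], arms related by `pair` ("revcomp" or "reverse"),
# non-homopolymeric arm
is_armed <- function(x, arm_min, loop_max, pair, arm_max = Inf) {
  n <- nchar(x)
  if (n < 2 * arm_min || grepl("N", x)) return(FALSE)
  ch <- strsplit(x, "")[[1]]
  target <- if (pair == "revcomp") chartr("ACGTN", "TGCAN", x) else x
  tch <- strsplit(target, "")[[1]]
  amax <- min(n %/% 2L, arm_max)
  a <- 0L
  while (a < amax && ch[a + 1L] == tch[n - a]) a <- a + 1L
  a_needed <- max(arm_min, ceiling((n - loop_max) / 2))
  a >= a_needed && !is_homopolymer(substr(x, 1L, a))
}

is_z <- function(x, len_min = 12L) {
  n <- nchar(x)
  if (n < len_min) return(FALSE)
  ch <- strsplit(x, "")[[1]]
  all(paste0(ch[-n], ch[-1]) %in% c("GC", "CG", "CA", "AC", "GT", "TG"))
}

# chain-of-runs oracles for APR and GQ operate on the full sequence
# (tract/stem maximality depends on context)
oracle_chain_coverage <- function(s, run_regex, run_ok, gap_range, min_runs) {
  n <- nchar(s)
  cov <- rep(FALSE, n)
  m <- gregexpr(run_regex, s)[[1]]
  if (m[1] == -1L) return(cov)
  rs <- as.integer(m)
  re <- rs + attr(m, "match.length") - 1L
  ok <- vapply(seq_along(rs), function(i) run_ok(re[i] - rs[i] + 1L), logical(1))
  rs <- rs[ok]; re <- re[ok]
  if (length(rs) < min_runs) return(cov)
  gap <- rs[-1] - re[-length(re)] - 1L
  linked <- gap >= gap_range[1] & gap <= gap_range[2]
  i <- 1L
  while (i <= length(rs)) {
    j <- i
    while (j < length(rs) && linked[j]) j <- j + 1L
    if (j - i + 1L >= min_runs) cov[rs[i]:re[j]] <- TRUE
    i <- j + 1L
  }
  cov
}

oracle_coverage <- function(s, class, max_span = 150L) {
  n <- nchar(s)
  if (class == "APR") {
    return(oracle_chain_coverage(s, "A+|T+",
                                 function(l) l >= 3L && l <= 9L,
                                 c(4L, 9L), 3L))
  }
  if (class == "GQ") {
    plus <- oracle_chain_coverage(s, "G+", function(l) l >= 3L, c(1L, 7L), 4L)
    minus <- oracle_chain_coverage(s, "C+", function(l) l >= 3L, c(1L, 7L), 4L)
    return(plus | minus)
  }
  pred <- switch(class,
    DR  = function(x) is_tandem(x, 10:50, 20L),
    STR = function(x) is_tandem(x, 2:9, 20L),
    IR  = function(x) is_armed(x, 10L, 100L, "revcomp"),
    MR  = function(x) is_armed(x, 10L, 100L, "reverse"),
    Z   = function(x) is_z(x))
  cov <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in i:min(n, i + max_span - 1L)) {
      if (pred(substr(s, i, j))) cov[i:j] <- TRUE
    }
  }
  cov
}

scanner_coverage <- function(s, class, n) {
  hits <- scan_motifs(s, class)
  cov <- rep(FALSE, n)
  for (i in seq_along(hits))
    cov[GenomicRanges::start(hits)[i]:GenomicRanges::end(hits)[i]] <- TRUE
  cov
}

# alphabets that make chance hits likely for each class
oracle_alphabet <- function(class) {
  switch(class,
    APR = c(A = 0.35, C = 0.1, G = 0.1, T = 0.35, N = 0.1),
    GQ  = c(A = 0.1, C = 0.3, G = 0.4, T = 0.2),
    DR  = c(A = 0.5, C = 0.5),
    STR = c(A = 0.45, C = 0.45, G = 0.1),
    IR  = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4),
    MR  = c(A = 0.45, C = 0.1, G = 0.05, T = 0.4),
    Z   = c(A = 0.2, C = 0.35, G = 0.35, T = 0.1))
}

# --- Sinkhorn oracle for KR balancing --------------------------------------

sinkhorn_balance <- function(M, tol = 1e-10, max_iter = 1e5) {
  A <- M
  for (i in seq_len(max_iter)) {
    A <- A / rowSums(A)
    A <- t(t(A) / colSums(A))
    if (max(abs(rowSums(A) - 1)) < tol) break
  }
  A <- (A + t(A)) / 2
  A / mean(rowSums(A))
}
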