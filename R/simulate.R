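# Synthetic data with planted ground truth.
#
# Every downstream stage is validated by parameter recovery on data from
# these generators: genomes with planted non-B motifs, paired ChIP/Input
# count tracks with a planted CENH3 domain (and a contracted version in a
# derived sample), histone-mark tracks with region-specific elevation that
# decays into the pericentromere, and Hi-C matrices with planted
# compartments and TAD boundaries.

#' Truth set constructor
#'
#' Records everything a simulation planted so recovery can be scored.
#' Enforces the partition invariant: R1 and R2 are disjoint and their union
#' is the parental centromere.
#'
#' @param centromere parental centromere (`GRanges`), or `NULL`.
#' @param derived_centromere derived-sample centromere, or `NULL`.
#' @param R1,R2 variable/stable intervals (`GRanges`), or `NULL`.
#' @param elevation per-mark multipliers, or `NULL`.
#' @param decay_scale pericentromere decay scale (bp), or `NULL`.
#' @param motifs `GRanges` of planted motif spans with a `class` column.
#' @param compartments per-bin A/B labels, or `NULL`.
#' @param tad_boundaries planted boundary bin indices, or `NULL`.
#' @param seed RNG seed used.
#' @return an object of class `truth_set`.
#' @export
truth_set <- function(centromere = NULL, derived_centromere = NULL,
                      R1 = NULL, R2 = NULL, elevation = NULL,
                      decay_scale = NULL, motifs = NULL,
                      compartments = NULL, tad_boundaries = NULL,
                      seed = NA_integer_) {
  if (!is.null(R1) && !is.null(R2) && !is.null(centromere)) {
    if (sum(width(GenomicRanges::intersect(R1, R2))) != 0)
      stop("R1 and R2 overlap")
    u <- GenomicRanges::union(R1, R2)
    if (sum(width(GenomicRanges::setdiff(u, centromere))) != 0 ||
        sum(width(GenomicRanges::setdiff(centromere, u))) != 0)
      stop("R1 and R2 do not partition the parental centromere")
  }
  if (!is.null(elevation)) {
    mm <- unlist(elevation)
    if (any(mm <= 0)) stop("elevation multipliers must be > 0")
  }
  structure(list(centromere = centromere,
                 derived_centromere = derived_centromere,
                 R1 = R1, R2 = R2, elevation = elevation,
                 decay_scale = decay_scale, motifs = motifs,
                 compartments = compartments,
                 tad_boundaries = tad_boundaries, seed = seed),
            class = "truth_set")
}

#' Simulation configuration
#'
#' @param chrom chromosome name of the simulated segment.
#' @param chrom_len segment length in bp.
#' @param bin_width track bin width in bp.
#' @param enrich_fold CENH3 ChIP enrichment fold inside the centromere.
#' @param background expected Input reads per bin.
#' @param dispersion negative-binomial overdispersion (0 = Poisson).
#' @param replicates biological replicates per sample/mark.
#' @param seed global RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(chrom = "chrSim", chrom_len = 10e6, bin_width = 10e3,
                       enrich_fold = 10, background = 50, dispersion = 0.05,
                       replicates = 2L, seed = 1L) {
  stopifnot(chrom_len > 0, bin_width > 0, enrich_fold > 0, background > 0,
            dispersion >= 0, replicates >= 1)
  structure(list(chrom = chrom, chrom_len = chrom_len, bin_width = bin_width,
                 enrich_fold = enrich_fold, background = background,
                 dispersion = dispersion, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# independent, reproducible sub-streams per (seed, index)
sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)

rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
}

# ---------------------------------------------------------------------------
# Genome simulation
# ---------------------------------------------------------------------------

# canonical planted instances per motif class (each satisfies the scanner
# rule for its class by construction)
motif_unit <- function(class) {
  switch(class,
    APR = "AAAAACGTCGAAAAACGTCGAAAAACGTCGAAAAA",
    GQ  = "GGGTTAGGGTTAGGGTTAGGG",
    Z   = "GCGCGCGCGCGCGC",
    STR = "CAGCAGCAGCAGCAGCAGCAGCAG",
    DR  = "ACGGTCAGTCATACGGTCAGTCAT",
    IR  = paste0("ACGGTCAGCTACGT", "CCGGT", "ACGTAGCTGACCGT"),
    MR  = paste0("ACGGTCAGCTACGT", "CCGGT", "TGCATCGACTGGCA"),
    stop("unknown motif class: ", class))
}

#' Simulate a genome segment with planted non-B motifs
#'
#' Background sequence is i.i.d. with the requested GC content; planted
#' motif instances are written verbatim at the requested loci and recorded
#' in the truth set. A planting is a list `(class, at, n)`: `n` copies of
#' the canonical instance of `class` written head-to-tail starting at
#' position `at` (1-based), separated by 10 bp of background.
#'
#' @param length segment length in bp.
#' @param gc GC fraction in (0, 1).
#' @param plantings list of plantings (see above); may be empty.
#' @param seed RNG seed.
#' @param chrom sequence id.
#' @return list with `seq` (named `DNAStringSet` of length 1) and `truth`
#'   (a [truth_set()] with planted motif spans).
#' @export
simulate_genome <- function(length, gc = 0.35, plantings = list(), seed = 1L,
                            chrom = "chrSim") {
  stopifnot(length > 0, gc > 0, gc < 1)
  set.seed(sub_seed(seed, 1L))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- sample(names(p), length, replace = TRUE, prob = p)
  spans <- GRanges()
  for (pl in plantings) {
    unit <- motif_unit(pl$class)
    n <- if (is.null(pl$n)) 1L else pl$n
    at <- pl$at
    for (k in seq_len(n)) {
      u <- strsplit(unit, "")[[1]]
      if (at + base::length(u) - 1L > length)
        stop("planting extends beyond the segment end")
      span <- GRanges(chrom, IRanges(at, at + base::length(u) - 1L),
                      class = pl$class)
      if (base::length(spans) && any(overlapsAny(span, spans)))
        stop("overlapping plantings")
      s[at:(at + base::length(u) - 1L)] <- u
      spans <- c(spans, span)
      at <- at + base::length(u) + 10L
    }
  }
  seq <- DNAStringSet(paste(s, collapse = ""))
  names(seq) <- chrom
  list(seq = seq, truth = truth_set(motifs = sort_intervals(spans), seed = seed))
}

# ---------------------------------------------------------------------------
# ChIP/Input track simulation
# ---------------------------------------------------------------------------

bin_multiplier <- function(grid, region, mult) {
  # per-bin multiplier: `mult` weighted by the fraction of the bin inside region
  if (is.null(region) || length(region) == 0L) return(rep(1, length(grid)))
  ov <- findOverlaps(grid, region)
  frac <- numeric(length(grid))
  if (length(ov)) {
    w <- width(GenomicRanges::pintersect(grid[queryHits(ov)], region[subjectHits(ov)]))
    frac_ov <- w / width(grid[queryHits(ov)])
    agg <- tapply(frac_ov, queryHits(ov), sum)
    frac[as.integer(names(agg))] <- pmin(1, as.numeric(agg))
  }
  1 + (mult - 1) * frac
}

#' Simulate a paired ChIP/Input experiment
#'
#' Input counts are negative-binomial around the background rate; ChIP
#' counts multiply the expected rate by `config$enrich_fold` inside the
#' truth centromere. Replicates share the truth but draw independent noise
#' from derived sub-seeds. Library sizes are the realised totals.
#'
#' @param truth a [truth_set()] whose `centromere` is the planted domain
#'   (may be `NULL` for a null experiment).
#' @param config a [sim_config()].
#' @param sample sample label.
#' @param mark mark label (default "CENH3").
#' @return list with elements `chip` and `input`, each a list of
#'   `coverage_track`s (one per replicate), plus `grid`.
#' @export
simulate_chip_experiment <- function(truth, config, sample = "parent",
                                     mark = "CENH3") {
  grid <- make_windows(setNames(config$chrom_len, config$chrom),
                       config$bin_width)
  mult <- bin_multiplier(grid, truth$centromere, config$enrich_fold)
  chip <- input <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    set.seed(sub_seed(config$seed, 100L + r))
    ic <- rcounts(length(grid), config$background, config$dispersion)
    cc <- rcounts(length(grid), config$background * mult, config$dispersion)
    input[[r]] <- coverage_track(grid, ic, sum(ic), sample, paste0(mark, "-input"), r)
    chip[[r]] <- coverage_track(grid, cc, sum(cc), sample, mark, r)
  }
  list(chip = chip, input = input, grid = grid)
}

#' Simulate a centromere-contraction system with mark elevation
#'
#' Generates, for a "parent" and a "derived" sample: CENH3 ChIP/Input pairs
#' (the derived sample loses enrichment over `loss`), and per-mark count
#' tracks where the derived sample is elevated by the R1 multiplier over the
#' lost region, the R2 multiplier over the retained region, and by a
#' multiplier decaying exponentially with distance from the centromere edge
#' over the flanking `flank` bp.
#'
#' @param centromere parental centromere (`GRanges`, length 1).
#' @param loss intervals of CENH3 loss in the derived sample (subset of the
#'   centromere).
#' @param elevation named list per mark, each `list(r1 =, r2 =)` with
#'   `r1 >= r2 >= 1`; optional `flank` edge multiplier (default `r2`).
#' @param decay_scale exponential decay scale of the flank elevation, bp.
#' @param config a [sim_config()].
#' @param flank pericentromere extent in bp (default 5 Mb).
#' @return list with `cenh3` (parent/derived chip+input), `marks`
#'   (`marks[[sample]][[mark]]` = list of replicate tracks), `grid`, and
#'   `truth`.
#' @export
simulate_contraction_system <- function(centromere, loss, elevation,
                                        decay_scale = 1e6, config = sim_config(),
                                        flank = 5e6) {
  loss <- reduce(unstrand(loss))
  cen <- reduce(unstrand(centromere))
  if (sum(width(GenomicRanges::setdiff(loss, cen))) != 0)
    stop("loss intervals extend outside the parental centromere")
  for (e in elevation) {
    if (e$r1 < e$r2 || e$r2 < 1) stop("need r1 >= r2 >= 1")
  }
  retained <- GenomicRanges::setdiff(cen, loss)
  truth <- truth_set(centromere = cen, derived_centromere = retained,
                     R1 = loss, R2 = retained, elevation = elevation,
                     decay_scale = decay_scale, seed = config$seed)

  grid <- make_windows(setNames(config$chrom_len, config$chrom),
                       config$bin_width)
  mid <- (start(grid) + end(grid)) / 2
  cs <- min(start(cen)); ce <- max(end(cen))
  dist_edge <- ifelse(mid < cs, cs - mid, ifelse(mid > ce, mid - ce, 0))
  in_flank <- dist_edge > 0 & dist_edge <= flank

  cen_fold <- bin_multiplier(grid, cen, config$enrich_fold)
  ret_fold <- bin_multiplier(grid, retained, config$enrich_fold)

  out <- list(cenh3 = list(), marks = list(parent = list(), derived = list()),
              grid = grid, truth = truth)
  k <- 0L
  draw <- function(mu) {
    k <<- k + 1L
    set.seed(sub_seed(config$seed, 1000L + k))
    rcounts(length(grid), mu, config$dispersion)
  }
  for (smp in c("parent", "derived")) {
    fold <- if (smp == "parent") cen_fold else ret_fold
    chip <- input <- vector("list", config$replicates)
    for (r in seq_len(config$replicates)) {
      ic <- draw(rep(config$background, length(grid)))
      cc <- draw(config$background * fold)
      input[[r]] <- coverage_track(grid, ic, sum(ic), smp, "CENH3-input", r)
      chip[[r]] <- coverage_track(grid, cc, sum(cc), smp, "CENH3", r)
    }
    out$cenh3[[smp]] <- list(chip = chip, input = input)
  }
  for (mk in names(elevation)) {
    e <- elevation[[mk]]
    edge <- if (is.null(e$flank)) e$r2 else e$flank
    m_r1 <- bin_multiplier(grid, loss, e$r1)
    m_r2 <- bin_multiplier(grid, retained, e$r2)
    m_cen <- m_r1 * m_r2  # disjoint regions: at most one factor > 1 per bin
    m_flank <- ifelse(in_flank, 1 + (edge - 1) * exp(-dist_edge / decay_scale), 1)
    mult_derived <- pmax(m_cen, m_flank)
    for (smp in c("parent", "derived")) {
      mult <- if (smp == "parent") rep(1, length(grid)) else mult_derived
      reps <- vector("list", config$replicates)
      for (r in seq_len(config$replicates)) {
        cnt <- draw(config$background * mult)
        reps[[r]] <- coverage_track(grid, cnt, sum(cnt), smp, mk, r)
      }
      out$marks[[smp]][[mk]] <- reps
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Hi-C simulation
# ---------------------------------------------------------------------------

#' Simulate a Hi-C contact matrix with planted structure
#'
#' Expected contacts follow a power-law distance decay
#' mu(i,j) ~ (|i-j| + 1)^(-decay_exponent), multiplied by a same-compartment
#' affinity boost and a within-TAD block boost; counts are Poisson draws of
#' the upper triangle, symmetrised.
#'
#' @param n_bins number of bins (>= 20).
#' @param decay_exponent power-law exponent of distance decay.
#' @param compartments per-bin labels in {"A","B"}, or `NULL`.
#' @param tad_boundaries boundary bin indices strictly inside
#'   `[2, n_bins - 1]`, or `NULL`.
#' @param depth expected total contacts.
#' @param seed RNG seed.
#' @param compartment_strength same-label contact boost (fractional).
#' @param tad_strength within-TAD contact boost (fractional).
#' @param resolution bin size in bp (metadata only).
#' @return list with `matrix` (a [contact_matrix()]) and `truth`.
#' @export
simulate_contact_matrix <- function(n_bins, decay_exponent = 1,
                                    compartments = NULL, tad_boundaries = NULL,
                                    depth = 2e6, seed = 1L,
                                    compartment_strength = 0.6,
                                    tad_strength = 1.0, resolution = 20e3) {
  stopifnot(n_bins >= 20)
  if (!is.null(compartments))
    stopifnot(length(compartments) == n_bins, all(compartments %in% c("A", "B")))
  if (!is.null(tad_boundaries))
    stopifnot(all(tad_boundaries > 1 & tad_boundaries < n_bins))
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  mu <- (d + 1)^(-decay_exponent)
  if (!is.null(compartments)) {
    same <- outer(compartments, compartments, "==")
    mu <- mu * (1 + compartment_strength * same)
  }
  if (!is.null(tad_boundaries)) {
    dom <- findInterval(seq_len(n_bins) - 0.5, sort(tad_boundaries))
    same_tad <- outer(dom, dom, "==")
    mu <- mu * (1 + tad_strength * same_tad)
  }
  mu <- mu * depth / sum(mu[upper.tri(mu, diag = TRUE)])
  set.seed(sub_seed(seed, 9L))
  up <- upper.tri(mu, diag = TRUE)
  counts <- matrix(0, n_bins, n_bins)
  counts[up] <- rpois(sum(up), mu[up])
  counts <- counts + t(counts) - diag(diag(counts))
  cm <- contact_matrix(counts, resolution = resolution)
  list(matrix = cm,
       truth = truth_set(compartments = compartments,
                         tad_boundaries = tad_boundaries, seed = seed))
}
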