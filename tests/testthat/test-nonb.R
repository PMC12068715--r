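test_that("hand-constructed motifs are found exactly", {
  # three 3-bp A/T tracts with 4-bp spacers form a single APR
  apr <- "AAACGCGTTTCGCGAAA"
  h <- scan_motifs(apr, "APR")
  expect_length(h, 1L)
  expect_equal(c(start(h), end(h)), c(1L, 17L))

  # canonical G-quadruplex covers the whole string
  gq <- "GGGTTAGGGTTAGGGTTAGGG"
  h <- scan_motifs(gq, "GQ")
  expect_length(h, 1L)
  expect_equal(c(start(h), end(h)), c(1L, 21L))
  expect_equal(h$strand_hit, "+")
  # its reverse complement is reported on the minus strand
  h2 <- scan_motifs(revcomp_string(gq), "GQ")
  expect_equal(h2$strand_hit, "-")

  # Z-DNA: alternating GC of 14 bp
  h <- scan_motifs("GCGCGCGCGCGCGC", "Z")
  expect_length(h, 1L)
  expect_equal(width(h), 14L)

  # mirror and inverted repeats with 14-bp arms and a 5-bp loop
  arm <- "ACGGTCAGCTACGT"
  ir <- paste0(arm, "CCGGT", revcomp_string(arm))
  h <- scan_motifs(ir, "IR")
  expect_equal(c(start(h)[1], end(h)[1]), c(1L, nchar(ir)))
  mr <- paste0(arm, "CCGGT", rev_string(arm))
  h <- scan_motifs(mr, "MR")
  expect_equal(c(start(h)[1], end(h)[1]), c(1L, nchar(mr)))

  # direct repeat: 12-bp unit twice
  dr <- "ACGGTCAGTCATACGGTCAGTCAT"
  h <- scan_motifs(dr, "DR")
  expect_length(h, 1L)
  expect_equal(width(h), 24L)

  # homopolymers match no class at all
  for (cl in c("APR", "DR", "GQ", "IR", "MR", "STR", "Z")) {
    expect_length(scan_motifs(strrep("C", 200), cl), 0L)
    expect_length(scan_motifs(strrep("G", 200), cl), 0L)
  }
})

test_that("scanners match the rule oracle on random sequences", {
  set.seed(7)
  for (cl in c("APR", "GQ", "Z", "STR", "DR")) {
    for (i in 1:6) {
      s <- random_seq(500, oracle_alphabet(cl))
      expect_identical(scanner_coverage(s, cl, 500), oracle_coverage(s, cl),
                       label = sprintf("%s seq %d", cl, i))
    }
  }
  # IR/MR checked at reduced arm/loop bounds so the substring enumeration
  # stays exhaustive
  params <- list(arm_min = 6L, arm_max = 20L, loop_max = 12L)
  for (cl in c("IR", "MR")) {
    pair <- if (cl == "IR") "revcomp" else "reverse"
    for (i in 1:6) {
      s <- random_seq(300, oracle_alphabet(cl))
      hits <- scan_motifs(s, cl, params)
      cov <- rep(FALSE, 300)
      for (k in seq_along(hits)) cov[start(hits)[k]:end(hits)[k]] <- TRUE
      ocov <- rep(FALSE, 300)
      for (a in 1:300) {
        for (b in a:min(300, a + 2L * 20L + 12L - 1L)) {
          if (is_armed(substr(s, a, b), 6L, 12L, pair, arm_max = 20L))
            ocov[a:b] <- TRUE
        }
      }
      expect_identical(cov, ocov, label = sprintf("%s seq %d", cl, i))
    }
  }
})

test_that("motif density separates counts from coverage", {
  grid <- make_windows(c(c1 = 400000), 200000)
  expect_equal(motif_density(GRanges(), grid)$count, c(0L, 0L))
  hits <- GRanges("c1", IRanges(seq(1000, 46000, by = 5000), width = 50))
  d <- motif_density(hits, grid)
  expect_equal(d$count, c(10L, 0L))
  expect_equal(d$coverage, c(500 / 200000, 0))
  # overlapping hits are merged before coverage
  twice <- c(hits, hits)
  d2 <- motif_density(twice, grid)
  expect_equal(d2$coverage[1], 500 / 200000)
  expect_equal(d2$count[1], 20L)
})

test_that("permutation enrichment has exact boundary behaviour", {
  # all-equal densities: every permutation ties, p = 1
  out <- permutation_enrichment(rep(2, 50), 1:5, n_perm = 200, seed = 1)
  expect_equal(out$p_value, 1)
  # centromeric densities above the non-centromeric maximum: minimal p
  dens <- c(rep(10, 5), rep(1, 95))
  out <- permutation_enrichment(dens, 1:5, n_perm = 1000, seed = 1)
  expect_equal(out$p_value, 1 / 1001)
  expect_error(permutation_enrichment(rep(1, 10), 1:6), "pool")
  # rescaling densities leaves p unchanged
  set.seed(3)
  dens <- runif(80)
  p1 <- permutation_enrichment(dens, 1:10, n_perm = 500, seed = 9)$p_value
  p2 <- permutation_enrichment(dens * 1000, 1:10, n_perm = 500, seed = 9)$p_value
  expect_equal(p1, p2)
})

test_that("a genome with motifs planted only in the centromere is enriched", {
  g <- simulate_genome(200000, plantings = list(
    list(class = "APR", at = 90001, n = 30)), seed = 13)
  hits <- scan_motifs(g$seq, "APR")
  grid <- make_windows(c(chrSim = 200000), 10000)
  dens <- motif_density(hits, grid)
  cen_idx <- which(count_in_windows(g$truth$motifs, grid) > 0)
  out <- permutation_enrichment(dens$count, cen_idx, n_perm = 1000, seed = 5)
  expect_lte(out$p_value, 0.01)
})

test_that("nearest-neighbor window energies follow duplex thermodynamics", {
  # G/C windows are more stable (more negative) than A/T windows
  eA <- window_free_energy(strrep("A", 300))$energy
  eG <- window_free_energy(strrep("G", 300))$energy
  expect_lt(eG, eA)
  # hand value: 299 AA stacks at -1.00 plus two A/T initiations at 1.03
  expect_equal(eA, -299 + 2 * 1.03)

  # reverse complement has identical duplex energy
  set.seed(2)
  s <- random_seq(300)
  expect_equal(window_free_energy(s)$energy,
               window_free_energy(revcomp_string(s))$energy)

  # shifting by one step shifts window scores by one index
  s2 <- random_seq(1200)
  e1 <- window_free_energy(s2)
  e2 <- window_free_energy(paste0(substr(s2, 151, 1200)))
  expect_equal(e2$energy[1:6], e1$energy[2:7])

  # the external engine reads precomputed scores
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(chrom = "c1", start = 1, end = 300, energy = -42.5)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(window_free_energy(s, engine = "external",
                                  external_path = f)$energy, -42.5)
})

test_that("region energy comparisons detect planted stability differences", {
  set.seed(41)
  # build windows directly: R1 windows shifted less stable than R2
  mk <- function(start, n, mu) data.frame(chrom = "c1",
    start = seq(start, by = 300, length.out = n),
    end = seq(start, by = 300, length.out = n) + 299,
    energy = rnorm(n, mu, 0.5))
  r1 <- GRanges("c1", IRanges(1, 60000))
  r2 <- GRanges("c1", IRanges(60001, 120000))
  nc <- GRanges("c1", IRanges(120001, 240000))
  win <- rbind(mk(1, 150, -24.8), mk(60001, 150, -25.1), mk(120001, 300, -24))
  out <- compare_region_energy(win, list(R1 = r1, R2 = r2, noncen = nc))
  expect_equal(out$summary$region, c("R1", "R2", "noncen"))
  expect_lt(out$summary$mean[2], out$summary$mean[1])
  p12 <- out$pairwise$p_value[out$pairwise$region_a == "R1" &
                              out$pairwise$region_b == "R2"]
  expect_lt(p12, 0.05)
  # identical constant energies tie out to p = 1
  const <- rbind(mk(1, 50, -25), mk(120001, 50, -25))
  const$energy <- -25
  same <- compare_region_energy(const, list(R1 = r1, noncen = nc))
  expect_equal(same$pairwise$p_value, 1)
  expect_error(compare_region_energy(win[1:2, ], list(R1 = r1, R2 = r2)),
               "fewer than 3")
})
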