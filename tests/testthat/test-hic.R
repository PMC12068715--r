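sym_random_matrix <- function(n) {
  m <- matrix(runif(n * n, 0.5, 5), n, n)
  (m + t(m)) / 2
}

test_that("contact matrices validate shape and round-trip triplet TSV", {
  expect_error(contact_matrix(matrix(1:6, 2, 3), 1e4), "nrow")
  asym <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_error(contact_matrix(asym, 1e4), "symmetric")
  m <- contact_matrix(sym_random_matrix(8), 20e3)
  f <- tempfile(fileext = ".tsv")
  write_contact_matrix(m, f)
  back <- read_contact_matrix(f, 20e3)
  expect_equal(back$counts, m$counts, tolerance = 1e-12)
})

test_that("KR balancing equalises row sums and matches the Sinkhorn oracle", {
  set.seed(4)
  # constant matrix balances to equal row sums immediately
  mc <- contact_matrix(matrix(3, 6, 6), 1e4)
  bc <- balance_matrix(mc, "KR")
  expect_lt(sd(rowSums(bc$counts)) / mean(rowSums(bc$counts)), 1e-6)

  for (i in 1:40) {
    n <- sample(4:10, 1)
    m <- contact_matrix(sym_random_matrix(n), 1e4)
    b <- balance_matrix(m, "KR")
    r <- rowSums(b$counts)
    expect_lt(sd(r) / mean(r), 1e-6)
    expect_true(isSymmetric(unname(b$counts)))
    oracle <- sinkhorn_balance(m$counts)
    expect_equal(unname(b$counts), unname(oracle), tolerance = 1e-4)
  }

  # a zero row is masked, the rest balanced
  mz <- sym_random_matrix(6)
  mz[3, ] <- 0; mz[, 3] <- 0
  bz <- balance_matrix(contact_matrix(mz, 1e4), "KR")
  expect_equal(bz$masked, 3L)
  keep <- setdiff(1:6, 3)
  r <- rowSums(bz$counts[keep, keep])
  expect_lt(sd(r) / mean(r), 1e-6)

  # depth normalisation preserves proportions
  md <- contact_matrix(sym_random_matrix(5), 1e4)
  bd <- balance_matrix(md, "depth")
  expect_equal(sum(bd$counts), 1e6)
})

test_that("difference maps are exactly antisymmetric under operand swap", {
  set.seed(9)
  a <- contact_matrix(sym_random_matrix(12), 1e4)
  b <- contact_matrix(sym_random_matrix(12), 1e4)
  expect_equal(difference_map(a, a), matrix(0, 12, 12))
  expect_equal(difference_map(a, b) + difference_map(b, a),
               matrix(0, 12, 12), tolerance = 1e-12)

  # halving one block shows up as ~log2(2) in the comparative map
  sm <- simulate_contact_matrix(60, 1, NULL, NULL, depth = 5e6, seed = 3)
  half <- sm$matrix$counts
  blk <- 20:40
  half[blk, blk] <- round(half[blk, blk] / 2)
  d <- difference_map(sm$matrix, contact_matrix(half, 20e3), pseudocount = 1)
  expect_lt(abs(mean(d[blk, blk]) - 1), 0.15)
})

test_that("PC1 recovers planted compartments and respects orientation", {
  labs <- rep(rep(c("A", "B"), 10), each = 10)
  sm <- simulate_contact_matrix(200, 1, labs, NULL, depth = 6e6, seed = 11)
  bal <- balance_matrix(sm$matrix, "KR")
  anchor <- as.numeric(labs == "A")
  ct <- compartment_pc1(bal, orientation_track = anchor)
  expect_gte(mean(ct$labels == labs), 0.95)
  # flipping the anchor flips signs and labels
  ct2 <- compartment_pc1(bal, orientation_track = -anchor)
  expect_equal(ct2$pc1, -ct$pc1)
  expect_true(all(ct2$labels[ct$labels == "A"] == "B"))
  # scaling the matrix leaves PC1 unchanged up to sign
  bal2 <- bal; bal2$counts <- bal$counts * 7.5
  ct3 <- compartment_pc1(bal2, orientation_track = anchor)
  expect_equal(ct3$pc1, ct$pc1, tolerance = 1e-8)

  # a structureless matrix leaves PC1 weak
  null <- simulate_contact_matrix(200, 1, NULL, NULL, depth = 6e6, seed = 12)
  cn <- compartment_pc1(balance_matrix(null$matrix, "KR"))
  expect_lt(cn$var_explained, 0.2)
})

test_that("region PC1 statistics reproduce printed magnitude ratios", {
  # the printed mean PC1 values are the inputs; the ratio is the output
  expect_equal(pc1_magnitude_ratio(-0.0378, -0.0486), 1.29)
  expect_equal(pc1_magnitude_ratio(-0.0263, -0.0357), 1.36)

  labs <- rep(rep(c("A", "B"), 10), each = 10)
  sm <- simulate_contact_matrix(200, 1, labs, NULL, depth = 6e6, seed = 13)
  bal <- balance_matrix(sm$matrix, "KR")
  ct <- compartment_pc1(bal, as.numeric(labs == "A"))
  regions <- list(left = GRanges("seg", IRanges(1, 50 * 20e3)),
                  right = GRanges("seg", IRanges(50 * 20e3 + 1, 200 * 20e3)))
  st <- region_pc1_stats(ct, ct, regions)
  expect_equal(st$magnitude_ratio, c(1, 1))
  expect_equal(st$p_value, c(1, 1))
})

test_that("insulation TAD calling recovers planted boundaries", {
  # uniform decay, no blocks: no boundaries
  n0 <- simulate_contact_matrix(100, 1, NULL, NULL, seed = 21)
  t0 <- find_tads(balance_matrix(n0$matrix, "KR"), window = 8)
  expect_length(t0$boundaries, 0L)

  sm <- simulate_contact_matrix(100, 1, NULL, c(30L, 60L), seed = 5)
  td <- find_tads(balance_matrix(sm$matrix, "KR"), window = 8)
  expect_length(td$boundaries, 2L)
  expect_lte(abs(td$boundaries[1] - 30L), 2L)
  expect_lte(abs(td$boundaries[2] - 60L), 2L)
  # domains tile the segment between boundaries
  expect_equal(td$domains$start_bin[1], 1L)
  expect_equal(td$domains$end_bin[nrow(td$domains)], 100L)
  expect_equal(td$domains$start_bin[-1],
               td$domains$end_bin[-nrow(td$domains)])

  # strengthening the block contrast never removes a boundary
  found <- vapply(c(0.6, 1.0, 1.5, 2.5), function(s) {
    m <- simulate_contact_matrix(100, 1, NULL, 50L, tad_strength = s, seed = 8)
    t <- find_tads(balance_matrix(m$matrix, "KR"), window = 8)
    any(abs(t$boundaries - 50L) <= 2L)
  }, logical(1))
  expect_true(all(found[-1] >= found[-length(found)]))
  expect_error(find_tads(balance_matrix(n0$matrix, "depth"), window = 60),
               "insulation window")
})

test_that("boundary comparison classifies shared, gained and lost", {
  sm <- simulate_contact_matrix(100, 1, NULL, c(30L, 60L), seed = 5)
  td <- find_tads(balance_matrix(sm$matrix, "KR"), window = 8)
  same <- compare_boundaries(td, td)
  expect_equal(nrow(same$shared), length(td$boundaries))
  expect_length(same$gained, 0L)
  expect_length(same$lost, 0L)

  # a derived sample with one extra planted boundary: exactly one gained,
  # and it overlaps the feature placed at the same bin
  sm2 <- simulate_contact_matrix(100, 1, NULL, c(30L, 60L, 80L), seed = 5)
  td2 <- find_tads(balance_matrix(sm2$matrix, "KR"), window = 8)
  dmw <- GRanges("seg", IRanges(79 * 20e3 + 1, 82 * 20e3))
  cmp <- compare_boundaries(td, td2, features = dmw, slack = 2)
  expect_length(cmp$gained, 1L)
  expect_lte(abs(cmp$gained - 80L), 2L)
  expect_equal(cmp$gained_features$n_features, 1L)

  # shared count is monotone in slack
  s0 <- nrow(compare_boundaries(td, td2, slack = 0)$shared)
  s2 <- nrow(compare_boundaries(td, td2, slack = 2)$shared)
  expect_gte(s2, s0)
})
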