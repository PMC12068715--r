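test_that("region intensity is additive and library-normalized", {
  grid <- make_windows(c(c1 = 30000), 10000)
  tr <- coverage_track(grid, c(10, 20, 30), library_size = 1e6)
  whole <- region_intensity(tr, GRanges("c1", IRanges(1, 30000)))
  expect_equal(whole$raw, 60)
  # windows 1-2 only
  r12 <- region_intensity(tr, GRanges("c1", IRanges(1, 20000)))
  expect_equal(r12$raw, 30)
  expect_equal(r12$normalized, 3e-5)
  # additivity over disjoint regions
  r3 <- region_intensity(tr, GRanges("c1", IRanges(20001, 30000)))
  expect_equal(r12$raw + r3$raw, whole$raw)
  zero <- region_intensity(coverage_track(grid, c(0, 0, 0), 100),
                           GRanges("c1", IRanges(1, 30000)))
  expect_equal(zero$normalized, 0)
  expect_error(region_intensity(tr, GRanges()), "empty")
})

test_that("region Fisher test equals the exact hypergeometric computation", {
  rec <- function(raw, lib) structure(list(raw = raw, library_size = lib,
                                           normalized = raw / lib),
                                      class = "intensity_record")
  same <- region_fold_change_test(rec(30, 1000), rec(30, 1000))
  expect_equal(same$fold_change, 1)
  expect_equal(same$p_value, 1)

  # the 2x2 table [[30, 970], [10, 990]]
  ft <- region_fold_change_test(rec(30, 1000), rec(10, 1000))
  expect_equal(ft$fold_change, 3.0)
  expect_equal(ft$p_value,
               fisher.test(matrix(c(30, 970, 10, 990), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)

  # random tables with margins <= 500 against stats::fisher.test
  set.seed(17)
  for (i in 1:60) {
    la <- sample(50:500, 1); lb <- sample(50:500, 1)
    a <- rbinom(1, 40, 0.5); b <- rbinom(1, 40, 0.5)
    p_pkg <- region_fold_change_test(rec(a, la), rec(b, lb))$p_value
    p_ref <- fisher.test(matrix(c(a, la - a, b, lb - b), 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-8)
  }

  # doubling counts and libraries preserves FC and does not raise p
  p1 <- region_fold_change_test(rec(30, 1000), rec(10, 1000))
  p2 <- region_fold_change_test(rec(60, 2000), rec(20, 2000))
  expect_equal(p2$fold_change, p1$fold_change)
  expect_lte(p2$p_value, p1$p_value)
})

test_that("DMW calling respects both thresholds and finds planted windows", {
  grid <- make_windows(c(c1 = 1e6), 5000)
  nw <- length(grid)
  base <- coverage_track(grid, rep(1000, nw), library_size = nw * 1000)
  # identical tracks: no DMWs
  dm0 <- call_dmws(list(base), list(base), method = "fisher")
  expect_length(dm0$dmws, 0L)

  # true FC 1.4 with huge counts: significant but below the FC threshold,
  # so never called
  up14 <- coverage_track(grid, rep(1400, nw), library_size = nw * 1000)
  dm14 <- call_dmws(list(base), list(up14), method = "fisher")
  expect_length(dm14$dmws, 0L)
  expect_true(all(dm14$windows$padj < 0.05))  # power is not the limit

  # planted 3x windows with replicate noise are recovered (5-kb windows,
  # deep libraries, as in the sequenced system)
  cen <- GRanges("chrSim", IRanges(0.8e6 + 1, 1.8e6))
  loss <- GRanges("chrSim", IRanges(0.8e6 + 1, 1.2e6))
  sys <- simulate_contraction_system(cen, loss,
    list(mk = list(r1 = 3, r2 = 1, flank = 1)),
    config = sim_config(chrom_len = 2e6, bin_width = 5e3,
                        background = 25000, seed = 3))
  dm <- call_dmws(sys$marks$parent$mk, sys$marks$derived$mk)
  r1_windows <- which(overlapsAny(sys$grid, sys$truth$R1))
  called_up <- which(dm$windows$called & dm$windows$direction == "up")
  sens <- mean(r1_windows %in% called_up)
  expect_gte(sens, 0.9)
  expect_error(call_dmws(list(base),
    list(coverage_track(make_windows(c(c1 = 10000), 5000), c(1, 2)))),
    "grids")
})

test_that("pericentromere profiles order boxes by signed distance and clip", {
  grid <- make_windows(c(c1 = 20e6), 10e3)
  cen <- GRanges("c1", IRanges(9e6 + 1, 11e6))
  uni <- coverage_track(grid, rep(100, length(grid)), library_size = 1e6)
  prof <- pericentromere_profile(uni, cen)
  expect_equal(nrow(prof), 10L)
  expect_equal(prof$box_index, c(-5:-1, 1:5))
  expect_true(all(abs(prof$intensity - prof$intensity[1]) < 1e-12))
  expect_false(any(prof$clipped))

  # centromere 2 Mb from the chromosome start: short side has 2 boxes
  cen2 <- GRanges("c1", IRanges(2e6 + 1, 4e6))
  prof2 <- pericentromere_profile(uni, cen2)
  expect_equal(sum(prof2$box_index < 0), 2L)

  # simulated exponential elevation decays monotonically on each side
  cenS <- GRanges("chrSim", IRanges(4.5e6 + 1, 5.5e6))
  loss <- GRanges("chrSim", IRanges(4.5e6 + 1, 4.9e6))
  sys <- simulate_contraction_system(cenS, loss,
    list(mk = list(r1 = 3, r2 = 2, flank = 2)), decay_scale = 1.5e6,
    config = sim_config(background = 500, seed = 6), flank = 4e6)
  pp <- pericentromere_profile(sys$marks$parent$mk[[1]], cenS, flank = 4e6)
  pd <- pericentromere_profile(sys$marks$derived$mk[[1]], cenS, flank = 4e6)
  ratio <- pd$intensity / pp$intensity
  right <- ratio[pp$box_index > 0]
  left <- rev(ratio[pp$box_index < 0])
  expect_true(all(diff(right) < 0))
  expect_true(all(diff(left) < 0))
})

test_that("arm symmetry test is calibrated and powered", {
  set.seed(23)
  # identical vectors tie out to p = 1
  x <- rnorm(50)
  expect_equal(arm_symmetry_test(x, x)$p_value, 1, tolerance = 1e-6)
  expect_warning(out <- arm_symmetry_test(c(1, 2), rnorm(10)), "fewer than 3")
  expect_true(is.na(out$p_value))

  # null calibration: rejection rate near 5% over repeated draws
  rej <- mean(replicate(200, {
    arm_symmetry_test(rnorm(100), rnorm(100))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.04)

  # a 3-sigma shift is detected nearly always
  power <- mean(replicate(50, {
    arm_symmetry_test(rnorm(100) + 3, rnorm(100))$p_value < 0.01
  }))
  expect_gte(power, 0.95)
})

test_that("change correlation recovers coupled and null relationships", {
  set.seed(31)
  x <- rnorm(100)
  prop <- change_correlation(x, 2 * x)
  expect_equal(prop$r, 1)
  expect_warning(out <- change_correlation(rep(1, 10), rnorm(10)), "variance")
  expect_true(out$degenerate)

  # independent deltas: mean r near 0
  rs <- replicate(100, change_correlation(rnorm(50), rnorm(50))$r)
  expect_lt(abs(mean(rs)), 0.05)

  # shared latent factor: r matches the analytic value of the generator
  # x = l + e1, y = l + e2 with unit variances -> cor = 1/2
  rs2 <- replicate(200, {
    l <- rnorm(200)
    change_correlation(l + rnorm(200), l + rnorm(200))$r
  })
  expect_lt(abs(mean(rs2) - 0.5), 0.1)
})

test_that("the NB window test tracks an independent exact-test engine", {
  # cross-check against edgeR's exact NB test on one simulated contrast;
  # the package's own caller remains the implementation under test
  skip_if_not_installed("edgeR")
  cen <- GRanges("chrSim", IRanges(0.8e6 + 1, 1.8e6))
  loss <- GRanges("chrSim", IRanges(0.8e6 + 1, 1.2e6))
  sys <- simulate_contraction_system(cen, loss,
    list(mk = list(r1 = 3, r2 = 1, flank = 1)),
    config = sim_config(chrom_len = 2e6, bin_width = 5e3,
                        background = 2000, seed = 17))
  pt <- sys$marks$parent$mk; dt <- sys$marks$derived$mk
  dm <- call_dmws(pt, dt, normalization = "library")

  counts <- cbind(pt[[1]]$counts, pt[[2]]$counts,
                  dt[[1]]$counts, dt[[2]]$counts)
  group <- factor(c("p", "p", "d", "d"), levels = c("p", "d"))
  dge <- edgeR::DGEList(counts = counts, group = group,
                        lib.size = c(pt[[1]]$library_size,
                                     pt[[2]]$library_size,
                                     dt[[1]]$library_size,
                                     dt[[2]]$library_size))
  et <- edgeR::exactTest(dge, dispersion = dm$dispersion)
  p_ref <- et$table$PValue

  expect_gt(cor(-log10(dm$windows$p + 1e-300),
                -log10(p_ref + 1e-300), method = "spearman"), 0.95)
  calls_ref <- p.adjust(p_ref, "BH") < 0.05 &
    abs(et$table$logFC) > log2(1.5)
  agree <- mean((dm$windows$called) == calls_ref)
  expect_gt(agree, 0.95)
})
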