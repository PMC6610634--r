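test_that("window smoothing averages correctly", {
  # constant track: unchanged at every anchor
  tr <- coverage_track("c", 0, 10000, 2.5)
  sm <- smooth_windows(tr, 1000, 500)
  expect_true(all(abs(sm$value[2:19] - 2.5) < 1e-12))
  # unit impulse of width 1 bp: response peaks at 1/window
  imp <- coverage_track("c", 5000, 5001, 1)
  smi <- smooth_windows(imp, 1000, 500, extent_bp = 10000)
  expect_equal(max(smi$value), 1 / 1000)
  # random track equals brute-force window means
  set.seed(51)
  starts <- seq(0, 9900, by = 100)
  tr2 <- coverage_track("c", starts, starts + 100, stats::rnorm(100))
  sm2 <- smooth_windows(tr2, 1000, 500)
  arr <- rep(tr2$value, each = 100)
  for (k in seq_len(nrow(sm2))) {
    ctr <- (k - 0.5) * 500
    lo <- ctr - 500; hi <- ctr + 500
    vals <- arr[max(1, lo + 1):min(10000, hi)]
    bf <- sum(vals) / 1000  # bases outside the track count as 0
    expect_equal(sm2$value[k], bf, tolerance = 1e-10)
  }
})

test_that("scaling equalizes signal mass against a reference", {
  set.seed(52)
  s <- seq(0, 4900, by = 100)
  a <- coverage_track("c", s, s + 100, stats::runif(50, 0.5, 2))
  expect_equal(scale_to_reference(a, a)$value, a$value)
  b <- coverage_track("c", s, s + 100, 2 * a$value)
  expect_equal(scale_to_reference(b, a)$value, a$value, tolerance = 1e-12)
  r <- coverage_track("c", s, s + 100, stats::runif(50, 0.5, 2))
  sc <- scale_to_reference(a, r)
  Ia <- track_integral(sc)(5000); Ir <- track_integral(r)(5000)
  expect_equal(Ia, Ir, tolerance = 1e-9 * abs(Ir))
  zero <- coverage_track("c", 0, 100, 0)
  expect_error(scale_to_reference(zero, a), "zero signal")
})

test_that("delta tracks subtract pointwise over the breakpoint union", {
  set.seed(53)
  a <- coverage_track("c", c(0, 300, 800), c(200, 700, 1000), c(1, 2, 3))
  expect_true(all(delta_track(a, a)$value == 0))
  b <- coverage_track("c", c(100, 600), c(500, 900), c(0.5, 1.5))
  d1 <- delta_track(a, b); d2 <- delta_track(b, a)
  pos <- 0:999
  va <- track_value_at(a, pos); vb <- track_value_at(b, pos)
  expect_equal(track_value_at(d1, pos), va - vb)
  expect_equal(track_value_at(d2, pos), -(va - vb))
  expect_error(delta_track(a, coverage_track("other", 0, 1, 1)),
               "different chromosomes")
})

test_that("region density is a per-bp mean and is linear", {
  s <- seq(0, 1900, by = 100)
  uni <- coverage_track("c", 0, 2000, 4.2)
  regs <- region("c", c(0, 150, 900), c(100, 450, 2000))
  expect_equal(region_density(uni, regs), rep(4.2, 3))
  set.seed(54)
  a <- coverage_track("c", s, s + 100, stats::rnorm(20))
  b <- coverage_track("c", s, s + 100, stats::rnorm(20))
  ab <- coverage_track("c", s, s + 100, 2 * a$value + 3 * b$value)
  expect_equal(region_density(ab, regs),
               2 * region_density(a, regs) + 3 * region_density(b, regs),
               tolerance = 1e-12)
  # brute-force per-base oracle
  arr <- rep(a$value, each = 100)
  for (k in 1:3) {
    expect_equal(region_density(a, regs)[k],
                 mean(arr[(regs$start[k] + 1):regs$end[k]]),
                 tolerance = 1e-12)
  }
})

test_that("binned densities are length-weighted means", {
  b <- genome_binning("c", 1000, 400)  # last bin short (200 bp)
  tr <- coverage_track("c", c(0, 200, 800), c(200, 600, 1000), c(1, 3, 5))
  bs <- bin_track(tr, b)
  expect_equal(bs, c((200 * 1 + 200 * 3) / 400, (200 * 3 + 200 * 0) / 400,
                     (200 * 5) / 200))
})

test_that("the S1/S2 density test partitions bins and degrades gracefully", {
  set.seed(55)
  labels <- rep(c("+", "-"), each = 60)
  vals <- c(stats::rnorm(60, 1), stats::rnorm(60, 0))
  ts <- s1s2_density_test(vals, labels)
  expect_lt(ts$p.value, 0.05)
  expect_equal(ts$box$n, c(60, 60))
  expect_equal(ts$box$median, c(stats::median(vals[1:60]),
                                stats::median(vals[61:120])))
  expect_warning(s1s2_density_test(vals, rep("+", 120)), "one compartment")
})

test_that("summit metaprofiles slice the track around each summit", {
  set.seed(56)
  s <- seq(0, 99900, by = 100)
  tr <- coverage_track("c", s, s + 100, stats::rnorm(1000))
  summits <- region("c", c(20000, 50000, 80050), c(20001, 50001, 80051),
                    category = "peak_summit")
  mp <- summit_metaprofile(tr, summits, flank_bp = 10e3, step_bp = 100)
  expect_equal(dim(mp$profile), c(3, 200))
  # direct slicing oracle for summit 1 (aligned to the track grid)
  expect_equal(mp$profile[1, ], tr$value[101:300])
  expect_equal(mp$mean_curve, colMeans(mp$profile))
  # constant track -> flat curve at the constant
  cst <- coverage_track("c", 0, 1e5, 7)
  mpc <- summit_metaprofile(cst, summits)
  expect_true(all(mpc$mean_curve == 7))
  # impulse at each summit -> peak at the center
  imp <- coverage_track("c", summits$start, summits$start + 1, 100)
  mpi <- summit_metaprofile(imp, summits)
  expect_equal(which.max(mpi$mean_curve), 101)
  # summits too close to the chromosome edge are dropped and counted
  edge <- region("c", c(500, 50000), c(501, 50001))
  mpe <- summit_metaprofile(tr, edge, flank_bp = 10e3)
  expect_equal(mpe$n_dropped, 1)
  expect_equal(nrow(mpe$profile), 1)
})

test_that("fpm normalization scales total mass to one million", {
  tr <- coverage_track("c", c(0, 100), c(100, 300), c(2, 4))
  f <- fpm_normalize(tr)
  expect_equal(track_integral(f)(300), 1e6)
})

test_that("scaling then subtracting identical biology gives a near-zero delta", {
  truth <- architecture_truth(chrom_length_bp = 10e6, bin_size_bp = 100e3,
                              regime = "SMCHD1_KO", n_segments = 4,
                              megadomain_boundary_bp = 5e6, seed = 57)
  a <- simulate_coverage(truth, enrichment_S1 = 0.4, noise_sd = 0.1, seed = 58)
  b <- simulate_coverage(truth, enrichment_S1 = 0.4, noise_sd = 0.1, seed = 59)
  d <- delta_track(a, scale_to_reference(b, a))
  I <- track_integral(d)
  expect_lt(abs(I(10e6)) / 10e6, 0.01)  # mean |delta| below the noise floor
})
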