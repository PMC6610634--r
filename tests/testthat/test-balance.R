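test_that("mask_low_coverage masks the lowest-coverage bins deterministically", {
  set.seed(1)
  n <- 100
  b <- make_binning(n)
  v <- random_symmetric(n, 1, 10)
  m <- contact_matrix(v, b)
  mk <- mask_low_coverage(m, 0.14)
  expect_equal(sum(mk$mask), 14)
  # sort-based oracle with index tie-break
  marg <- rowSums(v)
  expect_equal(which(mk$mask), sort(order(marg, seq_len(n))[1:14]))
  # idempotence
  expect_identical(mask_low_coverage(mk, 0.14)$mask, mk$mask)
  # quantile 0: only all-zero rows
  v2 <- v; v2[5, ] <- 0; v2[, 5] <- 0
  mz <- mask_low_coverage(contact_matrix(v2, b), 0)
  expect_equal(which(mz$mask), 5L)
  expect_error(mask_low_coverage(m, 1), "quantile")
})

test_that("downsample hits the target exactly and preserves expectation", {
  set.seed(2)
  n <- 5
  b <- make_binning(n)
  v <- matrix(sample(0:40, n * n, TRUE), n)
  v <- v + t(v) - diag(diag(v))
  m <- contact_matrix(v, b)
  tot <- matrix_total(m)
  expect_identical(downsample(m, tot, seed = 1)$values, m$values)
  expect_equal(matrix_total(downsample(m, 0, seed = 1)), 0)
  target <- floor(tot / 2)
  reps <- 400
  acc <- matrix(0, n, n)
  for (s in seq_len(reps)) {
    d <- downsample(m, target, seed = s)
    expect_equal(matrix_total(d), target)
    acc <- acc + d$values
  }
  # hypergeometric expectation per cell = count * target / total
  ut <- upper.tri(v, diag = TRUE)
  expected <- v[ut] * target / tot
  observed <- acc[ut] / reps
  # 3 SE under the hypergeometric marginal
  se <- sqrt(v[ut] * (target / tot) * (1 - target / tot) *
               (tot - v[ut]) / pmax(tot - 1, 1) / reps)
  expect_true(all(abs(observed - expected) <= pmax(3 * se, 1e-9)))
  # determinism under seed
  expect_identical(downsample(m, target, seed = 9)$values,
                   downsample(m, target, seed = 9)$values)
  expect_error(downsample(m, tot + 1, seed = 1), "exceeds")
})

test_that("ice_balance equalizes marginals and matches a textbook iteration", {
  b <- make_binning(3)
  v <- matrix(c(0, 2, 4, 2, 0, 2, 4, 2, 0), 3)
  m <- ice_balance(contact_matrix(v, b), tol = 1e-10)
  s <- rowSums(m$values)
  expect_lt(stats::sd(s) / mean(s), 1e-10)
  expect_equal(m$values, bf_ice(v), tolerance = 1e-8)
  # already-balanced matrix is a fixed point
  m2 <- ice_balance(contact_matrix(m$values, b,
                                   metadata = list()), tol = 1e-8)
  expect_equal(m2$values, m$values, tolerance = 1e-7)
})

test_that("ice_balance respects the mask and preserves the unmasked mean", {
  set.seed(3)
  n <- 20
  b <- make_binning(n)
  v <- random_symmetric(n, 1, 8)
  mask <- rep(FALSE, n); mask[7] <- TRUE
  m <- ice_balance(contact_matrix(v, b, mask = mask))
  expect_true(all(is.na(m$values[7, ])))
  expect_true(all(is.na(m$values[, 7])))
  un <- !mask
  expect_equal(mean(m$values[un, un]), mean(v[un, un]), tolerance = 1e-9)
  expect_error(ice_balance(contact_matrix(v, b, mask = rep(TRUE, n))),
               "masked")
})

test_that("ICE converges on random positive matrices (marginal CV < 1e-6)", {
  set.seed(4)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    m <- ice_balance(contact_matrix(random_symmetric(n, 0.5, 12),
                                    make_binning(n)))
    s <- rowSums(m$values)
    expect_lt(stats::sd(s) / mean(s), 1e-6)
  }
})

test_that("observed/expected removes distance decay", {
  n <- 25
  b <- make_binning(n)
  # translation-invariant matrix -> O/E exactly 1
  v <- 10 / (abs(outer(1:n, 1:n, "-")) + 1)
  m <- contact_matrix(v, b, balanced = TRUE)
  oe <- observed_over_expected(m)
  expect_equal(oe$values, matrix(1, n, n), tolerance = 1e-12)
  # random matrix equals loop oracle; per-diagonal means of O/E are 1
  set.seed(5)
  v2 <- random_symmetric(20)
  m2 <- contact_matrix(v2, make_binning(20), balanced = TRUE)
  oe2 <- observed_over_expected(m2)
  expect_equal(oe2$values, bf_oe(v2), tolerance = 1e-12)
  for (d in 0:10) {
    idx <- cbind(1:(20 - d), (1 + d):20)
    expect_equal(mean(oe2$values[idx]), 1, tolerance = 1e-12)
  }
})

test_that("pearson_map equals brute-force pairwise Pearson with self-column exclusion", {
  set.seed(6)
  n <- 15
  b <- make_binning(n)
  v <- random_symmetric(n)
  mask <- rep(FALSE, n); mask[c(4, 12)] <- TRUE
  v[mask, ] <- NA; v[, mask] <- NA
  v[2, 9] <- NA; v[9, 2] <- NA
  pm <- pearson_map(contact_matrix(v, b, mask = mask, balanced = TRUE))
  bf <- bf_pearson(v, mask)
  expect_equal(pm$values, bf, tolerance = 1e-10)
  expect_identical(is.na(pm$values), is.na(bf))
  # symmetry, unit diagonal, range
  expect_equal(pm$values, t(pm$values))
  expect_true(all(diag(pm$values)[!mask] == 1))
  expect_true(all(abs(pm$values) <= 1, na.rm = TRUE))
})

test_that("pearson_map handles checkerboards, constants, and global scaling", {
  n <- 12
  b <- make_binning(n)
  type <- rep(c(1, -1), length.out = n)
  v <- 2 + outer(type, type)  # two-type checkerboard: 3 within, 1 across
  m <- contact_matrix(v, b, balanced = TRUE)
  pm <- pearson_map(m)
  within <- outer(type, type) > 0
  off <- !diag(n) > 0
  expect_true(all(pm$values[within & off] > 0.999))
  expect_true(all(pm$values[!within] < -0.999))
  # constant matrix: zero variance -> off-diagonal NA
  pmc <- pearson_map(contact_matrix(matrix(3, n, n), b, balanced = TRUE))
  expect_true(all(is.na(pmc$values[off & !diag(n)])))
  # invariance to global scaling
  m2 <- contact_matrix(v * 7.5, b, balanced = TRUE)
  expect_equal(pearson_map(m2)$values, pm$values, tolerance = 1e-12)
})

test_that("coarsening aggregates counts and masks consistently", {
  set.seed(8)
  n <- 10
  b <- make_binning(n)
  v <- matrix(sample(0:20, n * n, TRUE), n); v <- v + t(v) - diag(diag(v))
  mask <- rep(FALSE, n); mask[3:4] <- TRUE
  m <- coarsen_matrix(contact_matrix(v, b, mask = mask), 2)
  expect_equal(m$binning$n_bins, 5)
  expect_equal(m$values[1, 2], sum(v[1:2, 3:4]))
  expect_equal(matrix_total(m), matrix_total(contact_matrix(v, b)))
  expect_true(m$mask[2])   # both constituent bins masked
  expect_false(m$mask[1])
})
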