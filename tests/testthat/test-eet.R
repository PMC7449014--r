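test_that("concentration-difference inversion round-trips the rate law", {
  # r = k*A*1 inverts to exactly 1 mol/m^3
  k <- 4.23e-4; A <- 1.4e-11
  expect_equal(conc_difference(k * A * 1.0, k, A)$delta_c_molm3, 1.0,
               tolerance = 1e-12)
  # hand division of the benchmark rate (frozen from r/(k*A))
  dc <- conc_difference(2.458e-20, k, A)
  expect_equal(dc$delta_c_molm3, 4.150625e-6, tolerance = 1e-6)
  expect_equal(dc$sem, 0)
  expect_false(dc$suspect)
  # quadrature error propagation
  dc2 <- conc_difference(2.458e-20, k, A, rate_sem = 2.458e-21,
                         k_sem = 4.23e-5, area_sem = 1.4e-12)
  expect_equal(dc2$sem, dc2$delta_c_molm3 * sqrt(3 * 0.1^2),
               tolerance = 1e-12)
  expect_warning(neg <- conc_difference(-1e-20, k, A), "suspect")
  expect_true(neg$suspect)
  expect_error(conc_difference(1e-20, 0, A), "non-zero")
  # property: round trip for random positive triples
  set.seed(1)
  for (i in 1:25) {
    kk <- 10^runif(1, -5, -3); aa <- 10^runif(1, -12, -10)
    dd <- 10^runif(1, -7, -4)
    expect_equal(conc_difference(kk * aa * dd, kk, aa)$delta_c_molm3, dd,
                 tolerance = 1e-12)
  }
})

test_that("decoupled length-derivative matches hand values and signs", {
  dc <- 1 # unit driving force, mol/m^3
  L <- 4; D <- 1.1
  mt <- mass_transfer_coefficient(L)
  A <- pi * (D * 1e-6) * (L * 1e-6)
  d <- rate_length_derivative(L, D, mt$k_ms, A, dc)
  expect_equal(d$k_channel, -1.28554e-9, tolerance = 1e-5)
  expect_equal(d$a_channel, 1.357409e-9, tolerance = 1e-5)
  expect_lt(d$k_channel, 0)
  expect_gt(d$a_channel, 0)
  expect_gt(d$dr_dL, 0) # area gain outweighs the flux loss
  # zero driving force zeroes everything
  d0 <- rate_length_derivative(L, D, mt$k_ms, A, 0)
  expect_equal(unlist(d0), c(dr_dL = 0, k_channel = 0, a_channel = 0))
  # inconsistent area is flagged
  expect_warning(rate_length_derivative(L, D, mt$k_ms, 2 * A, dc),
                 "inconsistent")
})

test_that("analytic derivative matches a finite-difference oracle over an L sweep", {
  D <- 1.2
  for (L in seq(2, 8, by = 0.5)) {
    mt <- mass_transfer_coefficient(L)
    A <- pi * (D * 1e-6) * (L * 1e-6)
    for (dc in c(1, 4.2e-6)) {
      d <- rate_length_derivative(L, D, mt$k_ms, A, dc)
      fd <- central_diff(function(Lm) rate_of_length_si(Lm, D * 1e-6, dc),
                         L * 1e-6, 1e-3 * 1e-6)
      expect_equal(d$dr_dL, fd, tolerance = 1e-6)
    }
  }
})

test_that("fractional differences compose multiplicatively", {
  a <- consistent_snapshot(5, "diluted", 3.7, 1.25, 4.0e-6)
  expect_equal(unlist(fractional_differences(a, a)),
               c(dk = 0, dA = 0, dkA = 0, ddc = 0, dr = 0))
  # dkA from the product rule
  b <- consistent_snapshot(5, "control", 3.7, 1.25, 4.0e-6)
  b$k_ms <- b$k_ms / 1.1
  b$mean_area_um2 <- b$mean_area_um2 / 1.2
  fd <- fractional_differences(a, b)
  expect_equal(fd$dkA, 1.1 * 1.2 - 1, tolerance = 1e-12)
  # mismatched days are rejected
  cc <- consistent_snapshot(9, "control", 3.7, 1.25, 4.0e-6)
  expect_error(fractional_differences(a, cc), "matched")
})

test_that("fractional-difference identity holds for consistent cultures", {
  # both snapshots derive every quantity from one model evaluation, so
  # (1+dr) = (1+dk)(1+dA)(1+ddc) must hold to 1e-9
  test <- consistent_snapshot(13, "diluted", 3.7, 1.3, 5.1e-6)
  ctrl <- consistent_snapshot(13, "control", 4.6, 1.2, 4.4e-6)
  fd <- fractional_differences(test, ctrl)
  expect_equal((1 + fd$dr),
               (1 + fd$dk) * (1 + fd$dA) * (1 + fd$ddc),
               tolerance = 1e-9)
  # and across a seeded sweep of geometries
  set.seed(20)
  for (i in 1:20) {
    t_l <- runif(1, 2.5, 6); c_l <- runif(1, 2.5, 6)
    tt <- consistent_snapshot(1, "diluted", t_l, runif(1, 1, 1.4),
                              10^runif(1, -7, -5))
    cs <- consistent_snapshot(1, "control", c_l, runif(1, 1, 1.4),
                              10^runif(1, -7, -5))
    fd <- fractional_differences(tt, cs)
    expect_equal(1 + fd$dr, (1 + fd$dk) * (1 + fd$dA) * (1 + fd$ddc),
                 tolerance = 1e-9)
  }
})

test_that("MER is the sigmoid of the channel ratio with correct dominance", {
  m <- morphology_effect_ratio(0.3, 0.3)
  expect_equal(m$mer, 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(m$mer, 0.7311, tolerance = 1e-4)
  expect_equal(m$dominance, "balanced")
  expect_equal(morphology_effect_ratio(0, 0.2)$mer, 0.5)
  expect_equal(morphology_effect_ratio(0, 0.2)$dominance, "physiology")
  expect_equal(morphology_effect_ratio(5, 1e-3)$mer, 1, tolerance = 1e-9)
  expect_equal(morphology_effect_ratio(5, 1e-3)$dominance, "morphology")
  # sign of the deltas is irrelevant (absolute values)
  expect_equal(morphology_effect_ratio(-0.3, 0.3)$mer,
               morphology_effect_ratio(0.3, -0.3)$mer)
  # denominator-zero limit
  expect_warning(mz <- morphology_effect_ratio(0.3, 0), "denominator-zero")
  expect_equal(mz$mer, 1)
  expect_true(mz$denominator_zero)
})

test_that("MER is monotone in both channels and bounded in (0.5, 1)", {
  dkAs <- seq(0.05, 2, by = 0.05)
  mers <- vapply(dkAs, function(x) morphology_effect_ratio(x, 0.5)$mer, 0)
  expect_true(all(diff(mers) > 0))
  ddcs <- seq(0.05, 2, by = 0.05)
  mers2 <- vapply(ddcs, function(x) morphology_effect_ratio(0.5, x)$mer, 0)
  expect_true(all(diff(mers2) < 0))
  expect_true(all(c(mers, mers2) > 0.5 & c(mers, mers2) < 1))
})

test_that("Pearson correlation behaves on exact and null data", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_with_properties(x, 2 * x)$r, 1, tolerance = 1e-12)
  expect_equal(correlate_with_properties(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(correlate_with_properties(x, rep(1, 5)), "constant")
  expect_error(correlate_with_properties(x, x[1:3]), "paired")
  expect_error(correlate_with_properties(x[1:2], x[1:2]), "n >= 3")
  # null distribution: independent Gaussians rarely exceed |r| = 0.3
  set.seed(77)
  excess <- vapply(1:200, function(i) {
    abs(correlate_with_properties(rnorm(100), rnorm(100))$r) >= 0.3
  }, logical(1))
  expect_gte(mean(!excess), 0.95)
})
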