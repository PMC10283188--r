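test_that("velocity fit recovers noiseless and degenerate tracks", {
  tr <- synth_tracks(1, speed_um_s = 10, duration_s = 5, frame_dt_s = 1,
                     noise_sigma_um = 0, seed = 1)
  fit <- estimate_velocity(tr)
  expect_equal(fit$slope_um_s, 10)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n, 6L)

  static <- data.frame(t_s = 0:5, x_um = rep(2, 6), y_um = rep(-1, 6))
  expect_equal(estimate_velocity(static)$slope_um_s, 0)
  expect_error(estimate_velocity(static[1, ]), "2 frames")
  dup <- data.frame(t_s = c(0, 1, 1), x_um = 1:3, y_um = 1:3)
  expect_error(estimate_velocity(dup), "strictly increasing")
})

test_that("velocity fit is scale-equivariant and shift-invariant in time", {
  tr <- synth_tracks(1, 7, 20, 1, noise_sigma_um = 0.5, seed = 42)
  f1 <- estimate_velocity(tr)
  tr_scaled <- transform(tr, x_um = 3 * x_um, y_um = 3 * y_um)
  expect_equal(estimate_velocity(tr_scaled)$slope_um_s, 3 * f1$slope_um_s)
  tr_shift <- transform(tr, t_s = t_s + 100)
  expect_equal(estimate_velocity(tr_shift)$slope_um_s, f1$slope_um_s)
})

test_that("noisy-track speed estimates land within OLS sampling error", {
  n_ok <- 0L
  n_rep <- 50L
  sigma <- 0.5; nf <- 60L
  for (s in seq_len(n_rep)) {
    tr <- synth_tracks(1, 10, duration_s = nf - 1, frame_dt_s = 1,
                       noise_sigma_um = sigma, seed = 1000 + s)
    fit <- estimate_velocity(tr)
    # OLS slope SE for unit-spaced time with iid position noise
    t <- 0:(nf - 1)
    se <- sigma / sqrt(sum((t - mean(t))^2))
    if (abs(fit$slope_um_s - 10) <= 3 * se) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_rep, 0.9)
})

test_that("occupancy counts cells, bars and hot spots correctly", {
  p <- build_bar_array(nx = 2, ny = 5)  # 10 bars, 20 poles
  fm_hs <- data.frame(x_um = rep(c(-100, 100), 5),
                      y_um = rep(c(-900, -500, -100, 300, 700) + 100, each = 2))
  empty <- occupancy(data.frame(x_um = numeric(), y_um = numeric()),
                     p, fm_hs)
  expect_equal(empty$n_cells, 0L)
  expect_equal(empty$n_touching_pattern, 0L)
  expect_equal(empty$n_hot_spots_occupied, 0L)

  # 7 cells on 5 of 10 distinct poles
  hs10 <- fm_hs[1:10, ]
  pos <- hs10[c(1, 1, 2, 3, 4, 5, 5), ]
  rep7 <- occupancy(pos, p, hs10, capture_radius_um = 5)
  expect_equal(rep7$n_hot_spots_occupied, 5L)
  expect_equal(rep7$fraction_hot_spots_occupied, 0.5)

  # touch counts are monotone in the touch radius and order-invariant
  set.seed(7)
  cl <- data.frame(x_um = runif(200, -200, 200), y_um = runif(200, -1000, 1000))
  r0 <- occupancy(cl, p, NULL, touch_radius_um = 0)
  r10 <- occupancy(cl, p, NULL, touch_radius_um = 10)
  expect_lte(r0$n_touching_pattern, r10$n_touching_pattern)
  perm <- occupancy(cl[sample(nrow(cl)), ], p, NULL, touch_radius_um = 10)
  expect_equal(perm$n_touching_pattern, r10$n_touching_pattern)
  expect_equal(sum(perm$cells_per_bar), sum(r10$cells_per_bar))
})

test_that("uniform null fraction delegates to the effective area", {
  p <- bar_fixture
  af <- area_fractions(p, 10)
  expect_equal(uniform_null_fraction(p, 10), af$effective_fraction)
  expect_equal(uniform_null_fraction(p, 0), af$nominal_fraction,
               tolerance = 1e-12)
  full <- pattern_spec(shape_rect(0, 50, 0, 50), unit_cell = c(50, 50))
  expect_equal(uniform_null_fraction(full, 3), 1)
})

test_that("proportion test matches the exact binomial oracle", {
  null_case <- proportion_test(25, 125, 0.2)
  expect_lt(abs(null_case$statistic), 1e-12)
  expect_equal(null_case$p_value, 1)

  zres <- proportion_test(30, 100, 0.114)
  bres <- stats::binom.test(30, 100, 0.114)
  expect_lt(zres$p_value, 0.05)
  expect_lt(bres$p.value, 0.05)
  # z with continuity correction tracks prop.test's chi-square
  pt <- stats::prop.test(30, 100, 0.114)
  expect_equal(zres$statistic^2, unname(pt$statistic), tolerance = 1e-9)

  # normal approximation error is small at n = 1000
  z1000 <- proportion_test(210, 1000, 0.175)
  e1000 <- proportion_test(210, 1000, 0.175, method = "exact")
  expect_lt(abs(z1000$p_value - e1000$p_value), 0.01)

  # small expected counts fall back to the exact test
  small <- proportion_test(2, 20, 0.05)
  expect_match(small$method, "exact")
  expect_error(proportion_test(5, 10, 0), "inside")
  expect_error(proportion_test(11, 10, 0.5), "<=")
})

test_that("Welch test handles shifts, identity and degenerate input", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  shift <- two_sample_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$p_value, 0.01)
  expect_equal(shift$p_value,
               stats::t.test(c(1, 2, 3), c(11, 12, 13))$p.value)

  # exhaustive permutation oracle: the observed split of two separated
  # 3-point samples is the most extreme of all 20 assignments
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  pool <- c(a, b)
  splits <- utils::combn(6, 3)
  diffs <- apply(splits, 2, function(idx) {
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  obs <- abs(mean(a) - mean(b))
  expect_equal(max(diffs), obs)
  expect_equal(sum(diffs >= obs - 1e-12), 2L)  # the split and its mirror

  deg <- two_sample_t(c(5, 5), c(5, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})
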