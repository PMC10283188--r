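test_that("uniform field gives zero linear force", {
  grid <- list(plane = "xy", axis1 = 0:10, axis2 = 0:10, z_um = 2,
               spacing_um = 1,
               Bx = matrix(0.1, 11, 11), By = matrix(0.2, 11, 11),
               Bz = matrix(0, 11, 11))
  grid$Bnorm <- sqrt(grid$Bx^2 + grid$By^2 + grid$Bz^2)
  class(grid) <- "field_grid"
  fm <- linear_force(grid)
  expect_true(all(fm$Fnorm == 0))
})

test_that("too-coarse grids trigger a differencing warning", {
  coarse <- field_map(bar_fixture, z_um = 2, xlim = c(-40, 40),
                      ylim = c(-130, 130), spacing_um = 5)
  expect_warning(linear_force(coarse), "unstable")
})

test_that("the two linear-force forms agree pointwise", {
  pts <- rbind(c(0, 104, 0), c(10, 95, 0), c(-20, 112, 0), c(5, 60, 0))[, 1:2]
  f1 <- force_function(bar_fixture, form = "gradB2")(pts)
  f2 <- force_function(bar_fixture, form = "BgradB")(pts)
  for (i in seq_len(nrow(pts))) {
    expect_lt(rel_err(f1[i, ], f2[i, ]), 1e-3)
  }
})

test_that("the linear force field is conservative (curl-free)", {
  # in-plane curl component dFy/dx - dFx/dy, away from the map border
  # where one-sided stencils apply
  curl <- map_curl(bar_force_fine)
  scale <- max(bar_force_fine$Fnorm) / (bar_force_fine$spacing_um * 1e-6)
  expect_lt(max(abs(curl)) / scale, 1e-3)
})

test_that("force scales quadratically (linear) and linearly (saturated) in M", {
  pts <- rbind(c(7, 104), c(12, 95))  # off the symmetry axes
  base_M <- 1 / (4e-7 * pi)
  f1 <- force_function(bar_fixture, M_Am = base_M)(pts)
  f2 <- force_function(bar_fixture, M_Am = 2 * base_M)(pts)
  expect_equal(f2 / f1, matrix(4, 2, 3), ignore_attr = TRUE,
               tolerance = 1e-9)
  p3 <- cbind(pts, z_above(bar_fixture, 2))
  s1 <- saturated_force(c(0, 1e-14, 0), bar_fixture, p3, M_Am = base_M)
  s2 <- saturated_force(c(0, 1e-14, 0), bar_fixture, p3, M_Am = 2 * base_M)
  expect_equal(s2 / s1, matrix(2, 2, 3), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("saturated force reproduces a hand-built uniform-gradient field", {
  # B = (0, 0, a z): dBz/dz = a, so F = (m . grad)B = m_z * a * z-hat
  a <- 2e-3  # tesla per metre
  fld <- function(p) cbind(0 * p[, 1], 0 * p[, 1], a * p[, 3] * 1e-6)
  m <- c(0, 0, 3e-14)
  F <- saturated_force(m, fld, rbind(c(1, 2, 10), c(-5, 4, 30)))
  expect_equal(F[, "Fz"], rep(m[3] * a, 2), tolerance = 1e-9)
  expect_equal(F[, "Fx"], c(0, 0))
  expect_equal(max(abs(saturated_force(c(0, 0, 0), fld,
                                       matrix(c(0, 0, 5), 1)))), 0)
})

test_that("saturated force with a pole-ward moment points at the pole", {
  zt <- z_above(bar_fixture, 2)
  pt <- matrix(c(0, 115, zt), 1)  # outer region beyond the +y pole
  Vm <- pi / 6 * (2.8e-6)^3
  B <- pattern_field(bar_fixture, pt)
  m <- Vm * B[1, ] / sqrt(sum(B[1, ]^2)) * 4e5  # saturation along local B
  F <- saturated_force(m, bar_fixture, pt)
  expect_lt(F[1, "Fy"], 0)  # attraction back toward y = 100
})

test_that("the in-plane bar has exactly two hot spots at its poles", {
  expect_equal(nrow(bar_hot_spots), 2L)
  expect_lt(max(abs(abs(bar_hot_spots$y_um) - 100)), 5)
  expect_lt(max(abs(bar_hot_spots$x_um)), 5)
  expect_setequal(sign(bar_hot_spots$y_um), c(-1, 1))
})

test_that("hot-spot detection handles zero maps, superposition, refinement", {
  zero <- bar_force_map
  zero$Fx[] <- 0; zero$Fy[] <- 0; zero$Fz[] <- 0; zero$Fnorm[] <- 0
  expect_equal(nrow(find_hot_spots(zero)), 0L)

  two <- build_bar_array(nx = 2, ny = 1, lateral_spacing_um = 300)
  fm2 <- linear_force(two, z_um = 2, xlim = c(-220, 220),
                      ylim = c(-130, 130), spacing_um = 2)
  expect_equal(nrow(find_hot_spots(fm2)), 4L)

  # count is invariant to grid refinement
  fine <- linear_force(bar_fixture, z_um = 2, xlim = c(-30, 30),
                       ylim = c(-125, 125), spacing_um = 0.25)
  expect_equal(nrow(find_hot_spots(fine)), 2L)
  expect_error(find_hot_spots(bar_force_map, rel_threshold = 1.2), "0, 1")
})

test_that("plateau maxima merge to a single centroid hot spot", {
  m <- matrix(0, 21, 21)
  m[10:11, 10:11] <- 1  # 2 x 2 flat-topped plateau
  fm <- list(plane = "xy", axis1 = seq(0, 20), axis2 = seq(0, 20),
             z_um = 2, spacing_um = 1, Fx = m, Fy = 0 * m, Fz = 0 * m,
             Fnorm = m)
  class(fm) <- "force_map"
  hs <- find_hot_spots(fm)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$x_um, 9.5)
  expect_equal(hs$y_um, 9.5)
})

test_that("long-axis / short-axis anisotropy spans three orders of magnitude", {
  expect_equal(anisotropy_ratio(bar_force_map, list(x = 0), list(x = 0)), 0)
  r_map <- anisotropy_ratio(bar_force_map, list(x = 0), list(y = 80))
  expect_gte(r_map, 3)
  r_dense <- anisotropy_ratio(bar_fixture,
                              list(x = 0, range = c(-130, 130)),
                              list(y = 80, range = c(-40, 40)), n = 2001)
  expect_equal(r_map, r_dense, tolerance = 0.02)
  # peak position on the long-axis line matches a dense scan of the map
  j <- which.min(abs(bar_force_map$axis1 - 0))
  i_max <- which.max(bar_force_map$Fnorm[, j])
  pk <- peak_force_on_line(bar_fixture, list(x = 0, range = c(-130, 130)),
                           n = 2001)
  expect_lt(abs(bar_force_map$axis2[i_max] - pk$at), 1)
})

test_that("edge attraction is pole-localized in-plane, global out-of-plane", {
  e_in <- edge_attraction_profile(bar_fixture)
  expect_lt(e_in$fraction, 0.3)
  # the strong-force boundary points cluster at the two short ends
  strong <- e_in$points[e_in$magnitude > 0.5 * max(e_in$magnitude), ,
                        drop = FALSE]
  expect_gt(min(abs(strong[, 2])), 90)

  e_out <- edge_attraction_profile(bar_fixture,
                                   magnetization_direction = c(0, 0, 1))
  expect_gte(e_out$fraction, 0.9)

  # rotating the in-plane magnetization by 90 degrees swaps the hot edges
  e_rot <- edge_attraction_profile(bar_fixture,
                                   magnetization_direction = c(1, 0, 0))
  strong_rot <- e_rot$points[e_rot$magnitude > 0.5 * max(e_rot$magnitude), ,
                             drop = FALSE]
  expect_gt(min(abs(strong_rot[, 1])), 20)  # on the long edges x = +/- 25
})
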