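test_that("prism kernel matches the surface-integration oracle", {
  skip_if_not_installed("pracma")
  mag <- magnet_prism(c(-25, 25), c(-100, 100), c(0, 0.074))
  pts <- rbind(c(10, 120, 3), c(-40, 50, 5), c(30, -110, 1),
               c(5, 99, 0.5), c(0, 0, 2.074))
  B <- prism_field(mag, pts)
  for (i in seq_len(nrow(pts))) {
    Bq <- oracle_prism_field(mag, pts[i, ], n_major = 400, n_minor = 24)
    expect_lt(rel_err(B[i, ], Bq), 1e-6)
  }
  # oblique magnetization exercises all three sheet orientations
  mag2 <- magnet_prism(c(-25, 25), c(-100, 100), c(0, 0.074),
                       c(0.3, 0.8, 0.52) / (4e-7 * pi))
  B2 <- prism_field(mag2, pts[1:3, , drop = FALSE])
  for (i in 1:3) {
    expect_lt(rel_err(B2[i, ], oracle_prism_field(mag2, pts[i, ])), 1e-5)
  }
})

test_that("mirror symmetry and interior rejection hold", {
  mag <- magnet_prism(c(-25, 25), c(-100, 100), c(0, 0.074))
  B <- prism_field(mag, c(0, 0, 2.074))
  expect_equal(unname(B[1, "Bx"]), 0)
  expect_equal(unname(B[1, "Bz"]), 0)
  expect_gt(abs(B[1, "By"]), 0)
  expect_error(prism_field(mag, c(0, 0, 0.03)), "inside")
})

test_that("far field converges to the point dipole within 1%", {
  mag <- magnet_prism(c(-25, 25), c(-100, 100), c(0, 0.074))
  V <- 50e-6 * 200e-6 * 74e-9
  m <- c(0, V * mag$M[2], 0)
  for (pt in list(c(23000, 10000, 15000), c(-25000, 30000, 8000))) {
    Bd <- oracle_dipole_field(m, pt * 1e-6)
    Bp <- prism_field(mag, matrix(pt, 1, 3))
    expect_lt(rel_err(Bp[1, ], Bd), 0.01)
  }
})

test_that("pattern field is the superposition of its prisms", {
  one <- build_bar_array(nx = 1, ny = 1)
  two <- build_bar_array(nx = 2, ny = 1)
  pts <- rbind(c(0, 120, 2), c(-80, 0, 3), c(40, -130, 2))
  Btwo <- pattern_field(two, pts)
  # the two bars of the 2 x 1 array sit at x = -100 and x = +100
  left <- pattern_spec(mm_box(-100, 0, 25, 100), thickness_nm = 74)
  right <- pattern_spec(mm_box(100, 0, 25, 100), thickness_nm = 74)
  Bsum <- pattern_field(left, pts) + pattern_field(right, pts)
  expect_equal(Btwo, Bsum, tolerance = 1e-12)
  # empty pattern: zero field
  B0 <- pattern_field(pattern_spec(list(), unit_cell = c(1, 1)), pts)
  expect_true(all(B0 == 0))
})

test_that("pole field dominates the field above the bar centre", {
  B <- pattern_field(bar_fixture,
                     rbind(c(0, 100, z_above(bar_fixture, 2)),
                           c(0, 0, z_above(bar_fixture, 2))))
  expect_gt(sqrt(sum(B[1, ]^2)) / sqrt(sum(B[2, ]^2)), 10)
})

test_that("field maps have the pattern's reflection symmetries", {
  fm <- field_map(bar_fixture, z_um = 2, xlim = c(-40, 40),
                  ylim = c(-120, 120), spacing_um = 2)
  # |B| symmetric under x -> -x and y -> -y
  expect_equal(fm$Bnorm, fm$Bnorm[, rev(seq_along(fm$axis1))],
               tolerance = 1e-10)
  expect_equal(fm$Bnorm, fm$Bnorm[rev(seq_along(fm$axis2)), ],
               tolerance = 1e-10)
  # |B| peaks within 5 um of the bar ends
  peak <- which(fm$Bnorm == max(fm$Bnorm), arr.ind = TRUE)
  expect_lt(abs(abs(fm$axis2[peak[1, 1]]) - 100), 5)
  expect_error(field_map(bar_fixture, z_um = 0), "above the film")
})

test_that("vertical slice By has symmetric magnitude about y = 0", {
  sl <- field_map(bar_fixture, plane = "yz", at = 0, ylim = c(-120, 120),
                  zlim = c(1, 21), spacing_um = 4)
  expect_equal(abs(sl$By), abs(sl$By)[, rev(seq_along(sl$axis1))],
               tolerance = 1e-10)
})

test_that("stray field is divergence- and curl-free outside the sources", {
  h <- 0.5
  ctr <- expand.grid(x = seq(-10, 10, 5), y = seq(60, 120, 15))
  z0 <- z_above(bar_fixture, 4)
  fld <- function(dx, dy, dz) {
    pattern_field(bar_fixture,
                  cbind(ctr$x + dx, ctr$y + dy, z0 + dz))
  }
  B0 <- fld(0, 0, 0)
  dBdx <- (fld(h, 0, 0) - fld(-h, 0, 0)) / (2 * h)
  dBdy <- (fld(0, h, 0) - fld(0, -h, 0)) / (2 * h)
  dBdz <- (fld(0, 0, h) - fld(0, 0, -h)) / (2 * h)
  scale <- sqrt(rowSums(B0^2)) / h
  div <- dBdx[, 1] + dBdy[, 2] + dBdz[, 3]
  curl <- cbind(dBdy[, 3] - dBdz[, 2],
                dBdz[, 1] - dBdx[, 3],
                dBdx[, 2] - dBdy[, 1])
  expect_lt(max(abs(div) / scale), 1e-3)
  expect_lt(max(sqrt(rowSums(curl^2)) / scale), 1e-3)
})

test_that("thin-film field depends on the product M*t", {
  # halving the thickness at fixed M halves B well above the film
  pts <- rbind(c(0, 110, 10), c(10, 90, 8))
  thin <- build_bar_array(thickness_nm = 37)
  thick <- build_bar_array(thickness_nm = 74)
  B_thin <- pattern_field(thin, pts)
  B_thick <- pattern_field(thick, pts)
  expect_equal(sqrt(rowSums(B_thick^2)) / sqrt(rowSums(B_thin^2)),
               c(2, 2), tolerance = 0.01)
  # doubling M on the thin film reproduces the thick film's field
  B_resc <- pattern_field(thin, pts, M_Am = 2 / (4e-7 * pi))
  expect_equal(sqrt(rowSums(B_resc^2)) / sqrt(rowSums(B_thick^2)),
               c(1, 1), tolerance = 0.01)
})
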