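test_that("terminal velocity implements Stokes drag balance", {
  med <- medium(8.9e-4)
  expect_equal(terminal_velocity(c(0, 0, 0), cell_body(), med), c(0, 0, 0))
  u <- terminal_velocity(c(1e-12, 0, 0), cell_body(10), med)
  expect_equal(u[1], 1e-12 / (3 * pi * 8.9e-4 * 1e-5) * 1e6,
               tolerance = 1e-12)
  expect_equal(u[1], 11.92, tolerance = 0.01)  # ~ 11.9 um/s at 1 pN
  u20 <- terminal_velocity(c(1e-12, 0, 0), cell_body(20), med)
  expect_equal(u[1] / u20[1], 2)
  # linear in F
  expect_equal(terminal_velocity(c(3e-12, 0, 0), cell_body(10), med)[1],
               3 * u[1])
})

test_that("speed ratios follow moment-over-diameter scaling", {
  c1 <- cell_body(10, 1)
  c2 <- cell_body(10, 2)
  free <- magnetic_particle(2.8, 1)
  expect_equal(speed_ratio(c2, c1), 2)
  expect_equal(speed_ratio(free, c1), 10 / 2.8)
  expect_equal(speed_ratio(c1, c1), 1)
  # ratio transitivity
  c3 <- cell_body(10, 5)
  expect_equal(speed_ratio(c3, c2) * speed_ratio(c2, c1),
               speed_ratio(c3, c1))
  expect_error(speed_ratio(c1, cell_body(10, 0)), "zero moment")
})

test_that("trajectories are stationary without force, linear under constant force", {
  still <- simulate_trajectory(cell_body(), function(p) matrix(0, nrow(p), 3),
                               start = c(5, 5), max_time_s = 10)
  expect_true(all(still$x_um == 5) && all(still$y_um == 5))
  expect_equal(attr(still, "status"), "timeout")

  F0 <- 1e-12
  const <- function(p) cbind(rep(F0, nrow(p)), 0, 0)
  tr <- simulate_trajectory(cell_body(10, 1), const, c(0, 0),
                            max_time_s = 10, cap_um = 0.5)
  fit <- estimate_velocity(tr)
  u_expect <- F0 / (3 * pi * 8.9e-4 * 1e-5) * 1e6
  expect_equal(fit$slope_um_s, u_expect, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("cells released near a pole are captured at a hot spot", {
  # calibrate so a cell at the pole peak moves at ~10 um/s
  k <- calibrate_k_lin(10, max(bar_force_map$Fnorm), cell_body(10, 1))
  ff0 <- force_interpolator(bar_force_map)
  ff <- function(p) k * ff0(p)
  tr <- simulate_trajectory(cell_body(10, 1), ff, start = c(0, 130 - 0.5),
                            hot_spots = bar_hot_spots,
                            capture_radius_um = 5, max_time_s = 1e4,
                            scale_by_moment = FALSE)
  expect_equal(attr(tr, "status"), "captured")
  last <- tr[nrow(tr), ]
  d <- min(sqrt((bar_hot_spots$x_um - last$x_um)^2 +
                  (bar_hot_spots$y_um - last$y_um)^2))
  expect_lte(d, 5)
  # |B|^2 is non-decreasing along the path (gradient ascent)
  zt <- z_above(bar_fixture, 2)
  b2 <- rowSums(pattern_field(bar_fixture,
                              cbind(tr$x_um, tr$y_um, zt))^2)
  expect_true(all(diff(b2) > -1e-9 * max(b2)))
})

test_that("halving the displacement cap barely moves endpoints", {
  k <- calibrate_k_lin(10, max(bar_force_map$Fnorm), cell_body(10, 1))
  ff0 <- force_interpolator(bar_force_map)
  ff <- function(p) k * ff0(p)
  ends <- lapply(c(0.5, 0.25), function(cap) {
    tr <- simulate_trajectory(cell_body(10, 1), ff, start = c(20, 60),
                              max_time_s = 30, cap_um = cap,
                              scale_by_moment = FALSE)
    unlist(tr[nrow(tr), c("x_um", "y_um")])
  })
  expect_lt(sqrt(sum((ends[[1]] - ends[[2]])^2)), 0.5)
})

test_that("settle_population separates labeled and unlabeled cells", {
  cells <- data.frame(id = 1:6, n_particles = c(0, 0, 0, 1, 2, 4))
  starts <- data.frame(x_um = c(-30, 10, 25, 5, -10, 15),
                       y_um = c(70, -40, 110, 90, -80, 120))
  ff <- force_interpolator(bar_force_map)
  res <- settle_population(cells, starts, ff, hot_spots = bar_hot_spots,
                           max_time_s = 1e4)
  unl <- res$n_particles == 0
  expect_equal(res$x_um[unl], starts$x_um[unl])
  expect_equal(res$y_um[unl], starts$y_um[unl])
  expect_true(all(res$status[unl] == "unlabeled"))
  expect_true(all(res$status[!unl] == "captured"))
  # captured fraction equals the labeled fraction when basins cover starts
  expect_equal(mean(res$status == "captured"), mean(!unl))
  expect_error(settle_population(cells, starts[1:3, ], ff), "one start")
})

test_that("non-finite forces abort integration with a diagnostic", {
  bad <- function(p) matrix(NaN, nrow(p), 3)
  expect_error(simulate_trajectory(cell_body(), bad, c(1, 2), max_time_s = 5),
               "non-finite force")
})

test_that("k_lin calibration maps arbitrary forces onto observed speeds", {
  k <- calibrate_k_lin(speed_um_s = 10, force_arb = 16.4,
                       body = cell_body(10, 1))
  u <- terminal_velocity(16.4 * k, cell_body(10, 1))
  expect_equal(u, 10, tolerance = 1e-12)
})
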