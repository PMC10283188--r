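# Drag-balance magnetophoresis. At the micrometre scale the Reynolds
# number is << 1, so an object labeled with superparamagnetic particles
# moves at its terminal velocity everywhere: the magnetic force is
# balanced instantaneously by the Stokes drag 3 pi mu D u. Trajectories
# are therefore overdamped gradient dynamics over the force landscape,
# integrated with an adaptive explicit step capped in displacement.

#' Magnetic microparticle
#'
#' @param diameter_um Particle diameter, um (default 2.8, the
#'   streptavidin-coated bead used for membrane labeling).
#' @param moment Magnetic moment parameter (A m^2, or arbitrary units
#'   consistent with the force scale `k_lin`).
#' @return An object of class `magnetic_particle`.
#' @export
magnetic_particle <- function(diameter_um = 2.8, moment = 1) {
  stopifnot_scalar_pos(diameter_um, "diameter_um")
  if (moment < 0) stop("moment must be >= 0", call. = FALSE)
  structure(list(diameter_um = diameter_um, moment = moment),
            class = "magnetic_particle")
}

#' Particle-decorated cell
#'
#' A cell of diameter `D` carrying `n_particles` conjugated beads; its
#' total magnetic moment is `n_particles * particle$moment`, while drag
#' is set by the cell diameter alone (single-diameter Stokes drag; no
#' wall correction).
#'
#' @param diameter_um Cell diameter, um (default 10).
#' @param n_particles Number of conjugated particles (>= 0).
#' @param particle A `magnetic_particle`.
#' @return An object of class `cell_body`.
#' @export
cell_body <- function(diameter_um = 10, n_particles = 1L,
                      particle = magnetic_particle()) {
  stopifnot_scalar_pos(diameter_um, "diameter_um")
  if (n_particles < 0) stop("n_particles must be >= 0", call. = FALSE)
  structure(list(diameter_um = diameter_um,
                 n_particles = as.numeric(n_particles),
                 particle = particle),
            class = "cell_body")
}

total_moment <- function(body) {
  if (inherits(body, "cell_body")) body$n_particles * body$particle$moment
  else body$moment
}
body_diameter <- function(body) body$diameter_um

#' Suspension medium
#'
#' @param viscosity_Pa_s Dynamic viscosity, Pa s. Default 8.9e-4
#'   (water-like culture medium at room temperature); it cancels in every
#'   speed-ratio claim.
#' @return An object of class `mm_medium`.
#' @export
medium <- function(viscosity_Pa_s = 8.9e-4) {
  stopifnot_scalar_pos(viscosity_Pa_s, "viscosity_Pa_s")
  structure(list(viscosity_Pa_s = viscosity_Pa_s), class = "mm_medium")
}

#' Terminal velocity under Stokes drag
#'
#' `u = F / (3 pi mu D)`: the speed at which viscous drag balances the
#' applied magnetic force. Force in newtons gives velocity in um/s.
#'
#' @param force_N Force vector (any length), newtons.
#' @param body A `cell_body` or `magnetic_particle` (sets the drag
#'   diameter).
#' @param med An `mm_medium`.
#' @return Velocity vector, um/s, parallel to the force.
#' @export
#' @examples
#' terminal_velocity(c(1e-12, 0, 0), cell_body(10), medium())  # ~11.9 um/s
terminal_velocity <- function(force_N, body, med = medium()) {
  D_m <- body_diameter(body) * 1e-6
  force_N / (3 * pi * med$viscosity_Pa_s * D_m) * 1e6
}

#' Predicted speed ratio of two bodies in the same field
#'
#' In a shared local field every body's force is proportional to its
#' total moment, so terminal speeds scale as moment over diameter:
#' `ratio = (m_a / D_a) / (m_b / D_b)`. Doubling the conjugated-particle
#' count doubles the speed; a free 2.8 um particle versus a 10 um cell
#' with one particle gives 10/2.8 ~ 3.6.
#'
#' @param body_a,body_b `cell_body` or `magnetic_particle` objects.
#' @return Scalar speed ratio (a over b).
#' @export
#' @examples
#' speed_ratio(cell_body(n_particles = 2), cell_body(n_particles = 1))  # 2
#' speed_ratio(magnetic_particle(), cell_body(n_particles = 1))         # 10/2.8
speed_ratio <- function(body_a, body_b) {
  mb <- total_moment(body_b)
  if (mb == 0) stop("speed ratio undefined: body_b has zero moment",
                    call. = FALSE)
  (total_moment(body_a) / body_diameter(body_a)) /
    (mb / body_diameter(body_b))
}

#' Nanoparticle volume equivalence of a microparticle
#'
#' How many small magnetic nanoparticles share the volume of one
#' microparticle: `(D_micro / d_nano)^3`. One 2.8 um bead is worth about
#' 1.8e5 nanoparticles of 50 nm, which is why membrane-bound microbeads
#' give cells a far larger magnetic response than nanoparticle uptake.
#'
#' @param particle_diameter_um Microparticle diameter, um.
#' @param nanoparticle_diameter_nm Nanoparticle diameter, nm.
#' @return Scalar count.
#' @export
nanoparticle_equivalence <- function(particle_diameter_um = 2.8,
                                     nanoparticle_diameter_nm = 50) {
  stopifnot_scalar_pos(particle_diameter_um, "particle_diameter_um")
  stopifnot_scalar_pos(nanoparticle_diameter_nm, "nanoparticle_diameter_nm")
  (particle_diameter_um * 1000 / nanoparticle_diameter_nm)^3
}

#' Calibrate the linear force coefficient from one observed speed
#'
#' Maps an observed terminal speed at a point with known arbitrary-unit
#' force magnitude to the absolute `k_lin` scale.
#'
#' @param speed_um_s Observed speed, um/s.
#' @param force_arb Arbitrary-unit force magnitude at the same point
#'   (from a `k_lin = 1` map).
#' @param body The moving body.
#' @param med An `mm_medium`.
#' @return Scalar: multiply arbitrary-unit forces by this to get newtons.
#' @export
calibrate_k_lin <- function(speed_um_s, force_arb, body, med = medium()) {
  stopifnot_scalar_pos(force_arb, "force_arb")
  D_m <- body_diameter(body) * 1e-6
  (speed_um_s * 1e-6) * 3 * pi * med$viscosity_Pa_s * D_m / force_arb
}

#' Integrate an overdamped magnetophoretic trajectory
#'
#' Explicit adaptive stepping of `x' = F(x) / (3 pi mu D)` with each
#' step's displacement capped at `cap_um`, so the path resolves the force
#' landscape's feature scale. Stops on hot-spot capture (within
#' `capture_radius_um` of any supplied hot spot), on leaving `domain`, or
#' at `max_time_s`. The track is reported at fixed intervals of
#' `report_dt_s` (1 s, mirroring time-lapse frame increments).
#'
#' @param body A `cell_body` or `magnetic_particle`.
#' @param force_fn `function(points_xy) -> n x 3` forces (newtons, or
#'   arbitrary units — then time units are arbitrary too). Forces on a
#'   cell are its per-unit-moment force times `total_moment(body)` if
#'   `scale_by_moment` is `TRUE`.
#' @param start Length-2 start position, um.
#' @param med An `mm_medium`.
#' @param hot_spots Optional data.frame with `x_um`, `y_um`.
#' @param capture_radius_um Capture distance, um (default 5, one cell
#'   radius).
#' @param max_time_s Time budget.
#' @param domain `c(xmin, xmax, ymin, ymax)` or `NULL`.
#' @param cap_um Per-step displacement cap, um.
#' @param report_dt_s Reporting interval, s.
#' @param max_steps Hard cap on integration steps (stops with status
#'   `"step_limit"` if exceeded; a diagnostic for stalled dynamics).
#' @param scale_by_moment Multiply forces by the body's total moment
#'   (default `TRUE`; supply `FALSE` when `force_fn` already includes it).
#' @param noise_sigma_um Optional Gaussian displacement noise per
#'   reported frame (default 0, the deterministic model); requires
#'   `seed`.
#' @param seed Seed for the optional noise.
#' @return A data.frame track (`t_s`, `x_um`, `y_um`) with attributes
#'   `status` (`"captured"`, `"exited"`, `"timeout"`) and `hot_spot`
#'   (index or `NA`).
#' @export
simulate_trajectory <- function(body, force_fn, start, med = medium(),
                                hot_spots = NULL, capture_radius_um = 5,
                                max_time_s = 600, domain = NULL,
                                cap_um = 0.5, report_dt_s = 1,
                                scale_by_moment = TRUE,
                                noise_sigma_um = 0, seed = NULL,
                                max_steps = 2e5) {
  stopifnot_scalar_pos(cap_um, "cap_um")
  stopifnot_scalar_pos(report_dt_s, "report_dt_s")
  mob <- 1 / (3 * pi * med$viscosity_Pa_s * body_diameter(body) * 1e-6) * 1e6
  mom <- if (scale_by_moment) total_moment(body) else 1
  pos <- as.numeric(start)
  t_now <- 0
  out_t <- 0; out_x <- pos[1]; out_y <- pos[2]
  status <- "timeout"; hit <- NA_integer_
  noise <- NULL
  if (noise_sigma_um > 0) {
    n_frames <- ceiling(max_time_s / report_dt_s) + 1L
    noise <- with_seed(seed, matrix(stats::rnorm(2L * n_frames, 0,
                                                 noise_sigma_um),
                                    ncol = 2L))
  }
  check_stop <- function(pos) {
    if (!is.null(hot_spots) && nrow(hot_spots) > 0L) {
      d2 <- (hot_spots$x_um - pos[1])^2 + (hot_spots$y_um - pos[2])^2
      i <- which.min(d2)
      if (d2[i] <= capture_radius_um^2) return(list("captured", i))
    }
    if (!is.null(domain) &&
        (pos[1] < domain[1] || pos[1] > domain[2] ||
         pos[2] < domain[3] || pos[2] > domain[4])) {
      return(list("exited", NA_integer_))
    }
    NULL
  }
  st <- check_stop(pos)
  frame <- 1L
  n_steps <- 0L
  while (is.null(st) && t_now < max_time_s && n_steps < max_steps) {
    t_frame_end <- min(t_now + report_dt_s, max_time_s)
    while (t_now < t_frame_end && n_steps < max_steps) {
      n_steps <- n_steps + 1L
      F <- force_fn(matrix(pos, 1L, 2L))[1, ]
      if (any(!is.finite(F))) {
        stop(sprintf("non-finite force at (%.3g, %.3g)", pos[1], pos[2]),
             call. = FALSE)
      }
      u <- mob * mom * F[1:2]           # um/s in-plane
      sp <- sqrt(sum(u^2))
      if (sp * (t_frame_end - t_now) < 1e-12) { t_now <- t_frame_end; break }
      dt <- min(t_frame_end - t_now, cap_um / sp)
      pos <- pos + u * dt
      t_now <- t_now + dt
      st <- check_stop(pos)
      if (!is.null(st)) break
    }
    if (!is.null(noise)) {
      frame <- frame + 1L
      pos <- pos + noise[min(frame, nrow(noise)), ]
      st <- st %||% check_stop(pos)
    }
    out_t <- c(out_t, t_now); out_x <- c(out_x, pos[1]); out_y <- c(out_y, pos[2])
    if (!is.null(st)) { status <- st[[1]]; hit <- st[[2]]; break }
    if (n_steps >= max_steps) status <- "step_limit"
  }
  track <- data.frame(t_s = out_t, x_um = out_x, y_um = out_y)
  attr(track, "status") <- status
  attr(track, "hot_spot") <- hit
  track
}

#' Settle a cell population over a force landscape
#'
#' Runs [simulate_trajectory()] for every cell; cells with zero particles
#' feel no magnetic force and stay at their start (the uniformly
#' dispersed control).
#'
#' @param cells data.frame with `id` and `n_particles`.
#' @param start_positions data.frame with `x_um`, `y_um` (one row per
#'   cell).
#' @param force_fn Per-unit-moment force function (see
#'   [simulate_trajectory()]).
#' @param med,hot_spots,capture_radius_um,max_time_s,domain,cap_um
#'   Passed through.
#' @param particle The `magnetic_particle` carried by labeled cells.
#' @param cell_diameter_um Cell diameter, um.
#' @return data.frame `id`, `n_particles`, `x0_um`, `y0_um`, `x_um`,
#'   `y_um`, `status`, `hot_spot`.
#' @export
settle_population <- function(cells, start_positions, force_fn,
                              med = medium(), hot_spots = NULL,
                              capture_radius_um = 5, max_time_s = 600,
                              domain = NULL, cap_um = 0.5,
                              particle = magnetic_particle(),
                              cell_diameter_um = 10) {
  n <- nrow(cells)
  if (nrow(start_positions) != n) {
    stop("one start position is required per cell", call. = FALSE)
  }
  res <- vector("list", n)
  for (i in seq_len(n)) {
    np <- cells$n_particles[i]
    x0 <- start_positions$x_um[i]; y0 <- start_positions$y_um[i]
    if (np <= 0) {
      res[[i]] <- data.frame(id = cells$id[i], n_particles = np,
                             x0_um = x0, y0_um = y0, x_um = x0, y_um = y0,
                             status = "unlabeled", hot_spot = NA_integer_)
      next
    }
    body <- cell_body(cell_diameter_um, np, particle)
    tr <- simulate_trajectory(body, force_fn, c(x0, y0), med, hot_spots,
                              capture_radius_um, max_time_s, domain, cap_um)
    last <- tr[nrow(tr), ]
    res[[i]] <- data.frame(id = cells$id[i], n_particles = np,
                           x0_um = x0, y0_um = y0,
                           x_um = last$x_um, y_um = last$y_um,
                           status = attr(tr, "status"),
                           hot_spot = attr(tr, "hot_spot"))
  }
  do.call(rbind, res)
}

#' Bilinear force interpolator over a force map
#'
#' Precomputing the force on a grid and interpolating makes population
#' settling cheap; outside the grid the force is zero.
#'
#' @param force_map A `force_map`.
#' @return `function(points_xy) -> n x 3` forces.
#' @export
force_interpolator <- function(force_map) {
  ax <- force_map$axis1; ay <- force_map$axis2
  interp1 <- function(M, x, y) {
    ix <- findInterval(x, ax, all.inside = TRUE)
    iy <- findInterval(y, ay, all.inside = TRUE)
    x1 <- ax[ix]; x2 <- ax[ix + 1L]; y1 <- ay[iy]; y2 <- ay[iy + 1L]
    wx <- (x - x1) / (x2 - x1); wy <- (y - y1) / (y2 - y1)
    (1 - wx) * (1 - wy) * M[cbind(iy, ix)] +
      wx * (1 - wy) * M[cbind(iy, ix + 1L)] +
      (1 - wx) * wy * M[cbind(iy + 1L, ix)] +
      wx * wy * M[cbind(iy + 1L, ix + 1L)]
  }
  function(points_xy) {
    pts <- if (is.null(dim(points_xy))) matrix(points_xy, ncol = 2L)
           else as.matrix(points_xy)
    x <- pts[, 1]; y <- pts[, 2]
    inb <- x >= ax[1] & x <= ax[length(ax)] & y >= ay[1] & y <= ay[length(ay)]
    F <- matrix(0, nrow(pts), 3L, dimnames = list(NULL, c("Fx", "Fy", "Fz")))
    if (any(inb)) {
      F[inb, 1] <- interp1(force_map$Fx, x[inb], y[inb])
      F[inb, 2] <- interp1(force_map$Fy, x[inb], y[inb])
      F[inb, 3] <- interp1(force_map$Fz, x[inb], y[inb])
    }
    F
  }
}
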