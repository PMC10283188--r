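# Attraction-force landscapes for superparamagnetic particles. In the
# linear (sub-saturation) regime the particle moment is proportional to B,
# so F = k_lin (B . grad) B; because curl B = 0 outside the sources this
# equals k_lin grad(|B|^2)/2, and both forms are implemented as independent
# finite-difference routes and cross-checked. The absolute particle
# susceptibility and induced pattern magnetization are not pinned down by
# the study, so k_lin defaults to 1 (arbitrary force units): hot-spot
# structure, anisotropy ratios, and speed ratios are all scale-free.

#' Force evaluator over a pattern's stray field
#'
#' Returns a function mapping in-plane points (n x 2, um) at a fixed
#' height to 3-vector forces, computed by central differences of the
#' analytic field with step `h_um`.
#'
#' @param pattern A `pattern_spec`.
#' @param z_um Evaluation height above the film top, um (default 2).
#' @param k_lin Lumped linear-response coefficient
#'   (particle volume x susceptibility / mu0); arbitrary units by default.
#' @param M_Am Magnetization magnitude, A/m.
#' @param h_um Finite-difference step, um.
#' @param form `"gradB2"` (k/2 grad |B|^2, default) or `"BgradB"`
#'   (directional derivative form, (B . grad) B).
#' @return `function(points_xy) -> n x 3 matrix` of forces.
#' @export
force_function <- function(pattern, z_um = 2, k_lin = 1, M_Am = 1 / MU0,
                           h_um = 0.05, form = c("gradB2", "BgradB")) {
  form <- match.arg(form)
  zs <- z_above(pattern, z_um)
  fld <- function(pts3) pattern_field(pattern, pts3, M_Am,
                                      check_interior = FALSE)
  h <- h_um
  function(points_xy) {
    pts <- if (is.null(dim(points_xy))) matrix(points_xy, ncol = 2L)
           else as.matrix(points_xy)
    p3 <- cbind(pts[, 1], pts[, 2], zs)
    if (form == "gradB2") {
      b2 <- function(p) rowSums(fld(p)^2)
      gx <- (b2(shift3(p3, 1, h)) - b2(shift3(p3, 1, -h))) / (2 * h)
      gy <- (b2(shift3(p3, 2, h)) - b2(shift3(p3, 2, -h))) / (2 * h)
      gz <- (b2(shift3(p3, 3, h)) - b2(shift3(p3, 3, -h))) / (2 * h)
      F <- k_lin / 2 * cbind(gx, gy, gz) * 1e6  # d/d(um) -> d/d(m)
    } else {
      B0 <- fld(p3)
      dBdx <- (fld(shift3(p3, 1, h)) - fld(shift3(p3, 1, -h))) / (2 * h)
      dBdy <- (fld(shift3(p3, 2, h)) - fld(shift3(p3, 2, -h))) / (2 * h)
      dBdz <- (fld(shift3(p3, 3, h)) - fld(shift3(p3, 3, -h))) / (2 * h)
      F <- k_lin * (B0[, 1] * dBdx + B0[, 2] * dBdy + B0[, 3] * dBdz) * 1e6
    }
    colnames(F) <- c("Fx", "Fy", "Fz")
    F
  }
}

new_force_map <- function(axis1, axis2, z_um, spacing_um, Fx, Fy, Fz) {
  out <- list(plane = "xy", axis1 = axis1, axis2 = axis2, z_um = z_um,
              spacing_um = spacing_um, Fx = Fx, Fy = Fy, Fz = Fz,
              Fnorm = sqrt(Fx^2 + Fy^2 + Fz^2))
  class(out) <- "force_map"
  out
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("force_map: %d x %d at %.3g um, z = %.3g um, max |F| = %.4g\n",
              length(x$axis1), length(x$axis2), x$spacing_um, x$z_um,
              max(x$Fnorm)))
  invisible(x)
}

#' Linear-regime force map
#'
#' Converts a stray-field description into an attraction-force map,
#' `F = k_lin (B . grad) B = k_lin grad(|B|^2)/2`. Given a sampled
#' horizontal `field_grid`, derivatives are in-plane central differences
#' of `|B|^2` on the grid (vertical force omitted, `Fz = 0`); given a
#' `pattern_spec`, the full 3-D force is evaluated from the analytic
#' field on a grid.
#'
#' @param field A `field_grid` or a `pattern_spec`.
#' @param k_lin Linear coefficient (see [force_function()]).
#' @param z_um,xlim,ylim,spacing_um Grid specification for the
#'   `pattern_spec` route.
#' @param form Difference form for the `pattern_spec` route.
#' @return A `force_map`.
#' @export
linear_force <- function(field, k_lin = 1, ...) UseMethod("linear_force")

#' @rdname linear_force
#' @export
linear_force.field_grid <- function(field, k_lin = 1, ...) {
  if (field$plane != "xy") {
    stop("force maps are computed on horizontal planes", call. = FALSE)
  }
  # the sharpest field features above a thin film vary on the scale of the
  # evaluation height, so differencing needs spacing well below it
  if (is.finite(field$z_um) && field$spacing_um > field$z_um) {
    warning(sprintf(
      "grid spacing (%.3g um) exceeds the evaluation height (%.3g um); force differencing may be unstable",
      field$spacing_um, field$z_um), call. = FALSE)
  }
  h <- field$spacing_um * 1e-6
  B2 <- field$Bx^2 + field$By^2 + field$Bz^2
  gx <- ddx(B2, h)  # along axis1 = columns
  gy <- ddy(B2, h)
  new_force_map(field$axis1, field$axis2, field$z_um, field$spacing_um,
                k_lin / 2 * gx, k_lin / 2 * gy, 0 * gx)
}

#' @rdname linear_force
#' @export
linear_force.pattern_spec <- function(field, k_lin = 1, z_um = 2,
                                      xlim = NULL, ylim = NULL,
                                      spacing_um = 1, M_Am = 1 / MU0,
                                      h_um = 0.05,
                                      form = c("gradB2", "BgradB"), ...) {
  form <- match.arg(form)
  bb <- pattern_bbox(field)
  xlim <- xlim %||% (bb[c(1, 2)] + c(-30, 30))
  ylim <- ylim %||% (bb[c(3, 4)] + c(-30, 30))
  ax1 <- seq(xlim[1], xlim[2], by = spacing_um)
  ax2 <- seq(ylim[1], ylim[2], by = spacing_um)
  g <- expand.grid(x = ax1, y = ax2)
  ff <- force_function(field, z_um, k_lin, M_Am, h_um, form)
  F <- ff(cbind(g$x, g$y))
  n1 <- length(ax1); n2 <- length(ax2)
  shp <- function(v) matrix(v, nrow = n2, ncol = n1, byrow = TRUE)
  new_force_map(ax1, ax2, z_um, spacing_um,
                shp(F[, 1]), shp(F[, 2]), shp(F[, 3]))
}

shift3 <- function(p, axis, d) { p[, axis] <- p[, axis] + d; p }

# column-wise / row-wise central differences (one-sided at borders)
ddx <- function(m, h) {
  n <- ncol(m)
  out <- m
  out[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / (2 * h)
  out[, 1] <- (m[, 2] - m[, 1]) / h
  out[, n] <- (m[, n] - m[, n - 1]) / h
  out
}
ddy <- function(m, h) t(ddx(t(m), h))

#' Saturated-regime force on a fixed-moment particle
#'
#' Above saturation the particle moment `m` is constant and
#' `F = (m . grad) B`, evaluated by central differences of the analytic
#' pattern field. With `m` proportional to `B` this reduces to the linear
#' form divided by `k_lin`.
#'
#' @param m_Am2 Magnetic moment vector, A m^2 (length 3).
#' @param field A `pattern_spec`, or a field function
#'   `function(points_um) -> n x 3` B matrix (tesla).
#' @param points_um n x 3 evaluation points, um.
#' @param M_Am Pattern magnetization, A/m (pattern route).
#' @param h_um Difference step, um.
#' @return n x 3 matrix of forces, newtons.
#' @export
saturated_force <- function(m_Am2, field, points_um, M_Am = 1 / MU0,
                            h_um = 0.05) {
  pts <- as_points3(points_um)
  if (inherits(field, "pattern_spec")) {
    t_um <- field$thickness_nm * 1e-3
    d <- pattern_distance(field, pts[, 1], pts[, 2])
    if (any(d <= 0 & pts[, 3] >= 0 & pts[, 3] <= t_um)) {
      stop("evaluation point inside the magnet film", call. = FALSE)
    }
    fld <- function(p) pattern_field(field, p, M_Am, check_interior = FALSE)
  } else if (is.function(field)) {
    fld <- field
  } else {
    stop("field must be a pattern_spec or a function", call. = FALSE)
  }
  h <- h_um
  dBdx <- (fld(shift3(pts, 1, h)) - fld(shift3(pts, 1, -h))) / (2 * h)
  dBdy <- (fld(shift3(pts, 2, h)) - fld(shift3(pts, 2, -h))) / (2 * h)
  dBdz <- (fld(shift3(pts, 3, h)) - fld(shift3(pts, 3, -h))) / (2 * h)
  F <- (m_Am2[1] * dBdx + m_Am2[2] * dBdy + m_Am2[3] * dBdz) * 1e6
  colnames(F) <- c("Fx", "Fy", "Fz")
  F
}

#' Detect magnetic hot spots in a force map
#'
#' Hot spots are strict local maxima of the force-magnitude layer above
#' `rel_threshold` times the global maximum; equal-valued neighbouring
#' maxima (plateaus) are merged to their centroid. For the in-plane
#' magnetized bar this yields the two attraction poles at the bar ends.
#'
#' @param force_map A `force_map`.
#' @param rel_threshold Fraction of the global maximum below which maxima
#'   are ignored, in (0, 1); default 0.05.
#' @param connectivity 8 (default) or 4.
#' @return data.frame with `id`, `x_um`, `y_um`, `magnitude`; zero rows
#'   for an all-zero map.
#' @export
find_hot_spots <- function(force_map, rel_threshold = 0.05,
                           connectivity = 8L) {
  if (rel_threshold <= 0 || rel_threshold >= 1) {
    stop("rel_threshold must be in (0, 1)", call. = FALSE)
  }
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8",
                                         call. = FALSE)
  m <- force_map$Fnorm
  empty <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      magnitude = numeric())
  gmax <- max(m)
  if (gmax <= 0) return(empty)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  offs <- if (connectivity == 8L) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  ge_all <- matrix(TRUE, nr, nc)   # >= all neighbours
  gt_any <- matrix(FALSE, nr, nc)  # > at least one neighbour (no full plateau)
  for (o in offs) {
    nb <- pad[2:(nr + 1L) + o[1], 2:(nc + 1L) + o[2]]
    ge_all <- ge_all & (core >= nb)
    gt_any <- gt_any | (core > nb)
  }
  cand <- which(ge_all & gt_any & core >= rel_threshold * gmax,
                arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  # merge candidates that are grid-adjacent with equal value (plateaus)
  n <- nrow(cand)
  comp <- seq_len(n)
  if (n > 1L) {
    for (a in 1:(n - 1L)) {
      for (b in (a + 1L):n) {
        if (max(abs(cand[a, ] - cand[b, ])) <= 1L &&
            m[cand[a, 1], cand[a, 2]] == m[cand[b, 1], cand[b, 2]]) {
          comp[comp == comp[b]] <- comp[a]
        }
      }
    }
  }
  groups <- split(seq_len(n), comp)
  res <- do.call(rbind, lapply(seq_along(groups), function(k) {
    idx <- groups[[k]]
    rows <- cand[idx, 1]; cols <- cand[idx, 2]
    data.frame(id = k,
               x_um = mean(force_map$axis1[cols]),
               y_um = mean(force_map$axis2[rows]),
               magnitude = m[cand[idx[1], 1], cand[idx[1], 2]])
  }))
  res <- res[order(-res$magnitude), , drop = FALSE]
  res$id <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Peak force magnitude along a sampling line
#'
#' Samples `|F|` densely along a horizontal line (constant x or constant
#' y) at the map height, using the analytic field.
#'
#' @param pattern A `pattern_spec`.
#' @param line `list(x = x0, range = c(lo, hi))` for a constant-x line
#'   sweeping y, or `list(y = y0, range = c(lo, hi))` for constant y.
#' @param z_um Height above the film top, um.
#' @param n Number of samples.
#' @param k_lin,M_Am Force scaling (cancels in ratios).
#' @return List with `peak`, `at` (position of the maximum, um), and the
#'   sampled `s`, `magnitude` vectors.
#' @export
peak_force_on_line <- function(pattern, line, z_um = 2, n = 2001,
                               k_lin = 1, M_Am = 1 / MU0) {
  ff <- force_function(pattern, z_um, k_lin, M_Am)
  s <- seq(line$range[1], line$range[2], length.out = n)
  pts <- if (!is.null(line$x)) cbind(line$x, s) else cbind(s, line$y)
  mag <- sqrt(rowSums(ff(pts)^2))
  i <- which.max(mag)
  list(peak = mag[i], at = s[i], s = s, magnitude = mag)
}

#' Long-axis / short-axis force anisotropy
#'
#' Base-10 logarithm of the ratio between peak force magnitudes on two
#' sampling lines. For a `force_map`, the nearest grid column/row is
#' extracted; for a `pattern_spec`, lines are sampled densely from the
#' analytic field (preferred near the sharp pole peaks).
#'
#' @param x A `force_map` or `pattern_spec`.
#' @param line_a,line_b `list(x = x0)` or `list(y = y0)`; for the pattern
#'   route each also needs a `range`.
#' @param ... Passed to [peak_force_on_line()] for the pattern route.
#' @return `log10(peak_a / peak_b)`; `Inf` (with a warning) when the
#'   denominator peak is zero.
#' @export
anisotropy_ratio <- function(x, line_a, line_b, ...) {
  UseMethod("anisotropy_ratio")
}

#' @rdname anisotropy_ratio
#' @export
anisotropy_ratio.force_map <- function(x, line_a, line_b, ...) {
  peak <- function(line) {
    if (!is.null(line$x)) {
      j <- which.min(abs(x$axis1 - line$x))
      max(x$Fnorm[, j])
    } else if (!is.null(line$y)) {
      i <- which.min(abs(x$axis2 - line$y))
      max(x$Fnorm[i, ])
    } else stop("line must specify x or y", call. = FALSE)
  }
  pa <- peak(line_a); pb <- peak(line_b)
  if (pb == 0) {
    warning("zero peak on line_b: infinite anisotropy ratio")
    return(Inf)
  }
  log10(pa / pb)
}

#' @rdname anisotropy_ratio
#' @export
anisotropy_ratio.pattern_spec <- function(x, line_a, line_b, ...) {
  pa <- peak_force_on_line(x, line_a, ...)$peak
  pb <- peak_force_on_line(x, line_b, ...)$peak
  if (pb == 0) {
    warning("zero peak on line_b: infinite anisotropy ratio")
    return(Inf)
  }
  log10(pa / pb)
}

#' Fraction of the pattern boundary under strong attraction
#'
#' Samples `|F|` at the pattern height `z_um` directly above points along
#' every shape boundary and reports the fraction exceeding half the
#' boundary maximum. Out-of-plane magnetization charges the whole top
#' face, so all edges attract (fraction near 1); in-plane magnetization
#' charges only the end faces, confining attraction to the poles.
#'
#' @param pattern A `pattern_spec`.
#' @param magnetization_direction Optional override of the pattern's
#'   direction.
#' @param z_um Height above the film top, um.
#' @param spacing_um Boundary sampling interval, um.
#' @return List with `fraction`, plus the sampled `points` and
#'   `magnitude`.
#' @export
edge_attraction_profile <- function(pattern, magnetization_direction = NULL,
                                    z_um = 2, spacing_um = 2) {
  if (!is.null(magnetization_direction)) {
    pattern <- pattern_spec(pattern$shapes, pattern$unit_cell,
                            pattern$thickness_nm, magnetization_direction)
  }
  pts <- do.call(rbind, lapply(pattern$shapes, function(b) {
    per <- box_perimeter(b)
    npt <- max(8L, ceiling(per / spacing_um))
    tt <- seq(0, per, length.out = npt + 1L)[-(npt + 1L)]
    # walk the rectangle boundary in the local frame
    u <- numeric(npt); v <- numeric(npt)
    L1 <- 2 * b$hx; L2 <- 2 * b$hy
    for (i in seq_len(npt)) {
      d <- tt[i]
      if (d < L1) { u[i] <- -b$hx + d; v[i] <- -b$hy }
      else if (d < L1 + L2) { u[i] <- b$hx; v[i] <- -b$hy + (d - L1) }
      else if (d < 2 * L1 + L2) { u[i] <- b$hx - (d - L1 - L2); v[i] <- b$hy }
      else { u[i] <- -b$hx; v[i] <- b$hy - (d - 2 * L1 - L2) }
    }
    s <- sin(b$theta); co <- cos(b$theta)
    cbind(b$cx + co * u - s * v, b$cy + s * u + co * v)
  }))
  ff <- force_function(pattern, z_um)
  mag <- sqrt(rowSums(ff(pts)^2))
  list(fraction = mean(mag > 0.5 * max(mag)), points = pts, magnitude = mag)
}
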