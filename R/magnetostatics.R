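# Stray field of uniformly magnetized rectangular prisms, via the
# equivalent surface-magnetic-charge model: a prism with magnetization M
# carries charge sheets sigma = +/- (M . n) on the two faces normal to each
# magnetization component, and B outside the material is the superposition
# of the sheet fields, which have a closed corner-sum form (log/arctan
# terms). SI units internally (tesla, A/m, metres); micrometres at the
# interface. This replaces a finite-element field solve: the film is thin
# (tens of nm) but the analytic kernel is exact at true thickness, so no
# thickness/magnetization rescaling is needed.

MU0 <- 4e-7 * pi

#' Uniformly magnetized rectangular prism
#'
#' @param xlim_um,ylim_um Footprint bounds `c(lo, hi)`, um.
#' @param zlim_um Vertical extent `c(lo, hi)`, um (film thickness interval).
#' @param M_Am Magnetization vector, A/m (length 3). The permalloy default
#'   corresponds to mu0*M = 1 T along y-hat.
#' @return An object of class `mm_magnet`.
#' @export
magnet_prism <- function(xlim_um, ylim_um, zlim_um,
                         M_Am = c(0, 1, 0) / MU0) {
  if (diff(xlim_um) <= 0 || diff(ylim_um) <= 0 || diff(zlim_um) <= 0) {
    stop("prism must have positive extent on every axis", call. = FALSE)
  }
  M_Am <- as.numeric(M_Am)
  if (length(M_Am) != 3L || !all(is.finite(M_Am))) {
    stop("M_Am must be a finite length-3 vector", call. = FALSE)
  }
  structure(list(xlim = xlim_um, ylim = ylim_um, zlim = zlim_um, M = M_Am),
            class = "mm_magnet")
}

# Field of one uniformly charged rectangular sheet lying in the plane
# z' = zf, spanning [x1,x2] x [y1,y2], with magnetic surface charge sigma
# (A/m). All lengths in metres. For points within 1 nm of the sheet plane
# the normal component is set to its exact two-sided limit, 0 (valid
# outside the sheet footprint; points on the sheet itself are inside
# material, where the charge-sheet field is not defined anyway) -- this
# keeps evaluations on symmetry planes exactly symmetric.
sheet_field_z <- function(px, py, pz, x1, x2, y1, y2, zf, sigma) {
  Z <- pz - zf
  nudge <- 1e-9
  in_plane <- abs(Z) < nudge
  Z[in_plane] <- nudge
  Bx <- 0; By <- 0; Bz <- 0
  for (i in 1:2) {
    X <- px - (if (i == 1) x1 else x2)
    for (j in 1:2) {
      Y <- py - (if (j == 1) y1 else y2)
      s <- if ((i + j) %% 2 == 0) 1 else -1
      R <- sqrt(X * X + Y * Y + Z * Z)
      Bx <- Bx - s * log(pmax(Y + R, 1e-300))
      By <- By - s * log(pmax(X + R, 1e-300))
      Bz <- Bz + s * atan((X * Y) / (Z * R))
    }
  }
  Bz[in_plane] <- 0
  k <- MU0 * sigma / (4 * pi)
  cbind(k * Bx, k * By, k * Bz)
}

# Sheet with arbitrary normal axis: relabel world coordinates so the sheet
# normal becomes the local z, evaluate, map B components back (the sheet
# field derives from a scalar potential, so handedness of the relabeling
# is immaterial). normal = 1 (x): local (x',y',z') = (y, z, x);
# normal = 2 (y): (x, z, y). lim_a/lim_b are the extents of the first/second
# remaining world axes in ascending order.
sheet_field <- function(points, normal, c0, lim_a, lim_b, sigma) {
  px <- points[, 1]; py <- points[, 2]; pz <- points[, 3]
  if (normal == 3L) {
    return(sheet_field_z(px, py, pz, lim_a[1], lim_a[2], lim_b[1], lim_b[2],
                         c0, sigma))
  }
  if (normal == 1L) {
    B <- sheet_field_z(py, pz, px, lim_a[1], lim_a[2], lim_b[1], lim_b[2],
                       c0, sigma)
    return(cbind(B[, 3], B[, 1], B[, 2]))
  }
  B <- sheet_field_z(px, pz, py, lim_a[1], lim_a[2], lim_b[1], lim_b[2],
                     c0, sigma)
  cbind(B[, 1], B[, 3], B[, 2])
}

#' Stray field of a magnetized prism at exterior points
#'
#' Evaluates the flux density of the equivalent-charge model. Each nonzero
#' magnetization component contributes a pair of oppositely charged sheets
#' on the corresponding faces.
#'
#' @param magnet An `mm_magnet`.
#' @param points_um n x 3 matrix of evaluation points, um.
#' @param check_interior If `TRUE` (default), error when a point lies
#'   inside the prism, where the charge-sheet field is not the material
#'   flux density.
#' @return n x 3 matrix of B vectors, tesla.
#' @export
prism_field <- function(magnet, points_um, check_interior = TRUE) {
  pts <- as_points3(points_um)
  if (check_interior) {
    inside <- pts[, 1] > magnet$xlim[1] & pts[, 1] < magnet$xlim[2] &
      pts[, 2] > magnet$ylim[1] & pts[, 2] < magnet$ylim[2] &
      pts[, 3] > magnet$zlim[1] & pts[, 3] < magnet$zlim[2]
    if (any(inside)) {
      stop(sprintf("%d evaluation point(s) lie inside the prism", sum(inside)),
           call. = FALSE)
    }
  }
  p <- pts * 1e-6
  xl <- magnet$xlim * 1e-6; yl <- magnet$ylim * 1e-6; zl <- magnet$zlim * 1e-6
  lims <- list(xl, yl, zl)
  B <- matrix(0, nrow(p), 3L)
  for (axis in 1:3) {
    Mc <- magnet$M[axis]
    if (Mc == 0) next
    others <- setdiff(1:3, axis)
    B <- B +
      sheet_field(p, axis, lims[[axis]][2], lims[[others[1]]],
                  lims[[others[2]]], +Mc) +
      sheet_field(p, axis, lims[[axis]][1], lims[[others[1]]],
                  lims[[others[2]]], -Mc)
  }
  colnames(B) <- c("Bx", "By", "Bz")
  B
}

as_points3 <- function(points_um) {
  pts <- if (is.null(dim(points_um))) matrix(points_um, ncol = 3L)
         else as.matrix(points_um)
  if (ncol(pts) != 3L) stop("points must be n x 3 (x, y, z in um)", call. = FALSE)
  storage.mode(pts) <- "double"
  pts
}

#' Decompose a pattern into magnetized prisms
#'
#' Each oriented box becomes a prism spanning the film thickness
#' `[0, thickness]`, magnetized along the pattern's direction with
#' magnitude `M_Am`. Rotated boxes are handled at evaluation time by
#' rotating points and field.
#'
#' @keywords internal
pattern_prisms <- function(pattern, M_Am) {
  t_um <- pattern$thickness_nm * 1e-3
  dir <- pattern$magnetization_direction
  lapply(pattern$shapes, function(b) {
    list(box = b,
         magnet = magnet_prism(c(-b$hx, b$hx), c(-b$hy, b$hy), c(0, t_um),
                               M_Am * rotate_dir(dir, -b$theta)))
  })
}

# Rotate the in-plane part of a 3-vector by angle (radians).
rotate_dir <- function(v, angle) {
  s <- sin(angle); co <- cos(angle)
  c(co * v[1] - s * v[2], s * v[1] + co * v[2], v[3])
}

#' Stray field of a whole pattern
#'
#' Superposes the prism fields of every shape in the pattern. The film
#' occupies `z` in `[0, thickness]`; evaluation points are in absolute
#' coordinates with `z` measured from the substrate (so "2 um above the
#' magnet" is `z = thickness_um + 2`; the helper `z_above()` does this).
#'
#' @param pattern A `pattern_spec`.
#' @param M_Am Magnetization magnitude, A/m; default `1/mu0` (i.e.
#'   mu0*M = 1 T), with the physically relevant sub-saturation induced
#'   magnetization absorbed into a dimensionless scale (all shipped claims
#'   are scale-free).
#' @param points_um n x 3 points, um.
#' @param check_interior Passed to [prism_field()].
#' @return n x 3 matrix of B vectors, tesla.
#' @export
pattern_field <- function(pattern, points_um, M_Am = 1 / MU0,
                          check_interior = TRUE) {
  pts <- as_points3(points_um)
  B <- matrix(0, nrow(pts), 3L, dimnames = list(NULL, c("Bx", "By", "Bz")))
  if (length(pattern$shapes) == 0L) return(B)
  for (pr in pattern_prisms(pattern, M_Am)) {
    b <- pr$box
    s <- sin(b$theta); co <- cos(b$theta)
    # world -> box frame
    dx <- pts[, 1] - b$cx; dy <- pts[, 2] - b$cy
    loc <- cbind(co * dx + s * dy, -s * dx + co * dy, pts[, 3])
    Bl <- prism_field(pr$magnet, loc, check_interior = check_interior)
    B <- B + cbind(co * Bl[, 1] - s * Bl[, 2],
                   s * Bl[, 1] + co * Bl[, 2],
                   Bl[, 3])
  }
  B
}

#' Absolute z of a plane a given height above the film top
#' @param pattern A `pattern_spec`.
#' @param height_um Height above the film top surface, um.
#' @return Absolute z coordinate, um.
#' @export
z_above <- function(pattern, height_um = 2) {
  pattern$thickness_nm * 1e-3 + height_um
}

#' Sample the stray field on a regular planar grid
#'
#' Horizontal maps (`plane = "xy"`, fixed height above the film, as in the
#' flux-density maps at 2 um) and vertical slices (`plane = "yz"`, fixed
#' x) are supported.
#'
#' @param pattern A `pattern_spec`.
#' @param z_um For `plane = "xy"`: height above the film top, um (> 0).
#' @param xlim,ylim,zlim Window bounds, um (zlim used for `plane = "yz"`,
#'   absolute z).
#' @param spacing_um Grid spacing, um.
#' @param plane `"xy"` (default) or `"yz"`.
#' @param at For `plane = "yz"`: the fixed x coordinate, um.
#' @param M_Am Magnetization magnitude, A/m.
#' @return A `field_grid`: axes `x`, `y` (or `y`, `z`), component matrices
#'   `Bx`, `By`, `Bz` and `Bnorm`, each indexed `[row = second axis,
#'   col = first axis]`.
#' @export
field_map <- function(pattern, z_um = 2, xlim = NULL, ylim = NULL,
                      spacing_um = 1, plane = c("xy", "yz"),
                      zlim = NULL, at = 0, M_Am = 1 / MU0) {
  plane <- match.arg(plane)
  stopifnot_scalar_pos(spacing_um, "spacing_um")
  bb <- pattern_bbox(pattern)
  if (plane == "xy") {
    if (z_um <= 0) {
      stop("z_um must be strictly above the film top (z_um > 0)", call. = FALSE)
    }
    xlim <- xlim %||% (bb[c(1, 2)] + c(-30, 30))
    ylim <- ylim %||% (bb[c(3, 4)] + c(-30, 30))
    ax1 <- seq(xlim[1], xlim[2], by = spacing_um)
    ax2 <- seq(ylim[1], ylim[2], by = spacing_um)
    g <- expand.grid(x = ax1, y = ax2)
    pts <- cbind(g$x, g$y, z_above(pattern, z_um))
  } else {
    ylim <- ylim %||% (bb[c(3, 4)] + c(-30, 30))
    zlim <- zlim %||% c(pattern$thickness_nm * 1e-3 + 0.5, 30)
    ax1 <- seq(ylim[1], ylim[2], by = spacing_um)
    ax2 <- seq(zlim[1], zlim[2], by = spacing_um)
    g <- expand.grid(y = ax1, z = ax2)
    pts <- cbind(at, g$y, g$z)
  }
  B <- pattern_field(pattern, pts, M_Am, check_interior = FALSE)
  n1 <- length(ax1); n2 <- length(ax2)
  shape <- function(v) matrix(v, nrow = n2, ncol = n1, byrow = TRUE)
  out <- list(plane = plane,
              axis1 = ax1, axis2 = ax2,
              z_um = if (plane == "xy") z_um else NA_real_,
              at = if (plane == "yz") at else NA_real_,
              spacing_um = spacing_um,
              Bx = shape(B[, 1]), By = shape(B[, 2]), Bz = shape(B[, 3]))
  out$Bnorm <- sqrt(out$Bx^2 + out$By^2 + out$Bz^2)
  class(out) <- "field_grid"
  out
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("field_grid (%s): %d x %d at %.3g um, max |B| = %.4g T\n",
              x$plane, length(x$axis1), length(x$axis2), x$spacing_um,
              max(x$Bnorm)))
  invisible(x)
}
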