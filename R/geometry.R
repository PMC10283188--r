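# Micro-magnet layout geometry: every planar primitive is an oriented box
# (centre, half-extents, rotation), so point-inside tests and exact Euclidean
# point-to-shape distances are closed form. Disk (Minkowski) dilation of a
# pattern is then just thresholding that distance, which keeps effective-area
# fractions free of raster dilation artifacts.

#' Oriented-box primitive
#'
#' The package's single planar primitive: a rectangle with centre
#' `(cx, cy)`, half-extents `hx`, `hy` along a local frame rotated by
#' `theta` radians (counter-clockwise). Axis-aligned rectangles, wide
#' polyline segments, zigzags and line grids all reduce to lists of these.
#'
#' @param cx,cy Centre, um.
#' @param hx,hy Half-extents along the local x/y axes, um; must be > 0.
#' @param theta Rotation of the local frame, radians.
#' @return An object of class `mm_box`.
#' @export
mm_box <- function(cx, cy, hx, hy, theta = 0) {
  stopifnot_scalar_pos(hx, "hx")
  stopifnot_scalar_pos(hy, "hy")
  structure(list(cx = cx, cy = cy, hx = hx, hy = hy, theta = theta),
            class = "mm_box")
}

#' @rdname mm_box
#' @param xmin,xmax,ymin,ymax Rectangle bounds, um.
#' @export
shape_rect <- function(xmin, xmax, ymin, ymax) {
  if (xmax <= xmin || ymax <= ymin) {
    stop("rectangle must have positive extent", call. = FALSE)
  }
  mm_box((xmin + xmax) / 2, (ymin + ymax) / 2,
         (xmax - xmin) / 2, (ymax - ymin) / 2, 0)
}

#' @rdname mm_box
#' @param x1,y1,x2,y2 Segment endpoints, um.
#' @param width Full width of the stroked segment, um.
#' @export
shape_segment <- function(x1, y1, x2, y2, width) {
  stopifnot_scalar_pos(width, "width")
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (len <= 0) stop("segment endpoints coincide", call. = FALSE)
  mm_box((x1 + x2) / 2, (y1 + y2) / 2, len / 2, width / 2,
         atan2(y2 - y1, x2 - x1))
}

#' Polyline stroked with a width
#'
#' Returns one oriented box per segment; joints are covered by the segment
#' overlap at shared vertices (a raster-level approximation of a mitred
#' join, adequate at the widths used here).
#'
#' @param xs,ys Vertex coordinates, um (length >= 2).
#' @param width Full stroke width, um.
#' @return List of `mm_box`.
#' @export
shape_polyline <- function(xs, ys, width) {
  n <- length(xs)
  if (n < 2L || length(ys) != n) stop("need >= 2 matching vertices", call. = FALSE)
  lapply(seq_len(n - 1L), function(i) {
    shape_segment(xs[i], ys[i], xs[i + 1L], ys[i + 1L], width)
  })
}

box_area <- function(b) 4 * b$hx * b$hy
box_perimeter <- function(b) 4 * (b$hx + b$hy)

box_corners <- function(b) {
  s <- sin(b$theta); co <- cos(b$theta)
  u <- c(-b$hx, b$hx, b$hx, -b$hx)
  v <- c(-b$hy, -b$hy, b$hy, b$hy)
  cbind(x = b$cx + co * u - s * v, y = b$cy + s * u + co * v)
}

# Exact Euclidean distance from points to one box (0 inside), vectorized.
box_distance <- function(b, x, y) {
  s <- sin(b$theta); co <- cos(b$theta)
  dx <- x - b$cx; dy <- y - b$cy
  u <- co * dx + s * dy
  v <- -s * dx + co * dy
  du <- pmax(abs(u) - b$hx, 0)
  dv <- pmax(abs(v) - b$hy, 0)
  sqrt(du * du + dv * dv)
}

#' Micro-magnet pattern specification
#'
#' A planar layout of magnetic shapes together with the film thickness and
#' the magnetization direction (in-plane for permalloy bars, out-of-plane
#' for CoFe/Pd multilayers). The unit cell is the periodic tile used for
#' area fractions; it defaults to the pattern bounding box.
#'
#' @param shapes A single `mm_box` or a (possibly nested) list of them.
#' @param unit_cell Numeric length-2, unit-cell width x height in um, or
#'   `NULL` to use the bounding box.
#' @param thickness_nm Film thickness, nm (> 0).
#' @param magnetization_direction Length-3 unit vector; normalized here.
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(shapes, unit_cell = NULL, thickness_nm = 74,
                         magnetization_direction = c(0, 1, 0)) {
  if (inherits(shapes, "mm_box")) shapes <- list(shapes)
  shapes <- flatten_shapes(shapes)
  stopifnot_scalar_pos(thickness_nm, "thickness_nm")
  m <- as.numeric(magnetization_direction)
  if (length(m) != 3L || !all(is.finite(m)) || sqrt(sum(m^2)) == 0) {
    stop("magnetization_direction must be a nonzero length-3 vector",
         call. = FALSE)
  }
  m <- m / sqrt(sum(m^2))
  p <- structure(list(shapes = shapes, unit_cell = unit_cell,
                      thickness_nm = thickness_nm,
                      magnetization_direction = m),
                 class = "pattern_spec")
  if (is.null(unit_cell)) {
    bb <- pattern_bbox(p)
    p$unit_cell <- c(bb[2] - bb[1], bb[4] - bb[3])
  } else {
    if (length(unit_cell) != 2L || any(unit_cell <= 0)) {
      stop("unit_cell must be two positive numbers", call. = FALSE)
    }
    p$unit_cell <- as.numeric(unit_cell)
  }
  p
}

flatten_shapes <- function(x) {
  if (inherits(x, "mm_box")) return(list(x))
  out <- list()
  for (el in x) out <- c(out, flatten_shapes(el))
  out
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat(sprintf(
    "pattern_spec: %d shape(s), unit cell %.6g x %.6g um, film %.6g nm, M dir (%g, %g, %g)\n",
    length(x$shapes), x$unit_cell[1], x$unit_cell[2], x$thickness_nm,
    x$magnetization_direction[1], x$magnetization_direction[2],
    x$magnetization_direction[3]))
  invisible(x)
}

#' Bounding box of a pattern's footprint
#'
#' @param pattern A `pattern_spec`.
#' @return Numeric `c(xmin, xmax, ymin, ymax)` in um.
#' @export
pattern_bbox <- function(pattern) {
  if (length(pattern$shapes) == 0L) return(c(0, 0, 0, 0))
  corners <- do.call(rbind, lapply(pattern$shapes, box_corners))
  c(min(corners[, 1]), max(corners[, 1]), min(corners[, 2]), max(corners[, 2]))
}

#' Distance from points to the pattern footprint
#'
#' Exact Euclidean distance to the nearest shape (0 inside any shape).
#'
#' @param pattern A `pattern_spec`.
#' @param x,y Point coordinates, um (vectorized).
#' @return Numeric vector of distances, um; `Inf` for an empty pattern.
#' @export
pattern_distance <- function(pattern, x, y) {
  if (length(pattern$shapes) == 0L) return(rep(Inf, length(x)))
  d <- rep(Inf, length(x))
  for (b in pattern$shapes) d <- pmin(d, box_distance(b, x, y))
  d
}

#' Regular array of rectangular bar magnets
#'
#' Builds `nx` x `ny` congruent bars on a regular lattice, long axis along
#' y-hat, centred on the origin. The lateral spacing is the gap between bar
#' columns along x-hat and the vertical spacing the gap between bar ends
#' along y-hat, so the periodic unit cell is
#' `(bar_width + lateral) x (bar_length + vertical)`.
#'
#' @param bar_length_um Bar length (long axis, along y), um.
#' @param bar_width_um Bar width (along x), um.
#' @param lateral_spacing_um Gap between adjacent columns, um.
#' @param vertical_spacing_um Gap between bar ends in a column, um.
#' @param nx,ny Number of columns / rows (>= 1).
#' @param thickness_nm Film thickness, nm.
#' @param magnetization_direction Unit 3-vector; default in-plane along the
#'   bar long axis.
#' @return A `pattern_spec`.
#' @export
#' @examples
#' p <- build_bar_array(200, 50, 150, 200)
#' p$unit_cell  # 200 x 400 um
build_bar_array <- function(bar_length_um = 200, bar_width_um = 50,
                            lateral_spacing_um = 150,
                            vertical_spacing_um = 200,
                            nx = 1L, ny = 1L, thickness_nm = 74,
                            magnetization_direction = c(0, 1, 0)) {
  stopifnot_scalar_pos(bar_length_um, "bar_length_um")
  stopifnot_scalar_pos(bar_width_um, "bar_width_um")
  stopifnot_scalar_pos(lateral_spacing_um, "lateral_spacing_um")
  stopifnot_scalar_pos(vertical_spacing_um, "vertical_spacing_um")
  if (nx < 1L || ny < 1L) stop("nx and ny must be >= 1", call. = FALSE)
  pitch_x <- bar_width_um + lateral_spacing_um
  pitch_y <- bar_length_um + vertical_spacing_um
  cx <- (seq_len(nx) - (nx + 1) / 2) * pitch_x
  cy <- (seq_len(ny) - (ny + 1) / 2) * pitch_y
  shapes <- list()
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      shapes[[length(shapes) + 1L]] <-
        mm_box(cx[i], cy[j], bar_width_um / 2, bar_length_um / 2, 0)
    }
  }
  pattern_spec(shapes, unit_cell = c(pitch_x, pitch_y),
               thickness_nm = thickness_nm,
               magnetization_direction = magnetization_direction)
}

#' Shipped pattern presets
#'
#' Parameterized layouts of the four auxiliary micropattern families
#' (thin lines, web, thick lines, zigzag). The default dimensions are
#' package choices on the same 1 mm-scale unit cell; their area fractions
#' are configuration-dependent, not literature-anchored.
#'
#' @param length_um Line length / cell span, um.
#' @param width_um Stroke width, um.
#' @param pitch_um Centre-to-centre spacing of the line family, um.
#' @param n Number of lines (per family for the web).
#' @param amplitude_um,period_um Zigzag geometry, um.
#' @param thickness_nm Film thickness, nm.
#' @param magnetization_direction Unit 3-vector; the auxiliary patterns
#'   default to out-of-plane (perpendicular-anisotropy multilayer).
#' @return A `pattern_spec`.
#' @name pattern_presets
NULL

#' @rdname pattern_presets
#' @export
pattern_thin_lines <- function(n = 5, length_um = 500, width_um = 5,
                               pitch_um = 100, thickness_nm = 18,
                               magnetization_direction = c(0, 0, 1)) {
  cx <- (seq_len(n) - (n + 1) / 2) * pitch_um
  shapes <- lapply(cx, function(x) mm_box(x, 0, width_um / 2, length_um / 2))
  pattern_spec(shapes, unit_cell = c(n * pitch_um, length_um),
               thickness_nm = thickness_nm,
               magnetization_direction = magnetization_direction)
}

#' @rdname pattern_presets
#' @export
pattern_thick_lines <- function(n = 5, length_um = 500, width_um = 20,
                                pitch_um = 100, thickness_nm = 18,
                                magnetization_direction = c(0, 0, 1)) {
  pattern_thin_lines(n, length_um, width_um, pitch_um, thickness_nm,
                     magnetization_direction)
}

#' @rdname pattern_presets
#' @export
pattern_web <- function(n = 5, length_um = 500, width_um = 10,
                        pitch_um = 100, thickness_nm = 18,
                        magnetization_direction = c(0, 0, 1)) {
  c0 <- (seq_len(n) - (n + 1) / 2) * pitch_um
  vert <- lapply(c0, function(x) mm_box(x, 0, width_um / 2, length_um / 2))
  horiz <- lapply(c0, function(y) mm_box(0, y, length_um / 2, width_um / 2))
  pattern_spec(c(vert, horiz), unit_cell = c(length_um, length_um),
               thickness_nm = thickness_nm,
               magnetization_direction = magnetization_direction)
}

#' @rdname pattern_presets
#' @export
pattern_zigzag <- function(n = 5, length_um = 500, width_um = 10,
                           amplitude_um = 50, period_um = 100,
                           pitch_um = 150, thickness_nm = 18,
                           magnetization_direction = c(0, 0, 1)) {
  n_seg <- max(2L, round(length_um / (period_um / 2)))
  xs <- seq(0, by = period_um / 2, length.out = n_seg + 1L) - length_um / 2
  ys <- rep_len(c(-amplitude_um / 2, amplitude_um / 2), n_seg + 1L)
  cy <- (seq_len(n) - (n + 1) / 2) * pitch_um
  shapes <- lapply(cy, function(y0) shape_polyline(xs, ys + y0, width_um))
  pattern_spec(shapes,
               unit_cell = c(length_um, n * pitch_um),
               thickness_nm = thickness_nm,
               magnetization_direction = magnetization_direction)
}

# ---- Raster masks ---------------------------------------------------------

new_mask <- function(origin, pixel_um, m) {
  structure(list(origin = origin, pixel_um = pixel_um, m = m),
            class = "mm_mask")
}

#' @export
print.mm_mask <- function(x, ...) {
  cat(sprintf("mm_mask: %d x %d px at %.4g um/px, origin (%.4g, %.4g), area %.6g um^2\n",
              ncol(x$m), nrow(x$m), x$pixel_um, x$origin[1], x$origin[2],
              mask_area(x)))
  invisible(x)
}

mask_axes <- function(mask) {
  list(x = mask$origin[1] + (seq_len(ncol(mask$m)) - 0.5) * mask$pixel_um,
       y = mask$origin[2] + (seq_len(nrow(mask$m)) - 0.5) * mask$pixel_um)
}

#' Occupied area of a raster mask
#' @param mask An `mm_mask`.
#' @return Area in um^2.
#' @export
mask_area <- function(mask) sum(mask$m) * mask$pixel_um^2

default_bounds <- function(pattern, margin = 0) {
  bb <- pattern_bbox(pattern)
  ctr <- c((bb[1] + bb[2]) / 2, (bb[3] + bb[4]) / 2)
  uc <- pattern$unit_cell
  c(ctr[1] - uc[1] / 2, ctr[1] + uc[1] / 2,
    ctr[2] - uc[2] / 2, ctr[2] + uc[2] / 2) + c(-1, 1, -1, 1) * margin
}

#' Rasterize a pattern onto a boolean pixel grid
#'
#' A pixel is occupied iff its centre lies inside any shape. Pixel centres
#' sit at half-integer offsets from the grid origin (lower-left corner);
#' the mask matrix is indexed `[row = y, col = x]` from the origin upward.
#'
#' @param pattern A `pattern_spec`.
#' @param pixel_um Pixel size, um (> 0).
#' @param bounds `c(xmin, xmax, ymin, ymax)` window, um; defaults to the
#'   unit cell centred on the pattern.
#' @return An `mm_mask`.
#' @export
rasterize <- function(pattern, pixel_um = 0.5, bounds = NULL) {
  stopifnot_scalar_pos(pixel_um, "pixel_um")
  bounds <- bounds %||% default_bounds(pattern)
  nx <- max(1L, round((bounds[2] - bounds[1]) / pixel_um))
  ny <- max(1L, round((bounds[4] - bounds[3]) / pixel_um))
  xc <- bounds[1] + (seq_len(nx) - 0.5) * pixel_um
  yc <- bounds[3] + (seq_len(ny) - 0.5) * pixel_um
  g <- expand.grid(x = xc, y = yc)
  inside <- pattern_distance(pattern, g$x, g$y) <= 0
  new_mask(c(bounds[1], bounds[3]), pixel_um,
           matrix(inside, nrow = ny, ncol = nx, byrow = TRUE))
}

#' Minkowski (disk) dilation of a pattern or mask
#'
#' Dilates the footprint by a disk of radius `radius_um`: cells are round,
#' so a cell touches the pattern iff its centre lies within one cell radius
#' of an edge; the effective-magnetic-area convention adds a 10 um margin.
#' For a `pattern_spec` the dilation is analytic (pixel occupied iff its
#' centre is within `radius_um` of any shape); for a raster `mm_mask` it is
#' morphological, via a disc structuring element.
#'
#' @param x A `pattern_spec` or `mm_mask`.
#' @param radius_um Dilation radius, um (>= 0).
#' @param pixel_um Pixel size for the pattern route, um.
#' @param bounds Optional raster window for the pattern route.
#' @return An `mm_mask`.
#' @export
dilate <- function(x, radius_um = 10, ...) UseMethod("dilate")

#' @rdname dilate
#' @export
dilate.pattern_spec <- function(x, radius_um = 10, pixel_um = 0.5,
                                bounds = NULL, ...) {
  if (radius_um < 0) stop("radius_um must be >= 0", call. = FALSE)
  stopifnot_scalar_pos(pixel_um, "pixel_um")
  bounds <- bounds %||% default_bounds(x)
  nx <- max(1L, round((bounds[2] - bounds[1]) / pixel_um))
  ny <- max(1L, round((bounds[4] - bounds[3]) / pixel_um))
  xc <- bounds[1] + (seq_len(nx) - 0.5) * pixel_um
  yc <- bounds[3] + (seq_len(ny) - 0.5) * pixel_um
  g <- expand.grid(x = xc, y = yc)
  inside <- pattern_distance(x, g$x, g$y) <= radius_um
  new_mask(c(bounds[1], bounds[3]), pixel_um,
           matrix(inside, nrow = ny, ncol = nx, byrow = TRUE))
}

#' @rdname dilate
#' @export
dilate.mm_mask <- function(x, radius_um = 10, ...) {
  if (radius_um < 0) stop("radius_um must be >= 0", call. = FALSE)
  r_px <- radius_um / x$pixel_um
  if (r_px < 0.5) return(x)
  brush <- EBImage::makeBrush(2L * floor(r_px) + 1L, shape = "disc")
  out <- EBImage::dilate(EBImage::Image(x$m * 1), brush)
  new_mask(x$origin, x$pixel_um, EBImage::imageData(out) > 0.5)
}

#' Nominal and effective area fractions of a pattern
#'
#' The nominal fraction is the pattern footprint area over the unit-cell
#' area; the effective fraction dilates the footprint by the cell-contact
#' margin first (both measured by rasterization over one unit cell, so the
#' dilated footprint is implicitly clipped to the tile). The effective
#' fraction is the uniform-landing null probability `p0` for the
#' one-sample proportion test.
#'
#' @param pattern A `pattern_spec` with a defined unit cell.
#' @param dilation_radius_um Disk radius of the contact margin, um
#'   (default 10, i.e. one cell diameter margin used by the study).
#' @param pixel_um Raster resolution, um.
#' @return List with `nominal_fraction` and `effective_fraction`.
#' @export
#' @examples
#' area_fractions(build_bar_array(), dilation_radius_um = 0)
area_fractions <- function(pattern, dilation_radius_um = 10,
                           pixel_um = 0.25) {
  if (prod(pattern$unit_cell) <= 0) {
    stop("unit cell must have positive area", call. = FALSE)
  }
  if (dilation_radius_um < 0) stop("dilation radius must be >= 0", call. = FALSE)
  bounds <- default_bounds(pattern)
  m0 <- rasterize(pattern, pixel_um, bounds)
  md <- dilate(pattern, dilation_radius_um, pixel_um, bounds)
  list(nominal_fraction = mean(m0$m), effective_fraction = mean(md$m))
}

#' Closed-form area of a disk-dilated convex box
#'
#' `A + P * r + pi * r^2` for one oriented box; exact when dilations of
#' distinct shapes do not overlap. Used as the analytic cross-check for
#' the raster route.
#'
#' @param b An `mm_box`.
#' @param radius_um Dilation radius, um.
#' @return Area in um^2.
#' @export
dilated_box_area <- function(b, radius_um) {
  box_area(b) + box_perimeter(b) * radius_um + pi * radius_um^2
}
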