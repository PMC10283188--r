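# Delimited-text round-trips for tracks, raster masks, field/force grids,
# and structured pattern / run configuration files (YAML or JSON). The
# CSV dialect is fixed: comma separator, dot decimal, header row, UTF-8;
# grid and mask files carry a single '#' header line with shape, spacing
# and units that is validated against the payload on read.

#' Write / read time-lapse tracks
#'
#' One row per frame: `track_id`, `t_s`, `x_um`, `y_um`.
#'
#' @param tracks data.frame of tracks.
#' @param path File path.
#' @return `read_tracks` returns the data.frame; writers return the path
#'   invisibly.
#' @export
write_tracks <- function(tracks, path) {
  need <- c("track_id", "t_s", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    stop("tracks need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(tracks[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("malformed track file (expected columns ",
         paste(need, collapse = ", "), "): ", path, call. = FALSE)
  }
  for (cc in c("t_s", "x_um", "y_um")) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad)) {
    stop(sprintf("malformed row %d in %s", bad[1] + 1L, path), call. = FALSE)
  }
  df
}

#' Write / read a boolean raster mask
#'
#' A `#` header records the origin, pixel size and matrix shape; the
#' payload is a 0/1 grid, one text row per mask row from the origin
#' upward.
#'
#' @param mask An `mm_mask`.
#' @param path File path.
#' @export
write_mask <- function(mask, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# micromag mask nx=%d ny=%d pixel_um=%.17g origin_x_um=%.17g origin_y_um=%.17g",
    ncol(mask$m), nrow(mask$m), mask$pixel_um, mask$origin[1],
    mask$origin[2]), con)
  utils::write.table(mask$m * 1L, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- parse_header(hdr, "mask",
                       c("nx", "ny", "pixel_um", "origin_x_um", "origin_y_um"))
  m <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(m) <- NULL
  if (nrow(m) != meta["ny"] || ncol(m) != meta["nx"]) {
    stop(sprintf("mask header (%d x %d) does not match payload (%d x %d): %s",
                 meta["ny"], meta["nx"], nrow(m), ncol(m), path),
         call. = FALSE)
  }
  new_mask(c(meta["origin_x_um"], meta["origin_y_um"]), meta[["pixel_um"]],
           m > 0)
}

parse_header <- function(hdr, kind, keys) {
  if (!startsWith(hdr, paste0("# micromag ", kind))) {
    stop("not a micromag ", kind, " file", call. = FALSE)
  }
  kv <- regmatches(hdr, gregexpr("[a-z_0-9]+=[-0-9.eE+]+", hdr))[[1]]
  vals <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  if (!all(keys %in% names(vals))) {
    stop("missing header keys in ", kind, " file", call. = FALSE)
  }
  vals[keys]
}

#' Write / read a sampled field or force grid
#'
#' Long-format delimited text (`x_um`, `y_um`, then one column per
#' component and the magnitude), preceded by a `#` header with the grid
#' shape, spacing and plane height; shape is validated on read.
#'
#' @param grid A `field_grid` or `force_map` (horizontal plane).
#' @param path File path.
#' @export
write_grid <- function(grid, path) {
  is_force <- inherits(grid, "force_map")
  comps <- if (is_force) c("Fx", "Fy", "Fz", "Fnorm")
           else c("Bx", "By", "Bz", "Bnorm")
  kind <- if (is_force) "force_map" else "field_grid"
  n1 <- length(grid$axis1); n2 <- length(grid$axis2)
  g <- expand.grid(x_um = grid$axis1, y_um = grid$axis2)
  for (cc in comps) g[[cc]] <- as.vector(t(grid[[cc]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# micromag %s nx=%d ny=%d spacing_um=%.17g z_um=%.17g",
                     kind, n1, n2, grid$spacing_um, grid$z_um), con)
  utils::write.csv(g, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  hdr <- readLines(path, n = 1L)
  kind <- if (grepl("force_map", hdr)) "force_map" else "field_grid"
  meta <- parse_header(hdr, kind, c("nx", "ny", "spacing_um", "z_um"))
  df <- utils::read.csv(path, skip = 1L)
  n1 <- as.integer(meta["nx"]); n2 <- as.integer(meta["ny"])
  if (nrow(df) != n1 * n2) {
    stop(sprintf("grid header (%d x %d = %d points) does not match payload (%d rows): %s",
                 n1, n2, n1 * n2, nrow(df), path), call. = FALSE)
  }
  ax1 <- sort(unique(df$x_um)); ax2 <- sort(unique(df$y_um))
  shp <- function(v) matrix(v, nrow = n2, ncol = n1, byrow = TRUE)
  if (kind == "force_map") {
    new_force_map(ax1, ax2, meta[["z_um"]], meta[["spacing_um"]],
                  shp(df$Fx), shp(df$Fy), shp(df$Fz))
  } else {
    out <- list(plane = "xy", axis1 = ax1, axis2 = ax2,
                z_um = meta[["z_um"]], at = NA_real_,
                spacing_um = meta[["spacing_um"]],
                Bx = shp(df$Bx), By = shp(df$By), Bz = shp(df$Bz))
    out$Bnorm <- sqrt(out$Bx^2 + out$By^2 + out$Bz^2)
    class(out) <- "field_grid"
    out
  }
}

#' Write a hot-spot table
#' @param hot_spots data.frame from [find_hot_spots()].
#' @param path File path.
#' @export
write_hot_spots <- function(hot_spots, path) {
  utils::write.csv(hot_spots, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a pattern configuration
#'
#' Structured config with keys `shapes` (list of oriented boxes:
#' `cx, cy, hx, hy, theta`), `unit_cell`, `thickness_nm`,
#' `magnetization_direction`. Format chosen by extension: `.yaml`/`.yml`
#' or `.json`. Unknown keys are rejected.
#'
#' @param pattern A `pattern_spec`.
#' @param path File path.
#' @export
write_pattern_config <- function(pattern, path) {
  obj <- list(
    shapes = lapply(pattern$shapes, function(b) {
      list(cx = b$cx, cy = b$cy, hx = b$hx, hy = b$hy, theta = b$theta)
    }),
    unit_cell = pattern$unit_cell,
    thickness_nm = pattern$thickness_nm,
    magnetization_direction = pattern$magnetization_direction)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 15L)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_pattern_config
#' @export
read_pattern_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  allowed <- c("shapes", "unit_cell", "thickness_nm",
               "magnetization_direction")
  extra <- setdiff(names(obj), allowed)
  if (length(extra)) {
    stop("unknown pattern config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  shapes <- lapply(obj$shapes, function(s) {
    mm_box(s$cx, s$cy, s$hx, s$hy, s$theta %||% 0)
  })
  pattern_spec(shapes, unlist(obj$unit_cell), obj$thickness_nm,
               unlist(obj$magnetization_direction))
}

#' Read and validate a run configuration
#'
#' YAML (or JSON) configuration for the analysis drivers, with blocks
#' `pattern` (preset name or file), `physics` (magnetization scale,
#' viscosity, k_lin, diameters), `simulation` (height, grid spacing,
#' integrator caps), `stats` (alpha, dilation radius) and `seed`.
#' Unknown top-level keys or block keys are rejected.
#'
#' @param path Config file path.
#' @return Named list with validated defaults filled in.
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  allowed <- c("pattern", "physics", "simulation", "stats", "seed",
               "out_dir")
  extra <- setdiff(names(obj), allowed)
  if (length(extra)) {
    stop("unknown run config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  check_block <- function(block, keys) {
    extra <- setdiff(names(block), keys)
    if (length(extra)) {
      stop("unknown config key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    block
  }
  physics <- check_block(obj$physics %||% list(),
                         c("mu0_M_T", "viscosity_Pa_s", "k_lin",
                           "cell_diameter_um", "particle_diameter_um"))
  simulation <- check_block(obj$simulation %||% list(),
                            c("z_um", "spacing_um", "cap_um",
                              "capture_radius_um", "max_time_s"))
  stats_blk <- check_block(obj$stats %||% list(),
                           c("alpha", "dilation_radius_um"))
  pattern <- obj$pattern %||% "bar_array"
  if (is.character(pattern) && file.exists(pattern)) {
    pattern <- read_pattern_config(pattern)
  } else if (is.character(pattern)) {
    pattern <- switch(pattern,
                      bar_array = build_bar_array(),
                      thin_lines = pattern_thin_lines(),
                      thick_lines = pattern_thick_lines(),
                      web = pattern_web(),
                      zigzag = pattern_zigzag(),
                      stop("unknown pattern preset: ", pattern,
                           call. = FALSE))
  }
  list(pattern = pattern,
       physics = utils::modifyList(
         list(mu0_M_T = 1, viscosity_Pa_s = 8.9e-4, k_lin = 1,
              cell_diameter_um = 10, particle_diameter_um = 2.8), physics),
       simulation = utils::modifyList(
         list(z_um = 2, spacing_um = 1, cap_um = 0.5,
              capture_radius_um = 5, max_time_s = 600), simulation),
       stats = utils::modifyList(
         list(alpha = 0.05, dilation_radius_um = 10), stats_blk),
       seed = obj$seed %||% NULL,
       out_dir = obj$out_dir %||% NULL)
}

#' Serialize an occupancy report or test result to JSON
#'
#' @param x An `occupancy_report` or a test-result list.
#' @param path File path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
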