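# Estimators and tests used to quantify guidance: constant-velocity fits
# to time-lapse tracks, occupancy metrics over a pattern, the
# uniform-landing null fraction, a one-sample proportion test and Welch's
# two-sample t-test. Standard fits and exact tests delegate to stats::.

#' Estimate speed from a time-lapse track
#'
#' Ordinary least-squares fit of distance travelled against time; under
#' the drag-balance model motion is at constant speed, so the slope is
#' the speed estimate. For the straight-line motion the model predicts,
#' distance from the start (`method = "net"`, the default) and cumulative
#' path length (`method = "path"`) coincide; under localization noise the
#' path length is inflated by the noise's own jitter (every frame's error
#' adds |noise| to the summed step lengths), biasing the slope upward by
#' about `sigma^2/(v dt^2)`, while the net distance stays unbiased -- so
#' the net fit is the default.
#'
#' @param track data.frame with `t_s`, `x_um`, `y_um` (>= 2 frames,
#'   strictly increasing `t_s`).
#' @param method `"net"` (distance from the first frame, default) or
#'   `"path"` (cumulative step lengths).
#' @return List of class `velocity_fit`: `slope_um_s`, `intercept_um`,
#'   `r_squared`, `n`.
#' @export
estimate_velocity <- function(track, method = c("net", "path")) {
  method <- match.arg(method)
  if (nrow(track) < 2L) stop("need at least 2 frames", call. = FALSE)
  t <- track$t_s
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing",
                              call. = FALSE)
  d <- if (method == "net") {
    sqrt((track$x_um - track$x_um[1])^2 + (track$y_um - track$y_um[1])^2)
  } else {
    c(0, cumsum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)))
  }
  fit <- stats::lm(d ~ t)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits are fine here
  structure(list(slope_um_s = unname(stats::coef(fit)[2]),
                 intercept_um = unname(stats::coef(fit)[1]),
                 r_squared = if (is.nan(r2)) 1 else r2,
                 n = nrow(track)),
            class = "velocity_fit")
}

#' @export
print.velocity_fit <- function(x, ...) {
  cat(sprintf("velocity_fit: %.4g um/s (R^2 = %.4f, n = %d frames)\n",
              x$slope_um_s, x$r_squared, x$n))
  invisible(x)
}

#' Occupancy metrics of settled cells over a pattern
#'
#' A cell touches the pattern iff its centre lies within the footprint
#' dilated by `touch_radius_um` (exact point-to-shape distance); a hot
#' spot is occupied iff at least one cell lies within
#' `capture_radius_um` of it; cells-per-bar assigns each touching cell to
#' the shape with the nearest centroid.
#'
#' @param final_positions data.frame with `x_um`, `y_um`.
#' @param pattern A `pattern_spec`.
#' @param hot_spots data.frame with `x_um`, `y_um`, or `NULL` (hot-spot
#'   occupancy then reported as `NA`).
#' @param touch_radius_um Contact margin, um (default 10).
#' @param capture_radius_um Hot-spot occupancy distance, um (default 5).
#' @param dilation_radius_um Margin for the uniform-landing null `p0`
#'   (defaults to `touch_radius_um`).
#' @return List of class `occupancy_report` (counts, fractions,
#'   cells-per-bar mean and SD, and `p0`).
#' @export
occupancy <- function(final_positions, pattern, hot_spots = NULL,
                      touch_radius_um = 10, capture_radius_um = 5,
                      dilation_radius_um = touch_radius_um) {
  if (touch_radius_um < 0) stop("touch_radius_um must be >= 0", call. = FALSE)
  n <- nrow(final_positions)
  if (n == 0L) {
    touching <- logical(0)
  } else {
    d <- pattern_distance(pattern, final_positions$x_um,
                          final_positions$y_um)
    touching <- d <= touch_radius_um
  }
  n_touch <- sum(touching)
  if (!is.null(hot_spots) && nrow(hot_spots) > 0L) {
    occ <- vapply(seq_len(nrow(hot_spots)), function(i) {
      any((final_positions$x_um - hot_spots$x_um[i])^2 +
            (final_positions$y_um - hot_spots$y_um[i])^2 <=
            capture_radius_um^2)
    }, logical(1))
    n_hs <- nrow(hot_spots); n_hs_occ <- sum(occ)
    frac_hs <- n_hs_occ / n_hs
  } else {
    n_hs <- 0L; n_hs_occ <- NA_integer_; frac_hs <- NA_real_
  }
  # assign touching cells to nearest shape centroid
  n_shapes <- length(pattern$shapes)
  if (n_shapes > 0L && n_touch > 0L) {
    cx <- vapply(pattern$shapes, function(b) b$cx, numeric(1))
    cy <- vapply(pattern$shapes, function(b) b$cy, numeric(1))
    xs <- final_positions$x_um[touching]; ys <- final_positions$y_um[touching]
    nearest <- vapply(seq_along(xs), function(i) {
      which.min((cx - xs[i])^2 + (cy - ys[i])^2)
    }, integer(1))
    per_bar <- tabulate(nearest, nbins = n_shapes)
  } else {
    per_bar <- rep(0L, n_shapes)
  }
  p0 <- if (length(pattern$shapes) > 0L) {
    uniform_null_fraction(pattern, dilation_radius_um)
  } else NA_real_
  structure(list(
    n_cells = n, n_touching_pattern = n_touch,
    fraction_touching = if (n > 0) n_touch / n else NA_real_,
    n_hot_spots = n_hs, n_hot_spots_occupied = n_hs_occ,
    fraction_hot_spots_occupied = frac_hs,
    cells_per_bar_mean = if (n_shapes > 0) mean(per_bar) else NA_real_,
    cells_per_bar_sd = if (n_shapes > 1) stats::sd(per_bar) else NA_real_,
    cells_per_bar = per_bar,
    p0 = p0), class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat(sprintf(
    "occupancy: %d/%d cells touching (%.1f%%), null p0 = %.3f\n",
    x$n_touching_pattern, x$n_cells, 100 * x$fraction_touching, x$p0))
  if (!is.na(x$fraction_hot_spots_occupied)) {
    cat(sprintf("  hot spots occupied: %d/%d (%.1f%%)\n",
                x$n_hot_spots_occupied, x$n_hot_spots,
                100 * x$fraction_hot_spots_occupied))
  }
  cat(sprintf("  cells per bar: %.2f +/- %.2f\n",
              x$cells_per_bar_mean, x$cells_per_bar_sd))
  invisible(x)
}

#' Uniform-landing null fraction
#'
#' The probability that a uniformly landing cell touches the pattern:
#' the effective area fraction of the footprint dilated by the contact
#' margin (delegates to [area_fractions()], the single source of truth).
#'
#' @param pattern A `pattern_spec`.
#' @param dilation_radius_um Contact margin, um.
#' @param ... Passed to [area_fractions()].
#' @return Scalar `p0` in `[0, 1]`.
#' @export
uniform_null_fraction <- function(pattern, dilation_radius_um = 10, ...) {
  area_fractions(pattern, dilation_radius_um, ...)$effective_fraction
}

#' One-sample proportion test
#'
#' Tests `H0: p = p0` from `k` successes in `n` trials. Uses the normal
#' z statistic with continuity correction when `n p0` and `n (1 - p0)`
#' both reach 5, otherwise the exact binomial test; two-sided by default.
#'
#' @param k_successes,n_trials Counts.
#' @param p0 Null proportion, strictly inside (0, 1).
#' @param alternative `"two.sided"` (default), `"less"`, `"greater"`.
#' @param method `"auto"` (default), `"z"`, or `"exact"`.
#' @return List: `statistic` (z, or `NA` for exact), `p_value`,
#'   `estimate` (k/n), `method`, `n`.
#' @export
proportion_test <- function(k_successes, n_trials, p0,
                            alternative = c("two.sided", "less", "greater"),
                            method = c("auto", "z", "exact")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be strictly inside (0, 1)",
                               call. = FALSE)
  if (k_successes < 0 || k_successes > n_trials) {
    stop("need 0 <= k_successes <= n_trials", call. = FALSE)
  }
  use_z <- switch(method,
                  auto = n_trials * p0 >= 5 && n_trials * (1 - p0) >= 5,
                  z = TRUE, exact = FALSE)
  if (use_z) {
    se <- sqrt(p0 * (1 - p0) / n_trials)
    diff <- k_successes / n_trials - p0
    cc <- min(abs(diff), 0.5 / n_trials)  # continuity correction toward H0
    z <- (abs(diff) - cc) / se * sign(diff)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                less = stats::pnorm(z),
                greater = stats::pnorm(-z))
    list(statistic = z, p_value = min(p, 1),
         estimate = k_successes / n_trials,
         method = "one-sample z test with continuity correction",
         n = n_trials)
  } else {
    bt <- stats::binom.test(k_successes, n_trials, p0,
                            alternative = alternative)
    list(statistic = NA_real_, p_value = bt$p.value,
         estimate = k_successes / n_trials,
         method = "exact binomial test", n = n_trials)
  }
}

#' Welch two-sample t-test
#'
#' Two-sided Welch test via [stats::t.test()]. The degenerate case of
#' two zero-variance samples with equal means is reported as `p = 1`
#' with a flag instead of an error.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return List: `t`, `df`, `p_value`, `mean_a`, `mean_b`, `degenerate`.
#' @export
two_sample_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    same <- mean(sample_a) == mean(sample_b)
    return(list(t = if (same) 0 else Inf, df = NA_real_,
                p_value = if (same) 1 else 0,
                mean_a = mean(sample_a), mean_b = mean(sample_b),
                degenerate = TRUE))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(sample_a),
       mean_b = mean(sample_b), degenerate = FALSE)
}
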