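#!/usr/bin/env Rscript
# Drag-balance kinetics: terminal velocities, the speed-ratio predictions
# for differently labeled objects, and a trajectory of a labeled cell
# relaxing into a pole hot spot. Speeds are calibrated so the fastest
# point of the landscape moves a cell at 10 um/s (the ~50 um in 5 s scale
# of observed tracks); everything else follows from the model.

library(micromag)

dir.create("results", showWarnings = FALSE)

# speed ratios: pure drag-balance algebra, no free parameters
one <- cell_body(10, 1)
two <- cell_body(10, 2)
free <- magnetic_particle(2.8, 1)
ratios <- data.frame(
  comparison = c("cell+2 vs cell+1", "free particle vs cell+1",
                 "cell+1 vs cell+1"),
  predicted_ratio = c(speed_ratio(two, one), speed_ratio(free, one),
                      speed_ratio(one, one)))
write.csv(ratios, "results/speed_ratios.csv", row.names = FALSE)
print(ratios, digits = 3)

message(sprintf("1 pN on a 10 um cell in medium: %.1f um/s terminal speed",
                terminal_velocity(1e-12, cell_body(10), medium())))
message(sprintf("a 2.8 um bead displaces ~%.3g 50 nm nanoparticles by volume",
                nanoparticle_equivalence()))

# trajectory into a hot spot over the bar's force landscape
bar <- build_bar_array()
fmap <- linear_force(bar, z_um = 2, xlim = c(-40, 40), ylim = c(-130, 130),
                     spacing_um = 0.5)
hs <- find_hot_spots(fmap)
k <- calibrate_k_lin(10, max(fmap$Fnorm), one)
ff0 <- force_interpolator(fmap)
ff <- function(p) k * ff0(p)
tr <- simulate_trajectory(one, ff, start = c(10, 125), hot_spots = hs,
                          capture_radius_um = 5, max_time_s = 1e4,
                          scale_by_moment = FALSE)
tr_out <- data.frame(track_id = 1L, tr)
write_tracks(tr_out, "results/capture_track.csv")
message(sprintf("cell released at (10, 125): %s after %.0f s at (%.1f, %.1f)",
                attr(tr, "status"), max(tr$t_s),
                tr$x_um[nrow(tr)], tr$y_um[nrow(tr)]))

# constant-speed fit of a synthetic time-lapse track
tl <- synth_tracks(1, 10, 5, 1, noise_sigma_um = 0.5, seed = 1)
fit <- estimate_velocity(tl)
message(sprintf("synthetic track at 10 um/s: fitted %.2f um/s (R^2 = %.3f)",
                fit$slope_um_s, fit$r_squared))
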