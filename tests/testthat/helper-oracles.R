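# Independent oracles and shared fixtures.

mu0 <- 4e-7 * pi

# Brute-force surface integration of the equivalent-charge field over the
# prism's charged faces, tensor Gauss-Legendre per face. Independent of the
# closed-form corner-sum kernel under test.
oracle_prism_field <- function(magnet, pt_um, n_major = 160, n_minor = 12) {
  p <- pt_um * 1e-6
  lims <- list(magnet$xlim * 1e-6, magnet$ylim * 1e-6, magnet$zlim * 1e-6)
  Btot <- c(0, 0, 0)
  for (axis in 1:3) {
    Mc <- magnet$M[axis]
    if (Mc == 0) next
    others <- setdiff(1:3, axis)
    la <- lims[[others[1]]]; lb <- lims[[others[2]]]
    na <- if (diff(la) > diff(lb)) n_major else n_minor
    nb <- if (diff(la) > diff(lb)) n_minor else n_major
    ga <- pracma::gaussLegendre(na, la[1], la[2])
    gb <- pracma::gaussLegendre(nb, lb[1], lb[2])
    g <- expand.grid(a = ga$x, b = gb$x)
    w <- as.vector(outer(ga$w, gb$w))
    for (side in 1:2) {
      sg <- if (side == 2) Mc else -Mc
      rp <- matrix(0, nrow(g), 3)
      rp[, axis] <- lims[[axis]][side]
      rp[, others[1]] <- g$a
      rp[, others[2]] <- g$b
      d <- cbind(p[1] - rp[, 1], p[2] - rp[, 2], p[3] - rp[, 3])
      r3 <- rowSums(d^2)^1.5
      Btot <- Btot + (mu0 * sg / (4 * pi)) * colSums(d / r3 * w)
    }
  }
  Btot
}

# Point-dipole field of moment m (A m^2) at displacement r (m).
oracle_dipole_field <- function(m, r_m) {
  rn <- sqrt(sum(r_m^2))
  (mu0 / (4 * pi)) * (3 * sum(m * r_m) * r_m / rn^5 - m / rn^3)
}

rel_err <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# Shared fixtures: the 200 x 50 um permalloy bar and its force map at 2 um.
bar_fixture <- build_bar_array()
bar_force_map <- linear_force(bar_fixture, z_um = 2,
                              xlim = c(-40, 40), ylim = c(-130, 130),
                              spacing_um = 0.5)
bar_hot_spots <- find_hot_spots(bar_force_map)
# refined map around the +y pole: curl truncation error scales with the
# grid spacing squared, so the conservativity check uses this finer grid
bar_force_fine <- linear_force(bar_fixture, z_um = 2, xlim = c(-30, 30),
                               ylim = c(75, 130), spacing_um = 0.25)

# In-plane curl dFy/dx - dFx/dy of a force map, restricted to the interior
# region where all stencils are central (discrete central-difference
# operators commute there, so a gradient field must give ~0).
map_curl <- function(fm) {
  h <- fm$spacing_um * 1e-6
  n1 <- length(fm$axis1); n2 <- length(fm$axis2)
  dFy_dx <- (fm$Fy[, 3:n1] - fm$Fy[, 1:(n1 - 2)]) / (2 * h)
  dFx_dy <- (fm$Fx[3:n2, ] - fm$Fx[1:(n2 - 2), ]) / (2 * h)
  curl <- dFy_dx[2:(n2 - 1), ] - dFx_dy[, 2:(n1 - 1)]
  curl[3:(n2 - 4), 3:(n1 - 4)]
}

# Connected-component count of a boolean mask (flood fill, 8-connected).
n_components <- function(m) {
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  max(EBImage::imageData(lab))
}
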