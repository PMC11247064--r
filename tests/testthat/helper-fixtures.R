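# Shared fixture builders: everything is generated in code at test time.

# Concentric disc cross-section (lumen + media + adventitia annuli).
disc_section <- function(R = 1, media = 0.25, adv = 0.25,
                         grid = hex_grid(120, 120, 0.0375)) {
  ctr <- hex_centers(grid)
  cx <- ctr$x[round(grid$n_rows / 2), round(grid$n_cols / 2)]
  cy <- ctr$y[round(grid$n_rows / 2), round(grid$n_cols / 2)]
  r <- sqrt((ctr$x - cx)^2 + (ctr$y - cy)^2)
  lab <- matrix(LABELS["exterior"], grid$n_rows, grid$n_cols)
  lab[r < R + media + adv] <- LABELS["adventitia"]
  lab[r < R + media] <- LABELS["media"]
  lab[r < R] <- LABELS["lumen"]
  cross_section(grid, lab)
}

# Uniform shear field (wss in Pa); high values silence the shear stimulus.
flat_wss <- function(wss = 10, n = 72) {
  data.frame(angle = seq(-pi, pi, length.out = n + 1)[-1], wss = wss)
}

# Small single-plane diseased vessel for fast dynamic tests.
small_vessel <- function(grid = hex_grid(110, 110, 0.0375)) {
  vessel_spec(n_planes = 1, lumen_radius = 0.9, media_thickness = 0.3,
              adventitia_thickness = 0.25, plaque_planes = c(1, 1),
              plaque_max_thickness = 0.55, eccentricity = 0.1, grid = grid)
}

# Paper-sized single-plane vessel (lumen r = 1.65 mm, 0.35 mm layers) on a
# 200 x 200 grid; the scale used by the calibration checks.
paper_plane <- function() {
  vessel_spec(n_planes = 1, lumen_radius = 1.65, media_thickness = 0.35,
              adventitia_thickness = 0.35, plaque_planes = c(1, 1),
              plaque_max_thickness = 1.0, eccentricity = 0.15,
              grid = hex_grid(200, 200, 0.0375))
}

# Fine polygonized circle.
circle_contour <- function(R = 1, n = 720, cx = 0, cy = 0) {
  th <- seq(-pi, pi, length.out = n + 1)[-1]
  cbind(x = cx + R * cos(th), y = cy + R * sin(th))
}
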