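#' Synthetic vessel specification
#'
#' Describes an idealized diseased femoral-artery segment in its
#' post-intervention configuration: a tapering lumen, media and adventitia
#' annuli and an eccentric plaque bulging into the lumen over a range of
#' planes.  Defaults emulate the dimensions of a superficial femoral
#' artery segment: 11 planes spaced 2 mm, lumen diameter tapering from
#' 3.3 mm to 2.9 mm, external diameter from 4.7 mm to 5.0 mm.
#'
#' @param n_planes number of cross-sectional planes.
#' @param plane_spacing axial spacing, mm.
#' @param lumen_radius nominal lumen radius at the first and last plane,
#'   mm (linearly interpolated).
#' @param media_thickness,adventitia_thickness layer thicknesses at the
#'   first and last plane, mm.
#' @param plaque_planes first and last plane carrying plaque.
#' @param plaque_angle angular position of the plaque center, radians.
#' @param plaque_half_angle angular half-extent of the plaque, radians.
#' @param plaque_max_thickness peak inward plaque thickness, mm.
#' @param eccentricity offset of the vessel center from the grid center,
#'   mm (along +x).
#' @param grid the [hex_grid()] every plane is rasterized on.
#' @return Object of class `vessel_spec`.
#' @export
vessel_spec <- function(n_planes = 11, plane_spacing = 2,
                        lumen_radius = c(1.65, 1.45),
                        media_thickness = c(0.35, 0.52),
                        adventitia_thickness = c(0.35, 0.53),
                        plaque_planes = c(4, 8),
                        plaque_angle = 0,
                        plaque_half_angle = 100 * pi / 180,
                        plaque_max_thickness = 1.0,
                        eccentricity = 0.15,
                        grid = hex_grid()) {
  lumen_radius <- rep_len(lumen_radius, 2)
  media_thickness <- rep_len(media_thickness, 2)
  adventitia_thickness <- rep_len(adventitia_thickness, 2)
  stopifnot(all(lumen_radius > 0), all(media_thickness > 0),
            all(adventitia_thickness > 0), plaque_max_thickness >= 0,
            plaque_half_angle >= 0)
  if (plaque_max_thickness >= min(lumen_radius))
    stop("plaque thicker than the lumen radius", call. = FALSE)
  structure(list(n_planes = as.integer(n_planes),
                 plane_spacing = plane_spacing,
                 lumen_radius = lumen_radius,
                 media_thickness = media_thickness,
                 adventitia_thickness = adventitia_thickness,
                 plaque_planes = as.integer(rep_len(plaque_planes, 2)),
                 plaque_angle = plaque_angle,
                 plaque_half_angle = plaque_half_angle,
                 plaque_max_thickness = plaque_max_thickness,
                 eccentricity = eccentricity,
                 grid = grid),
            class = "vessel_spec")
}

# Per-plane geometry numbers (linear taper + plaque axial cosine ramp).
plane_geometry <- function(spec, plane) {
  f <- if (spec$n_planes > 1) (plane - 1) / (spec$n_planes - 1) else 0
  lerp <- function(v) v[1] + f * (v[2] - v[1])
  pp <- spec$plaque_planes
  t_axial <- 0
  if (spec$plaque_max_thickness > 0 && plane >= pp[1] && plane <= pp[2]) {
    mid <- mean(pp); half <- max(1e-9, diff(pp) / 2)
    t_axial <- spec$plaque_max_thickness *
      0.5 * (1 + cos(pi * (plane - mid) / half))
    if (diff(pp) == 0) t_axial <- spec$plaque_max_thickness
  }
  list(R0 = lerp(spec$lumen_radius),
       t_med = lerp(spec$media_thickness),
       t_adv = lerp(spec$adventitia_thickness),
       t_plq = t_axial)
}

# Angular plaque thickness profile (cosine-tapered bulge), vectorized.
plaque_thickness <- function(theta, spec, t_axial) {
  if (t_axial <= 0 || spec$plaque_half_angle <= 0) return(0 * theta)
  dth <- atan2(sin(theta - spec$plaque_angle), cos(theta - spec$plaque_angle))
  out <- numeric(length(theta))
  inside <- abs(dth) < spec$plaque_half_angle
  out[inside] <- t_axial *
    0.5 * (1 + cos(pi * dth[inside] / spec$plaque_half_angle))
  out
}

#' Generate synthetic labelled cross-sections
#'
#' Rasterizes the vessel specification onto the hexagonal grid, one
#' cross-section per plane: lumen inside the (plaque-narrowed) lumen
#' boundary, plaque between that boundary and the nominal lumen radius,
#' then the media and adventitia annuli, exterior beyond.  The geometry
#' is deterministic given the specification.
#'
#' @param spec a [vessel_spec()].
#' @return List of [cross_section()] objects, each carrying a `geom`
#'   attribute with its analytic per-plane geometry (used by
#'   [generate_damage()]).
#' @export
generate_vessel <- function(spec = vessel_spec()) {
  grid <- spec$grid
  ctr <- hex_centers(grid)
  cx <- ctr$x[round(grid$n_rows / 2), round(grid$n_cols / 2)] +
    spec$eccentricity
  cy <- ctr$y[round(grid$n_rows / 2), round(grid$n_cols / 2)]
  dx <- ctr$x - cx; dy <- ctr$y - cy
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  lapply(seq_len(spec$n_planes), function(p) {
    g <- plane_geometry(spec, p)
    r_out <- g$R0 + g$t_med + g$t_adv
    if (r_out > min(cx - min(ctr$x), max(ctr$x) - cx,
                    cy - min(ctr$y), max(ctr$y) - cy))
      stop("vessel geometry exceeds the grid at plane ", p, call. = FALSE)
    tp <- plaque_thickness(th, spec, g$t_plq)
    rlb <- g$R0 - tp
    lab <- matrix(LABELS["exterior"], grid$n_rows, grid$n_cols)
    lab[r < g$R0 + g$t_med + g$t_adv] <- LABELS["adventitia"]
    lab[r < g$R0 + g$t_med] <- LABELS["media"]
    lab[r < g$R0 & tp > 0 & r >= rlb] <- LABELS["plaque"]
    lab[r < rlb] <- LABELS["lumen"]
    cs <- cross_section(grid, lab, plane_id = p,
                        axial_mm = (p - 1) * spec$plane_spacing)
    attr(cs, "geom") <- list(center = c(cx, cy), R0 = g$R0,
                             t_med = g$t_med, t_adv = g$t_adv,
                             t_plq = g$t_plq, r = NULL)
    cs
  })
}

# Vectorized damage of the layered wall at the peak of a monotone
# circumferential stretch ramp (the historical maximum is the final value,
# so the history integral collapses to a closed form).
uniaxial_final_damage <- function(lambda, params) {
  I1 <- lambda^2 + 2 / lambda
  I4 <- lambda^2
  I6 <- 1 / lambda
  k <- params$kappa
  E4 <- k * (I1 - 3) + (1 - 3 * k) * (I4 - 1)
  E6 <- k * (I1 - 3) + (1 - 3 * k) * (I6 - 1)
  wm <- matrix_energy(I1, params$c10)
  wf <- fiber_energy(E4, E6, params)
  comp <- function(w, Xi0, XiF) {
    if (is.na(Xi0) || is.na(XiF)) return(0 * w)
    smoothstep_damage(reduction_factor(damage_norm(w), Xi0, XiF))
  }
  pmax(comp(wm, params$Xi0_m, params$XiF_m),
       comp(wf$energy_A1, params$Xi0_fA1, params$XiF_fA1),
       comp(wf$energy_A2, params$Xi0_fA2, params$XiF_fA2))
}

# Vectorized plaque ductile damage at the peak stretch.
plaque_damage_lambda <- function(lambda, params) {
  eps <- pmax(0, log(pmax(lambda, params$lambda_y) / params$lambda_y))
  over <- pmax(0, eps - params$uf_pl)
  gf_eff <- params$Gf / params$char_length
  ifelse(over > 0, 1 - exp(-params$sigma_y * over / gf_eff), 0)
}

#' Generate post-intervention damage fields and laceration masks
#'
#' Emulates the outcome of the balloon-expansion stage with a virtual
#' circumferential stretch field peaking at the lumen:
#' `lambda = 1 + (expansion_ratio - 1) * R0 / r` (log-normal site noise on
#' the overstretch), where `R0` is the plane's nominal lumen radius and
#' `r` the site radius.  Media damage follows the fibrous-tissue
#' continuum-damage law at the ramp peak, plaque damage the ductile
#' surrogate, and the adventitia stays undamaged.  Element deletion at the
#' threshold then opens lacerations: deleted sites contiguous with the
#' lumen merge into it, enclosed ones become voids.  A unit expansion
#' ratio produces zero damage; raising the ratio can only grow the deleted
#' set (site noise is drawn once from the seed, independent of the ratio).
#'
#' @param sections list of cross-sections from [generate_vessel()].
#' @param expansion_ratio balloon-to-target-lumen expansion ratio `>= 1`
#'   (default 1.8).
#' @param media_p,plaque_p constitutive parameter sets.
#' @param noise_sd standard deviation of the log-normal overstretch noise.
#' @param threshold element-deletion damage threshold.
#' @param seed integer seed for the site noise.
#' @return List (one element per plane) with fields `cs` (post-deletion
#'   cross-section), `damage`, `deleted` (laceration mask),
#'   `deleted_plaque` and `lambda` matrices.
#' @export
generate_damage <- function(sections, expansion_ratio = 1.8,
                            media_p = media_params(),
                            plaque_p = plaque_params(),
                            noise_sd = 0.1, threshold = 0.8, seed = 1L) {
  if (expansion_ratio < 1)
    stop("expansion_ratio must be >= 1", call. = FALSE)
  set.seed(seed)
  lapply(sections, function(cs) {
    geom <- attr(cs, "geom")
    if (is.null(geom))
      stop("sections must carry the geometry attribute from generate_vessel",
           call. = FALSE)
    grid <- cs$grid
    ctr <- hex_centers(grid)
    r <- sqrt((ctr$x - geom$center[1])^2 + (ctr$y - geom$center[2])^2)
    noise <- matrix(exp(stats::rnorm(length(r), 0, noise_sd)),
                    nrow(r), ncol(r))
    lambda <- 1 + (expansion_ratio - 1) * (geom$R0 / pmax(r, grid$spacing)) *
      noise
    lab <- cs$label
    damage <- matrix(0, grid$n_rows, grid$n_cols)
    med <- lab == LABELS["media"]
    plq <- lab == LABELS["plaque"]
    damage[med] <- uniaxial_final_damage(lambda[med], media_p)
    damage[plq] <- plaque_damage_lambda(lambda[plq], plaque_p)
    tissue <- matrix(lab %in% TISSUE_CODES, nrow(lab), ncol(lab))
    deleted <- element_deletion(damage, threshold) & tissue
    list(cs = apply_deletion(cs, deleted),
         damage = damage,
         deleted = deleted,
         deleted_plaque = deleted & plq,
         lambda = lambda)
  })
}

#' Remove deleted sites from a cross-section
#'
#' Deleted tissue sites become voids; void regions contiguous with the
#' lumen are merged into it.
#'
#' @param cs a [cross_section()].
#' @param mask logical deletion mask.
#' @return The relabelled cross-section.
#' @export
apply_deletion <- function(cs, mask) {
  lab <- cs$label
  tissue <- matrix(lab %in% TISSUE_CODES, nrow(lab), ncol(lab))
  lab[mask & tissue] <- LABELS["void"]
  nb <- cs_neighbors(cs)
  open <- matrix(lab %in% OPEN_CODES, nrow(lab), ncol(lab))
  reach <- lab == LABELS["lumen"]
  repeat {
    grow <- open & !reach &
      matrix(neighbor_count(reach, nb) > 0, nrow(lab), ncol(lab))
    if (!any(grow)) break
    reach <- reach | grow
  }
  lab[reach] <- LABELS["lumen"]
  cross_section(cs$grid, lab, plane_id = cs$plane_id, axial_mm = cs$axial_mm)
}

#' Generate matched wall shear stress fields
#'
#' Applies the Poiseuille-style surrogate to each post-deletion lumen
#' contour and attenuates the samples nearest to laceration-lining wall
#' sites, emulating the recirculating, low-shear flow inside dissection
#' pockets: with the default attenuation those sites fall below 1 Pa for
#' physiological femoral flow.  Larger lacerations (deeper recesses)
#' receive lower minima through the surrogate's radius power law.
#'
#' @param damaged list from [generate_damage()] (post-deletion sections
#'   plus masks).
#' @param flow_rate,viscosity surrogate hemodynamics settings.
#' @param lac_attenuation multiplicative attenuation at laceration-lining
#'   samples (default 0.25).
#' @return List of per-plane data frames (`angle`, `wss`).
#' @export
generate_wss <- function(damaged, flow_rate = 100, viscosity = 0.0035,
                         lac_attenuation = 0.25) {
  lapply(damaged, function(d) {
    cs <- d$cs
    ct <- lumen_contour(cs)
    field <- wss_surrogate(ct, flow_rate, viscosity)
    lab <- cs$label
    nb <- cs_neighbors(cs)
    open_lac <- matrix(lab %in% OPEN_CODES, nrow(lab), ncol(lab)) & d$deleted
    if (any(open_lac)) {
      tissue <- matrix(lab %in% TISSUE_CODES, nrow(lab), ncol(lab))
      lining <- which(tissue & matrix(neighbor_count(open_lac, nb) > 0,
                                      nrow(lab), ncol(lab)))
      if (length(lining)) {
        ctr <- hex_centers(cs$grid)
        lum <- lab == LABELS["lumen"]
        cx <- mean(ctr$x[lum]); cy <- mean(ctr$y[lum])
        th <- atan2(ctr$y[lining] - cy, ctr$x[lining] - cx)
        dth <- abs(outer(field$angle, th, "-"))
        dth <- pmin(dth, 2 * pi - dth)
        hit <- apply(dth, 1, min) <= 2 * pi / length(field$angle)
        field$wss[hit] <- field$wss[hit] * lac_attenuation
      }
    }
    field
  })
}

#' Write a synthetic fixture bundle to disk
#'
#' Serializes sections (with damage), laceration masks and shear fields as
#' CSVs plus the specification as JSON, so a full pipeline run can be
#' reproduced without external data.
#'
#' @param spec a [vessel_spec()].
#' @param damaged list from [generate_damage()].
#' @param wss list from [generate_wss()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture_bundle <- function(spec, damaged, wss, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    lapply(unclass(spec), function(v) if (inherits(v, "hex_grid"))
      unclass(v) else v),
    file.path(dir, "vessel_spec.json"), auto_unbox = TRUE, digits = NA)
  for (i in seq_along(damaged)) {
    write_cross_section_csv(damaged[[i]]$cs,
                            file.path(dir, sprintf("section_%02d.csv", i)),
                            damage = damaged[[i]]$damage)
    utils::write.csv(
      data.frame(plane_id = i,
                 angle_or_arc_position = wss[[i]]$angle,
                 wss_pa = wss[[i]]$wss),
      file.path(dir, sprintf("wss_%02d.csv", i)), row.names = FALSE)
  }
  invisible(dir)
}
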