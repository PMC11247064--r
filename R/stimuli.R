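#' Post-intervention inflammatory curve
#'
#' Smooth bump normalized to a unit peak: zero before the onset `delay`,
#' a sin^2 rise over one day to the peak at `delay + 1`, then a raised-cosine
#' decay reaching exactly zero at `inflammation_end` and staying there.
#' Only the landmarks (peak around day 3-4, vanishing at one month) are
#' constrained by observation; the shape between them is a modeling choice
#' and fully configurable through [stimulus_params()].
#'
#' @param t time since the intervention, days (vectorized).
#' @param params a [stimulus_params()].
#' @return Inflammation level in `[0, 1]`.
#' @export
inflammation <- function(t, params = stimulus_params()) {
  d0 <- params$delay
  d1 <- params$delay + 1
  de <- params$inflammation_end
  out <- numeric(length(t))
  rise <- t >= d0 & t < d1
  out[rise] <- sin(pi / 2 * (t[rise] - d0))^2
  fall <- t >= d1 & t < de
  out[fall] <- (1 + cos(pi * (t[fall] - d1) / (de - d1))) / 2
  out
}

#' Damage-weighted inflammatory input
#'
#' Pointwise product of the (static) post-intervention damage field and the
#' inflammation level at time `t`; bounded by the damage and identically
#' zero once inflammation has vanished.
#'
#' @param damage site damage field in `[0, 1]` (vector or matrix).
#' @param t time, days.
#' @param params a [stimulus_params()].
#' @return Field with the shape of `damage`.
#' @export
dinput <- function(damage, t, params = stimulus_params()) {
  damage * inflammation(t, params)
}

#' Endothelial dysfunction level from wall shear stress
#'
#' `D(WSS) = 1 - 1 / (1 + exp(L1 * (WSS - L2)))`: for negative `L1` a
#' monotone decreasing sigmoid with value 0.5 at `WSS = L2`, approaching 1
#' at stagnant flow and 0 at high shear.
#'
#' @param wss wall shear stress, Pa (vectorized).
#' @param params a [stimulus_params()].
#' @return Dysfunction level in `(0, 1)`.
#' @export
wss_sigmoid <- function(wss, params = stimulus_params()) {
  1 - 1 / (1 + exp(params$L1 * (wss - params$L2)))
}

#' Propagate the shear-derived input across the media thickness
#'
#' Lumen-wall sites carry the dysfunction level `D(WSS)` of their own wall
#' sample.  Each deeper media site at depth `x < dist` from the wall
#' receives `D(WSS) * Amp * (1 + cos(pi * x / dist))` evaluated at its
#' nearest wall site, which reduces to the wall formula as `x -> 0` (up to
#' the factor `2 * Amp`) and vanishes continuously at `x = dist`.  Sites
#' deeper than `dist`, and all adventitia/plaque sites, receive zero, so
#' the support of the field is exactly the media band within `dist` of the
#' lumen.
#'
#' @param dwall numeric vector of `D(WSS)` values at the wall sites, named
#'   by their linear site indices (as produced by [wall_dysfunction()]).
#' @param cs a [cross_section()].
#' @param params a [stimulus_params()].
#' @param dist_field optional precomputed [distance_to_lumen()] matrix.
#' @return Matrix of shear-input values over the grid.
#' @export
propagate_wssinput <- function(dwall, cs, params = stimulus_params(),
                               dist_field = NULL) {
  out <- matrix(0, cs$grid$n_rows, cs$grid$n_cols)
  if (!length(dwall)) return(out)
  widx <- as.integer(names(dwall))
  if (is.null(dist_field))
    dist_field <- distance_to_lumen(cs, max_dist = 2 * params$dist)
  media <- cs$label == LABELS["media"]
  inner <- which(media & dist_field > 0 & dist_field < params$dist)
  ctr <- hex_centers(cs$grid)
  wx <- ctr$x[widx]; wy <- ctr$y[widx]
  if (length(inner)) {
    d2 <- outer(ctr$x[inner], wx, "-")^2 + outer(ctr$y[inner], wy, "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    x <- sqrt(d2[cbind(seq_along(inner), nearest)])
    val <- dwall[nearest] * params$Amp * (1 + cos(pi * pmin(x, params$dist) /
                                                    params$dist))
    val[x >= params$dist] <- 0
    out[inner] <- val
  }
  wall_media <- widx[cs$label[widx] == LABELS["media"]]
  out[wall_media] <- dwall[match(wall_media, widx)]
  out
}

#' Wall-site dysfunction levels from a shear field
#'
#' Assigns each lumen-wall site (tissue site adjacent to the lumen) the WSS
#' of the nearest angular sample of the field, then maps it through the
#' sigmoid.
#'
#' @param cs a [cross_section()].
#' @param wss_field data frame with columns `angle` (radians, about the
#'   lumen centroid) and `wss` (Pa), as produced by [wss_surrogate()] or
#'   [read_wss_csv()].
#' @param params a [stimulus_params()].
#' @return Named numeric vector of `D(WSS)` values keyed by wall-site
#'   linear index; the raw WSS is attached as attribute `wss`.
#' @export
wall_dysfunction <- function(cs, wss_field, params = stimulus_params()) {
  lab <- cs$label
  lum <- lab == LABELS["lumen"]
  nb <- cs_neighbors(cs)
  tissue <- matrix(lab %in% TISSUE_CODES, nrow(lab), ncol(lab))
  wall <- which(tissue & matrix(neighbor_count(lum, nb) > 0,
                                nrow(lab), ncol(lab)))
  if (!length(wall)) return(setNames(numeric(0), character(0)))
  ctr <- hex_centers(cs$grid)
  cx <- mean(ctr$x[lum]); cy <- mean(ctr$y[lum])
  th <- atan2(ctr$y[wall] - cy, ctr$x[wall] - cx)
  dth <- abs(outer(th, wss_field$angle, "-"))
  dth <- pmin(dth, 2 * pi - dth)
  nearest <- max.col(-dth, ties.method = "first")
  wss <- wss_field$wss[nearest]
  out <- stats::setNames(wss_sigmoid(wss, params), wall)
  attr(out, "wss") <- stats::setNames(wss, wall)
  out
}

#' Poiseuille-style wall shear stress surrogate
#'
#' Stands in for a CFD solution on a single cross-section.  The mean level
#' is the Poiseuille wall shear stress of the equivalent circle,
#' `tau = 4 mu Q / (pi R_eq^3)` with `R_eq = sqrt(A / pi)`, and the local
#' value is modulated by `(r_mean / r_local)^p` so that recesses (local
#' radius above the mean, e.g. laceration pockets) receive low shear.  The
#' exact Poiseuille value is recovered for a circular contour.
#'
#' @param contour lumen contour, matrix `n x 2` (mm).
#' @param flow_rate volumetric flow rate, mL/min (default 100).
#' @param viscosity effective dynamic viscosity, Pa s (default 0.0035).
#' @param p radius-modulation exponent (default 3, the Poiseuille scaling).
#' @return Data frame with columns `angle` (radians about the contour
#'   centroid) and `wss` (Pa).
#' @export
wss_surrogate <- function(contour, flow_rate = 100, viscosity = 0.0035,
                          p = 3) {
  if (flow_rate <= 0) stop("flow rate must be positive", call. = FALSE)
  area <- abs(polygon_area(contour, check = FALSE))  # mm^2
  if (area <= 0) stop("degenerate contour", call. = FALSE)
  q <- flow_rate * 1e-6 / 60                    # m^3/s
  r_eq <- sqrt(area / pi) * 1e-3                # m
  tau0 <- 4 * viscosity * q / (pi * r_eq^3)     # Pa
  cx <- mean(contour[, 1]); cy <- mean(contour[, 2])
  r <- sqrt((contour[, 1] - cx)^2 + (contour[, 2] - cy)^2)
  th <- atan2(contour[, 2] - cy, contour[, 1] - cx)
  r_mean <- mean(r)
  data.frame(angle = th, wss = tau0 * (r_mean / r)^p)
}

#' Read a per-plane wall shear stress CSV
#'
#' Expected columns: `plane_id`, `angle_or_arc_position` (radians) and
#' `wss_pa`.
#'
#' @param path CSV path.
#' @return Named list of data frames (`angle`, `wss`) keyed by plane id.
#' @export
read_wss_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("plane_id", "angle_or_arc_position", "wss_pa")
  if (!all(need %in% names(df)))
    stop("WSS CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) stop("WSS CSV is empty", call. = FALSE)
  if (any(df$wss_pa < 0)) stop("negative WSS in ", path, call. = FALSE)
  split_df <- split(df, df$plane_id)
  lapply(split_df, function(d)
    data.frame(angle = d$angle_or_arc_position, wss = d$wss_pa))
}
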