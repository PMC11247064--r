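#' Arterial layer material parameters
#'
#' Constructs the parameter set of the anisotropic hyperelastic strain-energy
#' function with two fiber families and, for the media, continuum damage of
#' the isotropic matrix and of each fiber family.  Defaults are the media and
#' adventitia values calibrated on human distal superficial femoral artery
#' specimens.  Energy-norm damage thresholds (`Xi0_*`, `XiF_*`) are in
#' MPa^(1/2); stiffnesses in MPa; `k2`, `k4` and `kappa` are dimensionless.
#'
#' The adventitia carries no damage parameters: damage is disabled for that
#' layer and its damage variables stay identically zero.
#'
#' @param c10 matrix (neo-Hookean) stiffness, MPa.
#' @param k1,k3 fiber stiffnesses of the circumferential and longitudinal
#'   families, MPa.
#' @param k2,k4 dimensionless fiber exponents.
#' @param kappa fiber dispersion in `[0, 1/3]`; `0` means perfectly aligned
#'   families, `1/3` the isotropic limit.
#' @param Xi0_m,XiF_m matrix damage onset/saturation energy norms.
#' @param Xi0_fA1,XiF_fA1,Xi0_fA2,XiF_fA2 fiber damage onset/saturation
#'   energy norms per family; `NA` disables damage for that component.
#' @param layer `"media"` or `"adventitia"`.
#' @return An object of class `layer_params`.
#' @export
layer_params <- function(c10, k1, k2, k3, k4, kappa = 0,
                         Xi0_m = NA_real_, XiF_m = NA_real_,
                         Xi0_fA1 = NA_real_, XiF_fA1 = NA_real_,
                         Xi0_fA2 = NA_real_, XiF_fA2 = NA_real_,
                         layer = c("media", "adventitia")) {
  layer <- match.arg(layer)
  stopifnot(c10 >= 0, k1 >= 0, k2 >= 0, k3 >= 0, k4 >= 0)
  if (kappa < 0 || kappa > 1 / 3)
    stop("kappa must lie in [0, 1/3]", call. = FALSE)
  chk <- function(x0, xF, nm) {
    if (!is.na(x0) && !is.na(xF) && xF <= x0)
      stop("XiF must exceed Xi0 for ", nm, call. = FALSE)
  }
  chk(Xi0_m, XiF_m, "matrix")
  chk(Xi0_fA1, XiF_fA1, "fiber family A1")
  chk(Xi0_fA2, XiF_fA2, "fiber family A2")
  structure(list(c10 = c10, k1 = k1, k2 = k2, k3 = k3, k4 = k4,
                 kappa = kappa,
                 Xi0_m = Xi0_m, XiF_m = XiF_m,
                 Xi0_fA1 = Xi0_fA1, XiF_fA1 = XiF_fA1,
                 Xi0_fA2 = Xi0_fA2, XiF_fA2 = XiF_fA2,
                 layer = layer),
            class = "layer_params")
}

#' @rdname layer_params
#' @export
media_params <- function() {
  layer_params(c10 = 0.183, k1 = 0.080, k2 = 0.253, k3 = 0.127, k4 = 0.217,
               kappa = 0,
               Xi0_m = 0.497, XiF_m = 0.808,
               Xi0_fA1 = 0.005, XiF_fA1 = 2.323,
               Xi0_fA2 = 0.040, XiF_fA2 = 2.179,
               layer = "media")
}

#' @rdname layer_params
#' @export
adventitia_params <- function() {
  layer_params(c10 = 0.104, k1 = 0.168, k2 = 0.009, k3 = 0.205, k4 = 0.009,
               kappa = 0, layer = "adventitia")
}

#' Plaque material parameters (ductile-damage surrogate)
#'
#' Elastic-perfectly-plastic plaque description with energy-regularized
#' exponential damage.  Yield occurs at stretch `lambda_y` under yield stress
#' `sigma_y`; damage initiates once the accumulated equivalent plastic strain
#' reaches `uf_pl` and then evolves as `1 - exp(-W_pl / (Gf / char_length))`
#' where `W_pl` is the plastic work density dissipated after initiation.
#'
#' @param c10 neo-Hookean stiffness, MPa.
#' @param sigma_y Cauchy yield stress, MPa.
#' @param lambda_y yield stretch (> 1), dimensionless.
#' @param Gf fracture energy, mJ/mm^2.
#' @param uf_pl equivalent plastic strain at damage initiation.
#' @param char_length regularization length converting `Gf` to a volumetric
#'   energy, mm.  Defaults to 0.5 mm, the scale of the coarse plaque
#'   tetrahedral elements the ductile model regularizes over.
#' @return An object of class `plaque_params`.
#' @export
plaque_params <- function(c10 = 0.0863, sigma_y = 0.43, lambda_y = 1.75,
                          Gf = 0.0215, uf_pl = 0.1, char_length = 0.5) {
  stopifnot(c10 >= 0, sigma_y >= 0, Gf >= 0, uf_pl >= 0, char_length > 0)
  if (lambda_y <= 1) stop("lambda_y must exceed 1", call. = FALSE)
  structure(list(c10 = c10, sigma_y = sigma_y, lambda_y = lambda_y,
                 Gf = Gf, uf_pl = uf_pl, char_length = char_length),
            class = "plaque_params")
}

#' Stimulus-field parameters
#'
#' Parameters of the two inputs driving the agent-based model: the
#' damage-weighted inflammatory input and the wall-shear-stress-derived
#' input.  `L1` (Pa^-1, negative) and `L2` (Pa) shape the sigmoidal
#' endothelial-dysfunction response `D(WSS)`; `Amp` and `dist` (mm) control
#' the sinusoidal propagation of the shear input across the media thickness;
#' `delay` and `inflammation_end` (days) are the landmarks of the
#' post-intervention inflammatory curve.
#'
#' @param L1 sigmoid slope, Pa^-1.
#' @param L2 WSS at which the dysfunction level equals 0.5, Pa.
#' @param Amp propagation scaling, dimensionless.
#' @param dist propagation depth into the media, mm.
#' @param delay inflammation onset delay after the intervention, days.
#' @param inflammation_end time at which inflammation has vanished, days.
#' @return An object of class `stimulus_params`.
#' @export
stimulus_params <- function(L1 = -7.5, L2 = 5, Amp = 1, dist = 0.1415,
                            delay = 3, inflammation_end = 30) {
  stopifnot(dist > 0, delay >= 0)
  if (inflammation_end <= delay)
    stop("inflammation_end must exceed delay", call. = FALSE)
  structure(list(L1 = L1, L2 = L2, Amp = Amp, dist = dist,
                 delay = delay, inflammation_end = inflammation_end),
            class = "stimulus_params")
}

#' Agent-based model rate parameters
#'
#' Per-cycle event probabilities/weights of the cellular automaton.
#' `alpha1` is the baseline mitosis and apoptosis probability of cells,
#' `alpha2`/`alpha3` the shear and inflammatory boosts to mitosis,
#' `alpha4` the baseline matrix-production probability, `alpha5`/`alpha6`
#' the corresponding boosts to production, and `beta_med`/`beta_adv` the
#' degradation divisors of the media and adventitia.
#'
#' The default `beta_med` is the calibrated equilibrium value
#' `ECM/SMC = 1/0.72` of the initial media composition, which balances
#' matrix production (hosted by smooth muscle cells) against degradation
#' (hosted by matrix agents) on the common matrix clock; see
#' [calibrate_beta_med()].  The literature value 1.85 remains available by
#' passing it explicitly.
#'
#' @param alpha1,alpha2,alpha3,alpha4,alpha5,alpha6 event weights, `>= 0`.
#' @param beta_med,beta_adv degradation divisors, `> 0`.
#' @param migration_threshold minimum post-intervention site damage for a
#'   lumen-lining smooth muscle cell to become a migration candidate.
#' @return An object of class `abm_rates`.
#' @export
abm_rates <- function(alpha1 = 0.05, alpha2 = 0.11, alpha3 = 0.66,
                      alpha4 = 0.008, alpha5 = 0.0413, alpha6 = 0.21,
                      beta_med = calibrate_beta_med(),
                      beta_adv = 2.5,
                      migration_threshold = 0.5) {
  a <- c(alpha1, alpha2, alpha3, alpha4, alpha5, alpha6)
  stopifnot(all(a >= 0), beta_med > 0, beta_adv > 0,
            migration_threshold >= 0, migration_threshold <= 1)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 alpha4 = alpha4, alpha5 = alpha5, alpha6 = alpha6,
                 beta_med = beta_med, beta_adv = beta_adv,
                 migration_threshold = migration_threshold),
            class = "abm_rates")
}

#' Equilibrium media degradation divisor
#'
#' Under homeostasis (zero stimuli) matrix production events are hosted by
#' smooth muscle cells with probability `alpha4` and degradation events by
#' matrix agents with probability `alpha4 / beta_med`, both on the matrix
#' clock.  Expected production balances expected degradation when
#' `beta_med` equals the matrix-to-cell count ratio, i.e. the reciprocal of
#' the SMC/ECM composition ratio.
#'
#' @param smc_ecm_ratio initial SMC/ECM site-count ratio of the media.
#' @return The equilibrium `beta_med`.
#' @export
calibrate_beta_med <- function(smc_ecm_ratio = 0.72) {
  stopifnot(smc_ecm_ratio > 0)
  1 / smc_ecm_ratio
}

#' Media/adventitia seeding composition
#'
#' @param smc_ecm media SMC/ECM site-count ratio.
#' @param collagen_elastin media collagen/elastin ratio within the ECM.
#' @param fibroblast_collagen adventitia fibroblast/collagen ratio.
#' @return An object of class `abm_composition`.
#' @export
abm_composition <- function(smc_ecm = 0.72, collagen_elastin = 0.63,
                            fibroblast_collagen = 0.43) {
  stopifnot(smc_ecm > 0, collagen_elastin > 0, fibroblast_collagen > 0)
  structure(list(smc_ecm = smc_ecm, collagen_elastin = collagen_elastin,
                 fibroblast_collagen = fibroblast_collagen),
            class = "abm_composition")
}

#' Full simulator configuration
#'
#' Bundles every tunable parameter of the framework into one nested list
#' that can be round-tripped through YAML or JSON.  Keys mirror the symbols
#' of the constitutive, stimulus and agent-rate tables.
#'
#' @param ... named overrides of top-level sections (`media`, `adventitia`,
#'   `plaque`, `stimulus`, `rates`, `composition`, `run`).
#' @return Nested configuration list of class `restenosim_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    media = unclass(media_params()),
    adventitia = unclass(adventitia_params()),
    plaque = unclass(plaque_params()),
    stimulus = unclass(stimulus_params()),
    rates = unclass(abm_rates()),
    composition = unclass(abm_composition()),
    run = list(n_planes = 11, plane_spacing = 2, replicates = 3,
               horizon_days = 60, coupling_days = 30, dt_hours = 2,
               T_cell = 24, T_ecm = 4, seed = 1,
               flow_rate = 100, viscosity = 0.0035,
               grid_rows = 300, grid_cols = 300, spacing = 0.0375)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(dots)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  class(cfg) <- "restenosim_config"
  cfg
}

#' Read or write a configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`) serialization of a configuration.
#' Unknown keys raise an error listing the offenders, so typos in hand-edited
#' files are caught early.
#'
#' @param path file path; the extension selects the format.
#' @param cfg configuration list as produced by [default_config()].
#' @return `read_config()` returns a validated `restenosim_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- default_config()
  bad <- setdiff(names(raw), names(base))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(base[[sec]]))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    base[[sec]] <- utils::modifyList(base[[sec]], raw[[sec]])
  }
  base
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  plain <- lapply(unclass(cfg), function(sec) {
    sec$layer <- NULL
    lapply(sec, function(v) if (is.na(v[1]) && length(v) == 1) NULL else v)
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(plain, path)
  }
  invisible(path)
}
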