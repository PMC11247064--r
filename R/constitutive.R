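#' Deformation state for point-wise constitutive evaluation
#'
#' Holds the isochoric right Cauchy-Green tensor together with the two
#' rank-one structural tensors of the fiber architecture, built from unit
#' circumferential and longitudinal direction vectors.
#'
#' @param Cbar 3x3 symmetric matrix with `det(Cbar) = 1` (isochoric).
#' @param n_c,n_l unit vectors of the circumferential and longitudinal fiber
#'   families (normalized internally).
#' @param tol tolerance on `det(Cbar) - 1` and on symmetry.
#' @return Object of class `deformation_state` with fields `Cbar`, `A1`, `A2`.
#' @export
deformation_state <- function(Cbar, n_c = c(1, 0, 0), n_l = c(0, 0, 1),
                              tol = 1e-6) {
  Cbar <- as.matrix(Cbar)
  if (!all(dim(Cbar) == c(3, 3)) || max(abs(Cbar - t(Cbar))) > tol)
    stop("Cbar must be a symmetric 3x3 matrix", call. = FALSE)
  if (abs(det(Cbar) - 1) > 1e-4)
    stop("invalid deformation: det(Cbar) = ", format(det(Cbar)),
         " differs from 1 beyond tolerance", call. = FALSE)
  n_c <- n_c / sqrt(sum(n_c^2))
  n_l <- n_l / sqrt(sum(n_l^2))
  structure(list(Cbar = Cbar,
                 A1 = tcrossprod(n_c),
                 A2 = tcrossprod(n_l)),
            class = "deformation_state")
}

#' Isochoric deformation state for a uniaxial circumferential stretch
#'
#' Convenience constructor for the deformation used throughout the virtual
#' balloon expansion: stretch `lambda` along the circumferential fiber axis
#' with equal transverse contraction `1/sqrt(lambda)` so the state stays
#' isochoric.
#'
#' @param lambda circumferential stretch, `> 0`.
#' @return A `deformation_state` with `n_c` on the first axis and `n_l` on
#'   the third.
#' @export
uniaxial_stretch_state <- function(lambda) {
  if (lambda <= 0) stop("stretch must be positive", call. = FALSE)
  deformation_state(diag(c(lambda^2, 1 / lambda, 1 / lambda)),
                    n_c = c(1, 0, 0), n_l = c(0, 0, 1))
}

#' Isochoric invariants of the deformation
#'
#' `I1bar = tr(Cbar)`, `I4bar = Cbar : A1`, `I6bar = Cbar : A2`.
#'
#' @param def a [deformation_state()].
#' @return List with `I1bar`, `I4bar`, `I6bar`.
#' @export
isochoric_invariants <- function(def) {
  stopifnot(inherits(def, "deformation_state"))
  list(I1bar = sum(diag(def$Cbar)),
       I4bar = sum(def$Cbar * def$A1),
       I6bar = sum(def$Cbar * def$A2))
}

#' Dispersed fiber strain measures
#'
#' `E4bar = kappa*(I1bar - 3) + (1 - 3*kappa)*(I4bar - 1)` and analogously
#' for `E6bar`.  The Macaulay bracket (compression exclusion) is applied by
#' the energy evaluation downstream, not here.
#'
#' @param inv invariant list from [isochoric_invariants()].
#' @param kappa fiber dispersion in `[0, 1/3]`.
#' @return List with `E4bar`, `E6bar`.
#' @export
fiber_strains <- function(inv, kappa = 0) {
  if (kappa < 0 || kappa > 1 / 3)
    stop("kappa must lie in [0, 1/3]", call. = FALSE)
  list(E4bar = kappa * (inv$I1bar - 3) + (1 - 3 * kappa) * (inv$I4bar - 1),
       E6bar = kappa * (inv$I1bar - 3) + (1 - 3 * kappa) * (inv$I6bar - 1))
}

#' Undamaged matrix strain energy
#'
#' `W = c10 * (I1bar - 3)`, clamped at zero from below to guard against
#' round-off slightly under the reference value 3.
#'
#' @param I1bar first isochoric invariant.
#' @param c10 matrix stiffness, MPa.
#' @return Energy density, MPa.
#' @export
matrix_energy <- function(I1bar, c10) {
  pmax(0, c10 * (I1bar - 3))
}

#' Undamaged fiber strain energies per family
#'
#' `k1/(2 k2) * (exp(k2 <E4>^2) - 1)` for the circumferential family and the
#' analogous `k3`,`k4` expression for the longitudinal one, with Macaulay
#' brackets excluding compressed fibers.  For a vanishing exponent the
#' quadratic limit `k/2 * <E>^2` is used.
#'
#' @param E4bar,E6bar fiber strain measures.
#' @param params a [layer_params()].
#' @return List with `energy_A1`, `energy_A2` (MPa).
#' @export
fiber_energy <- function(E4bar, E6bar, params) {
  e4 <- pmax(0, E4bar)
  e6 <- pmax(0, E6bar)
  fam <- function(k, kexp, e) {
    if (kexp == 0) k / 2 * e^2 else k / (2 * kexp) * (exp(kexp * e^2) - 1)
  }
  list(energy_A1 = fam(params$k1, params$k2, e4),
       energy_A2 = fam(params$k3, params$k4, e6))
}

#' Energy norm driving damage
#'
#' `Xi = sqrt(2 * W0)` where `W0` is the undamaged energy of the component.
#'
#' @param undamaged_energy component energy, MPa, `>= 0`.
#' @return Norm in MPa^(1/2).
#' @export
damage_norm <- function(undamaged_energy) {
  if (any(undamaged_energy < 0))
    stop("invalid state: negative strain energy", call. = FALSE)
  sqrt(2 * undamaged_energy)
}

#' Linear damage driver from the historical maximum energy norm
#'
#' `s = clamp((Xi_max - Xi0) / (XiF - Xi0), 0, 1)`.  The historical maximum
#' (not the instantaneous norm) enters so that damage is irreversible along
#' any loading history.
#'
#' @param Xi_history_max largest energy norm reached so far.
#' @param Xi0,XiF onset and saturation norms, `XiF > Xi0`.
#' @return `s` in `[0, 1]`.
#' @export
reduction_factor <- function(Xi_history_max, Xi0, XiF) {
  if (any(XiF <= Xi0)) stop("XiF must exceed Xi0", call. = FALSE)
  pmin(1, pmax(0, (Xi_history_max - Xi0) / (XiF - Xi0)))
}

#' Quintic smoothstep damage variable
#'
#' `d = s^3 * (10 - 15 s + 6 s^2)`: monotone, with `d(0) = 0`, `d(1) = 1`
#' and vanishing first derivative at both ends.
#'
#' @param s damage driver in `[0, 1]`; values outside are clamped with a
#'   warning.
#' @return `d` in `[0, 1]`.
#' @export
smoothstep_damage <- function(s) {
  if (any(s < 0 | s > 1)) {
    warning("s outside [0, 1]; clamping")
    s <- pmin(1, pmax(0, s))
  }
  s^3 * (10 - 15 * s + 6 * s^2)
}

#' Fresh (undamaged) damage state
#'
#' @return Object of class `damage_state` with all damage variables and
#'   historical energy-norm maxima at zero.
#' @export
damage_state <- function() {
  structure(list(d_m = 0, d_fA1 = 0, d_fA2 = 0,
                 ximax_m = 0, ximax_fA1 = 0, ximax_fA2 = 0),
            class = "damage_state")
}

damage_from_params <- function(ximax, Xi0, XiF) {
  if (is.na(Xi0) || is.na(XiF)) return(0)
  smoothstep_damage(reduction_factor(ximax, Xi0, XiF))
}

#' Damage-reduced total isochoric strain energy
#'
#' `W = (1 - d_m) W0_m + (1 - d_fA1) W0_fA1 + (1 - d_fA2) W0_fA2`.
#'
#' @param def a [deformation_state()].
#' @param params a [layer_params()].
#' @param dmg a `damage_state`.
#' @return Total energy density, MPa.
#' @export
damaged_sef <- function(def, params, dmg = damage_state()) {
  inv <- isochoric_invariants(def)
  es <- fiber_strains(inv, params$kappa)
  wm <- matrix_energy(inv$I1bar, params$c10)
  wf <- fiber_energy(es$E4bar, es$E6bar, params)
  (1 - dmg$d_m) * wm +
    (1 - dmg$d_fA1) * wf$energy_A1 +
    (1 - dmg$d_fA2) * wf$energy_A2
}

#' Integrate damage along a deformation history
#'
#' Walks an ordered deformation history; at each step the component energy
#' norms are evaluated, the historical maxima updated, and the damage
#' variables recomputed through the smoothstep law.  Each damage variable is
#' non-decreasing along the trajectory; adventitia parameters (no damage
#' thresholds) yield identically zero damage.
#'
#' @param def_history list of [deformation_state()] objects, or a numeric
#'   vector of circumferential stretches (converted through
#'   [uniaxial_stretch_state()]).
#' @param params a [layer_params()].
#' @param init starting `damage_state` (for restarting a history).
#' @return List of `damage_state` objects, one per history step; empty list
#'   for an empty history.
#' @export
evolve_damage <- function(def_history, params, init = damage_state()) {
  if (is.numeric(def_history))
    def_history <- lapply(def_history, uniaxial_stretch_state)
  out <- vector("list", length(def_history))
  st <- init
  for (i in seq_along(def_history)) {
    def <- def_history[[i]]
    inv <- isochoric_invariants(def)
    es <- fiber_strains(inv, params$kappa)
    wm <- matrix_energy(inv$I1bar, params$c10)
    wf <- fiber_energy(es$E4bar, es$E6bar, params)
    st$ximax_m <- max(st$ximax_m, damage_norm(wm))
    st$ximax_fA1 <- max(st$ximax_fA1, damage_norm(wf$energy_A1))
    st$ximax_fA2 <- max(st$ximax_fA2, damage_norm(wf$energy_A2))
    st$d_m <- damage_from_params(st$ximax_m, params$Xi0_m, params$XiF_m)
    st$d_fA1 <- damage_from_params(st$ximax_fA1, params$Xi0_fA1, params$XiF_fA1)
    st$d_fA2 <- damage_from_params(st$ximax_fA2, params$Xi0_fA2, params$XiF_fA2)
    out[[i]] <- st
  }
  out
}

#' Scalar tissue damage reached at the end of a stretch history
#'
#' The maximum of the matrix and fiber damage variables, the conservative
#' scalar used for element deletion and stimulus weighting.
#'
#' @inheritParams evolve_damage
#' @return Damage in `[0, 1]`.
#' @export
final_damage <- function(def_history, params) {
  tr <- evolve_damage(def_history, params)
  if (!length(tr)) return(0)
  st <- tr[[length(tr)]]
  max(st$d_m, st$d_fA1, st$d_fA2)
}

#' One-dimensional plaque ductile damage surrogate
#'
#' Perfect plasticity under uniaxial stretch: plastic flow starts once the
#' stretch exceeds `lambda_y`, accumulating equivalent (logarithmic) plastic
#' strain at constant stress `sigma_y`.  Damage initiates when the
#' accumulated plastic strain reaches `uf_pl`; afterwards it evolves
#' exponentially with the plastic work dissipated beyond initiation,
#' normalized by the fracture energy over the characteristic length:
#' `D = 1 - exp(-sigma_y * (eps_pl - uf_pl) * char_length / Gf)`,
#' saturating at 1.
#'
#' @param stretch_history numeric vector of stretches starting at 1.
#' @param params a [plaque_params()].
#' @return Damage in `[0, 1]` at the end of the history.
#' @export
plaque_damage_1d <- function(stretch_history, params = plaque_params()) {
  if (any(stretch_history <= 0))
    stop("non-physical stretch <= 0", call. = FALSE)
  lam_max <- max(stretch_history, 1)
  if (lam_max <= params$lambda_y) return(0)
  eps_pl <- log(lam_max / params$lambda_y)
  if (eps_pl <= params$uf_pl) return(0)
  gf_eff <- params$Gf / params$char_length        # mJ/mm^3 == MPa
  1 - exp(-params$sigma_y * (eps_pl - params$uf_pl) / gf_eff)
}

#' Element deletion mask from a damage field
#'
#' Marks every site whose damage reaches the deletion threshold; deleted
#' tissue represents lacerations/dissections opened by the balloon.
#' Lowering the threshold can only add sites to the mask.
#'
#' @param damage_field numeric vector or matrix of damage values in `[0, 1]`.
#' @param threshold deletion threshold (default 0.8).
#' @return Logical mask with the shape of `damage_field`.
#' @export
element_deletion <- function(damage_field, threshold = 0.8) {
  stopifnot(all(damage_field >= 0 & damage_field <= 1, na.rm = TRUE))
  mask <- damage_field >= threshold
  mask[is.na(mask)] <- FALSE
  mask
}
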