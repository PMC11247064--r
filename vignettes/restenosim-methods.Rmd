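---
title: "Modeling post-angioplasty restenosis on a hexagonal lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling post-angioplasty restenosis on a hexagonal lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`restenosim` is a desk-scale simulator of arterial wall remodeling in the
weeks after balloon angioplasty of a peripheral (femoral-type) artery.
Restenosis — the re-narrowing of the treated lumen — is driven by smooth
muscle cell (SMC) proliferation and extracellular matrix (ECM) synthesis,
triggered by the mechanical injury of the intervention and modulated by
wall shear stress (WSS).  The package couples four ingredients:

1. a **constitutive library** for the fibrous wall: an anisotropic
   hyperelastic strain-energy function with two fiber families and
   continuum damage, plus an elastoplastic ductile-damage surrogate for
   the plaque;
2. a **stimulus module** that converts (i) the post-intervention damage
   field and a transient inflammation clock and (ii) per-site WSS into
   the two inputs that drive cell behavior;
3. a **cellular automaton** on a hexagonal lattice that remodels each
   vessel cross-section with probabilistic mitosis/apoptosis, ECM
   production/degradation and SMC migration into lacerations;
4. a **synthetic vessel/damage/WSS generator** standing in for the
   patient-specific imaging, finite-element expansion and CFD stages,
   which are out of scope.

A multi-plane pipeline runs replicate simulations per cross-section,
selects representative replicates, recomputes WSS on the remodeled lumen
at a monthly coupling boundary, and lofts the per-plane contours into a
3D lumen surface.

# The wall model

## Layered anisotropic hyperelasticity with damage

Media and adventitia are modeled with an isotropic neo-Hookean matrix
plus two exponential fiber families along the circumferential and
longitudinal directions.  With the isochoric right Cauchy–Green tensor
$\bar{\mathbf{C}}$ and structural tensors
$\mathbf{A}_1 = \mathbf{n}_c \otimes \mathbf{n}_c$,
$\mathbf{A}_2 = \mathbf{n}_l \otimes \mathbf{n}_l$, the invariants are
$\bar I_1 = \operatorname{tr}\bar{\mathbf{C}}$,
$\bar I_4 = \bar{\mathbf{C}} : \mathbf{A}_1$,
$\bar I_6 = \bar{\mathbf{C}} : \mathbf{A}_2$, and the dispersed fiber
strains are
$\bar E_{4,6} = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar I_{4,6} - 1)$.
The undamaged energies are $\bar W^m = c_{10}(\bar I_1 - 3)$ and
$\bar W^f = \tfrac{k_1}{2k_2}(e^{k_2\langle\bar E_4\rangle^2} - 1) +
\tfrac{k_3}{2k_4}(e^{k_4\langle\bar E_6\rangle^2} - 1)$, with the
Macaulay bracket excluding compressed fibers.  Damage reduces each
component independently,
$\bar W = (1-d^m)\bar W_0^m + (1-d^f_{A_1})\bar W_0^{f,1} +
(1-d^f_{A_2})\bar W_0^{f,2}$,
through a quintic smoothstep $d = s^3(10 - 15s + 6s^2)$ of the linear
driver $s = (\Xi - \Xi_0)/(\Xi_F - \Xi_0)$, where
$\Xi = \sqrt{2\bar W_0}$ is an energy norm.  Defaults are the media and
adventitia parameter sets calibrated on human distal superficial femoral
artery specimens (`media_params()`, `adventitia_params()`); the
adventitia set carries no damage thresholds and its damage is disabled.

Two modeling decisions deserve emphasis:

* **Irreversibility.**  The damage law is stated point-wise in
  $\bar{\mathbf{C}}$; evaluating it on the current state alone would let
  unloading "heal" the wall.  `evolve_damage()` therefore evaluates $s$
  at the historical maximum of $\Xi$, the standard continuum-damage
  convention, making every damage variable non-decreasing along any
  loading path (property-tested over random histories).
* **Fiber dispersion.**  $\kappa$ appears in the strain measures but no
  calibrated value accompanies the stiffness table; the default is
  $\kappa = 0$ (perfectly aligned families), under which the formulas
  reduce to the classical two-family model and all published stiffness
  values retain their meaning.  $\kappa$ is configurable up to the
  isotropic limit $1/3$, at which the energy provably loses its
  directional dependence (tested).

## Plaque ductile-damage surrogate

The plaque is elastic–perfectly-plastic (yield stress $\sigma_y$, yield
stretch $\lambda_y$) with damage initiating at an equivalent plastic
strain $u_f^{pl}$ and evolving exponentially with the plastic work
dissipated after initiation, normalized by the fracture energy $G_f$
over a characteristic length:
$D = 1 - \exp\!\big(-\sigma_y(\varepsilon^{pl} - u_f^{pl})\,
L_c / G_f\big)$.
This reproduces the behavior of an energy-regularized ductile-damage
model without a finite-element mesh.  $L_c$ defaults to 0.5 mm, the
scale of the coarse plaque tetrahedra such a model regularizes over:
with that choice the published $(\sigma_y, G_f, u_f^{pl})$ make the
plaque tear (reach the deletion threshold) at local stretches around
2.3, which a balloon overexpansion plausibly produces at a stenotic
throat.  Regularizing over the lattice spacing (0.0375 mm) instead
would require stretches above 15 — the plaque could never tear — so the
site spacing is *not* an admissible default for this parameter.

## Element deletion

Sites whose scalar damage (the maximum of matrix and fiber components,
a conservative choice) reaches 0.8 are removed: `apply_deletion()`
relabels them as void and merges void regions contiguous with the lumen
into it.  These openings are the model's lacerations/dissections.

# Stimuli

## Inflammation and the damage input

The inflammatory input at site $h$ is
$Dinput^h = damage^h \times Inflammation(t)$, with the damage field
static (it is the footprint of the intervention) and the inflammation
curve transient.  Only two landmarks of the curve are constrained by
observation — a peak a few days after the intervention and extinction at
one month — so the package uses a smooth bump: zero before the onset
delay (3 days), a $\sin^2$ rise over one day, and a raised-cosine decay
to exactly zero at day 30.  Both landmarks and the shape parameters are
configurable; no result in the test suite depends on the shape between
the landmarks.

## Shear input

Each lumen-wall site $i$ carries an endothelial dysfunction level
$D(WSS)^i = 1 - 1/(1 + e^{L_1(WSS^i - L_2)})$ — a decreasing sigmoid
with half-maximum at $L_2$ (5 Pa) and slope $L_1$ (−7.5 Pa$^{-1}$) —
and the input propagates into the media as
$WSSinput^h = D(WSS)^{i(h)} \cdot Amp \cdot
(1 + \cos(\pi x / dist))$
for $x < dist$ (0.1415 mm), zero deeper, where $i(h)$ is the wall site
nearest to $h$ and $x$ the distance to it.  Pairing each interior site
with its *nearest* wall site (rather than summing contributions over
all wall sites within $dist$) keeps the input within its documented
range $[0, 2\,Amp]$; a sum over the roughly seven wall sites within
range would reach $\approx 7.5$ at the wall, saturate every mitosis
probability and close the lumen within days.

WSS itself comes either from an external per-plane CSV (the interface
to a CFD solution) or from `wss_surrogate()`: the Poiseuille wall shear
stress of the equivalent circle, $\tau = 4\mu Q / (\pi R_{eq}^3)$ at
100 mL/min and 3.5 mPa s, modulated by $(r_{mean}/r_{local})^3$ so that
recesses — laceration pockets with a locally enlarged radius — receive
low shear.  The surrogate reproduces the exact Poiseuille value on a
circle (about 1.65 Pa at 3.3 mm diameter).  Following the coupled
scheme, the shear field is recomputed only at coupling boundaries
(monthly), not every step.

# The cellular automaton

Each plane is a 300 × 300 hexagonal lattice at 0.0375 mm/site (about
1.5 cells per site at a 25 µm SMC diameter).  Media sites hold SMCs,
collagen and elastin (SMC/ECM 0.72, collagen/elastin 0.63); adventitia
sites hold fibroblasts and collagen (0.43); plaque sites hold inert
plaque matrix.  Agents carry desynchronized clocks — 24 h for cells,
4 h for matrix turnover — advanced in 2-h steps; an agent is tested for
events only when its cycle wraps.

## Events

Probabilities per cycle, in the media:
division $\alpha_1 + \alpha_2 WSSinput + \alpha_3 Dinput$ (clamped to
$[0,1]$), apoptosis $\alpha_1$, ECM production
$\alpha_4 + \alpha_5 WSSinput + \alpha_6 Dinput$, ECM degradation
$\alpha_4/\beta_{med}$; in the adventitia the baseline values apply with
$\beta_{adv}$.  Production is hosted by the cells (SMCs synthesize
matrix; matrix does not synthesize itself) on the matrix clock, and
degradation by the matrix agents; produced matrix draws collagen or
elastin from the composition ratio so the ECM mix stays stationary.

Two mechanical conventions keep the neutral model exactly neutral:

* Division and apoptosis are decided by *independent* uniform draws and
  cancel when both fire.  Testing apoptosis only when division failed
  would make the effective death rate $(1-p_{div})\alpha_1 < p_{div}$
  and shrink the lumen by double-digit percentages over two months with
  no stimulus at all.
* $\beta_{med}$ defaults to the calibrated equilibrium value: expected
  production balances expected degradation when
  $\beta_{med} = N_{ECM}/N_{SMC} = 1/0.72 \approx 1.389$
  (`calibrate_beta_med()`).  The literature value 1.85 can be supplied
  explicitly; under this hosting scheme it would grow the media by
  roughly 30% in 60 unstimulated days, violating the homeostasis
  criterion the parameters are meant to satisfy.

## Growth mechanics

Media insertions (mitosis, production) place the new agent at the event
site and displace the radial chain of agents one site toward the lumen;
the innermost open site becomes tissue, so the lumen loses exactly one
site per event.  Removals collapse the chain and open one wall site.
Adventitia chains displace through the outer boundary, leaving the
lumen untouched.  Chains walk from the event site toward (or away from)
the lumen centroid, choosing at each hop the neighbor that strictly
approaches (or recedes from) it; a walk blocked by the grid edge skips
the event with a log entry.  Events drawn at the start of a step are
applied in random order; an event whose host was displaced by an
earlier chain in the same step is still applied at its site (only
sites that are no longer tissue are skipped), which keeps the expected
event count equal to the sum of the drawn probabilities.

## Migration

Lumen-lining media SMCs with site damage at or above 0.5 are migration
candidates; the target pool is fixed at initialization as the open
sites in and around the laceration-deleted plaque region, and each
occupied target is spent permanently, so migration halts after at most
the initial pool size — the published halting rule.  A candidate fires
with probability $\min(1, 1/d_{min})$ (distance in site units to the
nearest free target, ties toward the lowest site index), occupies that
target as media tissue, and its vacated wall site joins the lumen.
The candidate threshold cannot be the 0.8 deletion threshold: any site
at 0.8 has already been deleted, so that choice would make the
candidate set empty by construction.

## Boundary smoothing

Once per simulated day a majority-vote pass regularizes the interface:
lumen sites with more than four tissue neighbors (pits) and media sites
with more than four open neighbors (spikes) are flip candidates.  Fills
and carves are applied in matched pairs ordered by severity, so a pass
never changes the lumen site count; on a hexagonal lattice pits are
detected more readily than spikes, and an unpaired vote demonstrably
pushes the wall inward by ~15% area over 60 days.  Filled sites inherit
the kind of a random adjacent media agent to leave the local
composition unbiased.

# Multi-plane pipeline

Per plane and coupling cycle (30 days), `run_framework()` advances
three replicates, resamples each final lumen contour to 360 radii
about the shared centroid, and selects the replicate minimizing the
RMSD from the pointwise-mean contour (ties toward the lowest index).
All replicates restart from the selected state — keeping inter-replicate
variance interpretable per cycle — and WSS is recomputed on the
selected contour.  The per-plane contours (200 vertices, start vertex
at angle zero about each centroid) are lofted into ruled triangle
bands and written as ASCII PLY/OBJ.  Runs are deterministic given the
base seed: every replicate derives its stream from (plane, cycle,
replicate), which also makes a 30 + 30 day checkpoint-restart exactly
equal to a 60-day run (tested).

# Synthetic data

`generate_vessel()` rasterizes an idealized post-intervention femoral
segment: 11 planes at 2 mm, lumen diameter tapering 3.3 → 2.9 mm,
media/adventitia annuli growing 0.35 → ~0.5 mm, and an eccentric
plaque (100° half-angle, up to 1 mm thick) bulging into the lumen over
planes 4–8.  `generate_damage()` emulates the balloon stage with a
virtual circumferential stretch peaking at the lumen,
$\lambda = 1 + (er - 1)R_0/r$ with log-normal site noise
(sd 0.1), evaluated through the constitutive laws at the ramp peak
(for monotone ramps the history integral collapses to its final
value).  The default expansion ratio 1.8 produces the qualitative
post-intervention picture: damage concentrated in the lumen-adjacent
media, patchy media lacerations, and a contiguous deleted cluster in
the plaque core.  `generate_wss()` applies the surrogate to the
post-deletion contour and attenuates samples lining the lacerations
(×0.25), emulating recirculating flow in dissection pockets; at
physiological femoral flow those samples fall below 1 Pa.

What the generator does *not* emulate: the patient geometry, the true
finite-element stress/damage distribution (the synthetic damage band is
broader and more uniform along the circumference than an FE field, so
month-1 growth is more aggressive than the clinical case), endothelial
recovery, and any axial coupling between planes.  Passing tests
therefore demonstrate the correctness and calibration of the
remodeling machinery under controlled conditions, not agreement with a
specific patient.

# Numerical choices

* **Contour extraction** takes the star-shaped envelope of the lumen
  about its centroid (360 angular bins, maximum boundary-site radius
  per bin, circular interpolation of empty bins) plus half a site
  spacing for the finite site extent; disc round-trips are accurate to
  about 1% for radii 0.5–2 mm.  Deeply non-star-shaped lumens would be
  enveloped, which is acceptable for the shallow recesses produced
  here.
* **Contour smoothing** is a circular moving average of vertex radii
  with an area guard: the smoothed contour is blended back toward the
  input until the area change is at most 2%.
* **Quartiles** use linear interpolation between order statistics
  (`quantile` type 7).
* **Rank-sum test**: exact enumeration of the permutation distribution
  up to pooled size 12 (the 11-plane comparisons), tie-corrected normal
  approximation with continuity correction beyond; the two-sided
  p-value is `min(1, 2 min(P(U<=u), P(U>=u)))`.
* **Determinism**: all stochastic code consumes the R RNG seeded once
  per state; event logs are bit-reproducible under a fixed seed.

# Problem sizes in the test suite

The calibration and dynamics checks run one synthetic plane with the
published cross-section dimensions (lumen radius 1.65 mm, 0.35 mm
layers, eccentric plaque) on a 200 × 200 grid — the vessel with a
modest margin — for 60 simulated days at 2-h steps, three seeds, both
with the default stimuli and with zero stimuli (uniform 10 Pa shear,
zero damage, no mid-run hemodynamic update).  Unit tests use smaller
discs and vessels.  These sizes are the package's validation choice:
large enough that the binomial noise of event counts stays near 1% of
the lumen area, small enough to iterate on.

# Known limitations

* The ABM is strictly per-plane; no tissue moves axially.
* Plaque matrix is inert: lacerations heal only by migration and
  proliferation from the media, consistent with the narrated recovery
  mechanism, and intact plaque neither grows nor resorbs.
* The WSS surrogate is a radius power law, not a flow solution; use
  the CSV interface to couple a real CFD field.
* The damage field is frozen at its post-intervention state; tissue
  created during remodeling carries the damage of the site it occupies
  (zero in former lumen), so the inflammatory drive fades both in time
  and as the wall grows past the injured band.
* Endothelium regrowth, drugs and thrombosis are out of scope.
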