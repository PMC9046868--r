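---
title: "Modeling non-genetic melanoma heterogeneity under targeted therapy"
author: "melanosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling non-genetic melanoma heterogeneity under targeted therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Melanomas treated with BRAF/MEK kinase inhibitors almost always relapse, and
a substantial part of that relapse is *non-genetic*: single-cell mRNA
sequencing of treated tumors shows cells sliding continuously between
transcriptional states — proliferative/melanocytic, invasive, pigmented,
neural-crest-stem-like (NCSC), starved-like (SMC) and a poorly characterized
resistant state (URC) — rather than hopping between discrete clones.
`melanosim` implements a mesoscopic model of this process: one cell density
over two spatial and two cell-state ("structural") coordinates, evolving by
a continuity equation whose fluxes encode motility, chemotaxis/haptotaxis,
deterministic state drift and random state transitions, with proliferation
and state-selective drug kill as sources. The structural plane is an
abstract, dimensionless stand-in for a 2D embedding (t-SNE-like) of the
tumor transcriptome; the six states are configuration, not something the
package computes from sequencing data.

## Model structure and assumptions

The full state is the 4D density $c(t,x,y)$ plus five 2D fields: the
extracellular nutritional environment (ECNE) $v$, nutrient $n$, acid $a$
and two drug concentrations $w_B, w_H$:

$$\partial_t c = -\nabla_x\!\cdot\!F_x - \nabla_y\!\cdot\!F_y + S$$

* $F_x = -D_x\,(1-\rho/\rho_{\max})_+\nabla_x c +
  c\,(\chi_n\nabla_x n + \chi_v\nabla_x v)$. Volume filling acts on the
  diffusive term (the simplest reading of crowding-limited motility); a
  configuration flag (`spatial_fluxes.volume_filling: taxis`) moves it onto
  the taxis term instead. $\rho(t,x)=\int c\,dy$ is recomputed once per
  right-hand-side evaluation, keeping the operator linear within a step.
* $F_y = c\,\Phi(y) - D_y(y)\nabla_y c$ with
  $\Phi(y) = (-k_{adv}(y_1 - a(y_2)),\,0)$ and
  $a(y_2) = (1-y_2)\,y_1^{prolif} + y_2\, y_1^{SMC}$: advection is
  horizontal only and stabilizes an attractor line running from the
  proliferative anchor (south) to the SMC anchor (north); vertical state
  changes happen purely by diffusion. The diffusivity is diagonal:
  $D_h(y_2)$ increases linearly south to north (east–west mixing is easy
  among treatment-induced northern states, rare between proliferative and
  URC in the south) and $D_v(y_1)$ is parabolic, maximal at the west/east
  edges (transitions proliferative↔pigmented and invasive↔NCSC) and minimal
  at the center (the SMC state exchanges slowly with southern states).
  These are the simplest monotone/parabolic forms consistent with the
  qualitative assumptions; the exact published forms are not available.
* $S = P(y)\,g(n)\,(1-\rho/\rho_{\max})_+\,c - \sum_i \delta_i \psi_i(y)
  w_i(t,x)\, c$ with $g(n)=n/(n_{1/2}+n)$ and
  $P(y) = p_{\max} G(y;y_{prolif},\sigma_P)\,
  (1 - s\,G(y; y_{SMC}, \sigma_S))$, $G$ a unit-peak Gaussian bump.
  Treatment is the only source of active cell death. The suppression bump
  around SMC is deliberately wide ($\sigma_S = 0.45$): it encodes that the
  treatment-induced northern states (pigmented, NCSC, SMC) are slowly
  cycling, which is what lets them act as drug-tolerant reservoirs rather
  than growth engines.
* Drug responses: $\psi_B = \mathrm{clip}_{01}[(G(y;y_{prolif},\sigma_B) +
  w_{inv} G(y;y_{inv},\sigma_B)) (1 - d\,G(y;y_{pig},\sigma_{att}))]$ and
  $\psi_H = \mathrm{clip}_{01}[G(y;y_{inv},\sigma_H) +
  G(y;y_{URC},\sigma_H)]$ with $\sigma_H > \sigma_B$. BRAF/MEK inhibition
  kills the naive (proliferative) tumor, reaches into the invasive state and
  spares the pigmented north-west; the hypothetical cancer treatment (HCT)
  kills exactly the states that develop late under kinase inhibition.
* Environment: ECNE is immobile (logistic restoration, acid-driven and
  natural decay); nutrient, acid and drugs diffuse; nutrient is produced by
  the ECNE and consumed by cells; acid is produced by cells and degrades the
  ECNE; drugs are administered uniformly in space while ON, decay naturally
  and are taken up by cells. A small natural nutrient decay `lam_n` is
  included for well-posedness. The "chemo-attractant" the cells follow is
  identified with the nutrient field; no separate sixth field is introduced.

## Geometry

Both domains are unit squares (the embedding plane has no physical units;
only time, in days, is dimensional). The six anchors sit at their compass
positions: proliferative (0.20, 0.20), invasive (0.85, 0.50), pigmented
(0.20, 0.85), NCSC (0.85, 0.85), SMC (0.50, 0.90), URC (0.80, 0.15).
URC is placed *south-east*: the dynamical assumptions (horizontal diffusion
linking proliferative and URC along the south, HCT spanning the east and the
URC flank) are geometrically consistent only with a SE placement, although
the source text prints the same compass label for URC as for the
proliferative state; the atlas is configurable, so the literal reading can
be restored from the configuration alone. Subpopulation subdomains are
closed discs of radius 0.15; overlapping discs are resolved by the nearest
anchor. The discs deliberately do not cover the plane — states between them
are intermediate phenotypes and classify as `unassigned`.

## Numerics

* Cell-centered uniform finite-volume grids (default 24² spatial ×
  24² structural, i.e. 331,776 4D cells). All operators are written in flux
  form with zero-flux boundaries, so transport conserves mass to round-off
  (this is tested to 1e-10 relative over 10⁴ steps).
* Advection is first-order upwind by default; a minmod-limited MUSCL scheme
  is available (`structural_fluxes.advection_scheme: minmod`) and is used by
  the solver-verification instance, where upwind numerical diffusion on a
  deliberately coarse grid would otherwise mask the physical diffusivity.
  Face diffusivities are arithmetic averages of the cell-centered values,
  which keeps the diffusion operator symmetric and conservative.
* Divergence-form (Fickian) diffusion $\nabla\!\cdot\!(D\nabla c)$ is used
  throughout, *not* $\nabla\!\cdot\!\nabla(Dc)$; the particle oracle
  therefore carries the matching Itô drift correction $+\nabla\!\cdot\!D$
  (identically zero for the shipped separable profiles, but computed
  numerically so alternative profiles stay consistent).
* Time stepping is explicit two-stage Heun with a global step chosen as
  `safety / (Σ_axes 2D/h² + Σ_axes |u|_max/h + max linear rate)`. This sum
  form is the actual positivity condition of the combined explicit scheme
  and implies each of the familiar individual bounds h²/(4D), h/|u| and
  1/rate. Negative values produced by a step are clipped to zero and the
  clipped mass is recorded in the trajectory (`clippedMass`), so the
  positivity fix-up is auditable; at the reference resolution it is zero.
  Steps are aligned to integer fractions of a day so daily adaptive
  decisions and snapshot times are exact.
* The initial condition evaluates the Gaussian tumor profile as exact cell
  averages (normal-CDF differences per axis), the correct finite-volume
  representation; this also makes the particle oracle's initial law identical
  to the solver's, so oracle disagreement measures dynamics, not setup.

## The particle oracle

`simulateParticles()` integrates the stochastic counterpart of the same
dynamics — Euler–Maruyama state and space increments with mirrored
boundaries, frozen environment fields (one-way coupling) and optional
multiplicative birth/death weights. `verifyOracle()` runs a canned
transport-only instance on a coarse 8²×8² grid for 5 days and reports the
total-variation distance between the binned particle law (2×10⁵ particles)
and the grid solution; values ≤ 0.05 pass. The instance uses a compact,
slowly diffusing spatial blob and a well-resolved structural blob: the TV
statistic mixes Monte Carlo histogram noise (grows with the number of
occupied bins) with coarse-grid truncation error (grows when profiles are
under-resolved), and this configuration keeps both small without making the
dynamics trivial.

## Reference parameter set and calibration

The published supplementary parameter values are not available, so the
package ships a calibrated reference set (`defaultParams()`,
`defaultConfig()`), fixed once against four qualitative targets: (i) an
untreated doubling time near two weeks; (ii) a three-phase response to
continuous BRAF/MEK inhibition with resistance onset near four months;
(iii) early failure (< 2 months) of continuous HCT; (iv) the combination
ordering — HCT alone fails first, BRAF/MEKi alone next, BRAF→HCT later,
HCT→BRAF last with the lowest final burden.

The calibration logic, in the model's own terms:

* `p_max = 0.15`/day with the initial tumor at half its crowding capacity
  (`peak_density = 0.5`) and nutrient limitation gives a ~14-day doubling.
* `k_adv = 0.01`/day: advection weakly stabilizes the attractor line, strong
  enough to maintain the cellular hierarchy (URC stays rare in untreated
  tumors) but weak enough that the south-eastern escape route toward URC is
  reachable under treatment — with strong advection the URC state is
  unpopulatable and resistance never emerges.
* Structural diffusivities (`d_h` 4e-4..2.5e-3, `d_v` 2e-4..1e-3) set the
  MRD duration: they control how fast the drug-tolerant northern reservoir
  seeds the proliferating escape states, hence the regrowth onset.
* `delta_B = 0.32` per unit drug per day: deep response to BRAF/MEKi whose
  escape (URC/SE, plus a slow pigmented component) regrows at ~2%/day.
* `sigma_H = 0.26`, `delta_H = 1.5`: HCT kills the proliferative bulk only
  ~2-fold above its growth rate and barely reaches the far west of the
  structural plane, so continuous HCT produces a shallow dip and early
  regrowth from west-shifted sensitive cells — the "mild response". The same
  west sanctuary is what revives the tumor when HCT follows BRAF/MEKi
  (drug-holiday re-sensitization), and it caps how long HCT can hold the
  burden below baseline, which fixes the sequential switch times
  (`braf-then-hct` at day 40, `hct-then-braf` at day 30, just before the
  HCT-era burden regains baseline).

This ordering lives in a fairly narrow parameter corridor: the west flank of
the structural plane is an intrinsic sanctuary from any response profile
centered on the east, so the HCT-era recovery rate ties together the
continuous-HCT failure time, the BRAF→HCT comeback and the usable
HCT-first window. That coupling is a real property of this model geometry,
not an artifact of the implementation.

## Metrics

Burden is the 4D quadrature of the density ("tumor volume"); no detection
threshold is imposed — the MRD phase is defined by the slope-based phase
segmentation (moving-average smoothing over `min_duration` = 10 days,
slope threshold 0.002 of the initial burden per day), not a hard cutoff.
Time to resistance is the first post-treatment-start time the burden regains
its value at treatment start, linearly interpolated between samples; runs
that never regain it report `NA` (ordered as beyond-horizon in
comparisons). Heterogeneity is the trace of the structural covariance of
the mass-weighted state distribution (per-axis versus trace being a free
convention; trace chosen). Mode counting smooths the structural marginal
with a 2-cell Gaussian and counts strict 8-neighbor maxima above 5% of the
global maximum. Zoning is quantified by pairwise spatial cosine overlap of
the subpopulation density fields and the zonation index (one minus the mean
off-diagonal overlap over live pairs) — the source material shows pictures
only, and the cosine is symmetric, scale-free and testable.

Two practical notes on zoning in this calibration. First, zoning is
compared across therapies at each run's *beginning of resistance* (the
snapshot nearest the resistance-crossing time): once a tumor has fully
regrown, continuous and adaptive runs converge to the same resistant
attractor state and the spatial contrast washes out. Second, with spatially
uniform dosing and no vasculature the absolute zonation index is small —
the state-by-space coupling comes only from nutrient/crowding gradients and
drug uptake, so the subpopulation fields are nearly proportional — but the
adaptive-versus-continuous contrast is consistent and substantial in
relative terms (drug holidays let sensitive cells regrow where nutrient is
rich, sharpening segregation by severalfold).

## What the tests do and do not show

The test suite verifies the discrete operators against closed forms
(Gaussian heat kernel, characteristic solutions, algebraic equilibria),
conservation and positivity, the solver against the independent particle
oracle, and the scenario-level claims (three phases, onset window, ordering,
heterogeneity upsurge, zoning contrast) at the reference resolution. All of
this is internal consistency plus qualitative agreement with the modeled
biology; none of it validates the model against real tumor data. The
structural plane is an abstraction — distances in it have no biological
units, the six anchors are stylized, and the drug-response and proliferation
profiles are smooth caricatures. Conclusions about actual scheduling of
actual drugs do not follow.

## Problem sizes

The reference runs use 24² × 24² cells over 300 days (~4,500 Heun steps);
the verification instance 8² × 8² over 5 days with 2×10⁵ particles;
operator-level convergence studies use up to 64 structural cells per axis.
These sizes were chosen so the full scenario suite remains convenient to run
interactively on one core.

## Known limitations

* One spatial tumor section; no vasculature — drugs and nutrient sources are
  spatially uniform, so zoning is driven by consumption/shielding gradients
  only.
* Deterministic PDE: no demographic stochasticity, so "time to resistance"
  has no run-to-run variance (small escape masses are real numbers, not
  integer cells; relapse times are therefore systematically optimistic about
  detectability of rare states).
* The explicit integrator makes very stiff parameterizations (large kill or
  decay rates) expensive; the step bound refuses configurations whose stable
  step falls below `run.min_dt`.
* Sequential and adaptive scheduling assume instantaneous, spatially uniform
  dose switching; pharmacokinetics beyond first-order decay/uptake are out
  of scope.
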