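---
title: "Microdosimetric modelling of nanoparticle radiosensitization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microdosimetric modelling of nanoparticle radiosensitization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmicrodose)
```

## The problem

High atomic number nanoparticles (NPs) — gold, gadolinium — sensitize tumour
cells to photon irradiation far beyond what the extra absorbed dose explains.
One candidate mechanism is the Auger cascade: a photoelectric interaction in
the NP releases a fast photoelectron plus a burst of low-energy Auger
electrons that deposit their energy within a few hundred nanometres, in a
dense, spatially correlated cluster. `npmicrodose` quantifies whether that
spatial correlation is biologically potent enough to matter, using the
generalized theory of dual radiation action (TDRA), and offers a
phenomenological alternative — the bomb model — for the cases where it is
not.

## The dual-action model

Lesions (lethal chromosome aberrations) form by pairwise combination of
sublesions, whose yield is proportional to energy deposited in the sensitive
matrix of the nucleus. The geometry of energy deposition enters through the
*proximity function*: `t(x) dx` is the expected energy in a spherical shell
`[x, x + dx)` around a randomly chosen (energy-weighted) transfer point of a
track,

    t(x) dx = sum_i sum_j e_i e_j / sum_i e_i,

with `j` running over transfer points at distance `[x, x + dx)` from point
`i`. The dose-dependent form adds the uncorrelated inter-track term,
`t_D(x) = t(x) + 4 pi x^2 rho D`. The probability that two sublesions a
distance `x` apart combine is modelled as `g(x) = exp(-x / a)`; `a` is a
cell-line property (about 0.1–0.2 um in the lines packaged here).

Under these assumptions the nanoparticle-free lesion yield is
`N(D) = k (xi D + D^2)` with the radiation-quality parameter

    xi = integral( t(x) exp(-x/a) dx ) / (8 pi a^3 rho),

which is exactly the alpha/beta ratio of the linear-quadratic survival
model (`alpha = k xi`, `beta = k`). This gives two independent handles on
`xi`: from survival fits (`xi_from_lq()`) and from track structure
(`xi_from_proximity()`); equating them determines `a` (`solve_a()`).

With NPs, ionization events (at rate `n * mu * lambda` per Gy, i.e.
`n * p1Gy`) add a correlated term and a cross term:

    N(D) = k ( xi' D + D^2 + zeta D^2 ),   xi' = xi + delta_xi,

where `delta_xi` integrates `E * t_NP(x, E) * exp(-x/a)` over the per-event
nucleus energy spectrum `p(E)` (`delta_xi()`), and
`zeta = n * mu * lambda * E_bar / (rho V) = n * p1Gy * z_bar`
(`zeta_der()`). The dose enhancement ratio is `DER = 1 + zeta`, and the
equal-effect RBE at dose `D_NP` has the closed form implemented in
`rbe_tdra()`. Because `alpha = k xi`, the relative increase in alpha equals
`delta_xi / xi` (`dalpha_ratio()`).

Two symbolic constants never materialize numerically: the sublesion yield
coefficient `c` (and hence `k`) and the DNA volume fraction `eta`. Every
quantity the package exports — `xi`, `delta_xi`, `zeta`, DER, RBE,
`delta_alpha / alpha` — is a ratio in which they cancel, which is why
absolute lesion counts are deliberately out of scope.

One printed form of the cross-term prefactor in the source derivations
carries `8 pi` where the combination of the other two equations gives
`4 pi`; the explicit definition `zeta = n mu lambda E_bar / (rho V)` is
self-consistent with the lesion-yield decomposition and is the form
implemented here.

### Normalization of the per-event proximity function

`t_NP` for one ionization event is normalized by the energy `E` deposited
*in the nucleus* (not the whole-event energy): the defining statement of
the per-event spectrum fixes `E` as the in-nucleus total, and
`event_proximity_integral()` uses the same `E` as both the weighting factor
and the pair-sum normalizer, so the two cancel and the event contributes
the plain exponentially weighted pair sum. `delta_xi` scales directly with
this choice, so it is worth stating.

## The bomb model

The TDRA term above captures only the intra-event spatial correlation of
the Auger cascade. Measured sensitization is often far larger, so the
package also implements a deliberately mechanism-agnostic model: each NP
ionization "detonates" and kills the host cell with probability `p1` (NP
outside the nucleus; `p2` inside, with none observed inside in the packaged
data). The expected lethal events per cell scale linearly with dose, so the
entire effect is an increase of the linear LQ coefficient:

    delta_alpha = p1Gy * (N1 p1 + N2 p2).

Inverted against measured `alpha` shifts (`infer_p1()`), this turns
published survival fits into per-ionization kill probabilities. An inferred
`p1` above 1 is physically inadmissible and is flagged rather than
truncated — in the packaged 6 MV fit it signals that single lethal
ionizations cannot carry the observed effect. Survival (`sf_lq()`),
equal-effect RBE (`rbe_lq()`) and concentration-scaling predictions
(`predict_scaling()`, linear in NP count with beta held fixed) complete the
arithmetic layer. When a published fit reports a changed beta with NPs,
that beta is used for the with-NP effect in SF and RBE; the `p1` inference
itself uses only `alpha' - alpha`, as the model prescribes.

## The synthetic track generator

The pipeline normally consumes energy-transfer point lists from a Monte
Carlo track-structure code. To make every stage testable without one,
`cascade_model()` / `simulate_exposure()` generate toy events that
reproduce the *spatial-statistical* features the analysis actually uses:

- one optional fast photoelectron (emission probability 0.8, exponential
  energy, mean 30 keV) plus a Poisson(5) burst of Auger electrons
  (exponential, mean 2 keV) per ionization;
- straight, isotropic tracks with range `R = 0.04 E^1.7` um (E in keV), so
  Auger electrons below ~4.4 keV stay within 0.5 um of the NP while
  photoelectrons cross the cell;
- 10 transfers per electron at path fractions `sqrt(k/m)`, so the transfer
  density rises toward the track end (track-end clustering), with equal
  energy shares making conservation exact;
- Bernoulli self-absorption (default 0.1) standing in for electron loss
  inside the NP.

With the packaged cell geometries these defaults put the mean specific
energy per ionization within a factor of about three of the
`1e-4`–`1e-3` Gy scale expected for these NP/cell combinations (observed,
not asserted by tests: the generator is a stand-in, not a calibrated
transport result). What the toy physics deliberately does **not**
reproduce: realistic energy spectra, angular scattering, condensed-history
stopping, or the published proximity-function curves — so passing tests
demonstrate the correctness of the *estimators and arithmetic*, not
dosimetric fidelity on real track data.

Placement scenarios follow the three standard distribution assumptions:
uniform in the whole cell, uniform in the cytoplasm, and on the nuclear
membrane. "Around the nuclear membrane" is ambiguous in the source
literature; this package places membrane NP centres at
`r_nucleus + np_radius` (touching from outside), consistent with NPs that
accumulate around but never enter the nucleus. Deposits are translated —
never rotated — from the NP frame into the nucleus frame before scoring.

## Numerical choices

- **Distance bins**: logarithmic, `1e-4` to `1e3` um, 10 per decade by
  default (`default_bin_edges()`); pair distances span seven decades. The
  bin representative is the geometric mean of the edges.
- **Out-of-range pairs** are accumulated and reported, never dropped, so
  the per-track mass identity `sum(t dx) + overflow = T - sum(e^2)/T`
  holds exactly (it is tested to 1e-12).
- **`delta_xi` uses exact pairwise sums** per event, not binned curves, so
  the cross-term carries no discretization error; binned curves are for
  inspection and plotting.
- **`solve_a`** brackets on `[1e-3, 10]` um and refines to a residual of
  `1e-6 * xi_target`. For binned curves estimated from sparse toy tracks,
  `xi(a)` can rise and then fall across that wide bracket (there is no
  pair mass below the smallest transfer spacing); when the endpoints do
  not bracket the target, the solver scans the bracket and bisects on the
  decreasing branch beyond the peak — the physical regime, where a larger
  interaction range dilutes the pair integral. An unreachable target
  errors with the achievable range.
- **Units**: keV, um, g/cm^3 and Gy throughout, with a single conversion
  constant (1 keV = 1.602176634e-16 J) owned by one internal file.
- **Printed-input consistency**: `np_exposure()` accepts `p1Gy` alongside
  `lambda` and `mu` if they agree within 0.5% — published constants are
  rounded to three significant digits, so exact equality cannot be
  demanded.
- **Degenerate inputs**: single-transfer tracks carry zero pair mass;
  events with fewer than two nucleus transfers contribute zero to
  `delta_xi`; empty nucleus deposit sets are valid (they are the point
  mass at `E = 0`); a negative measured `delta_alpha` yields `p1 = 0` with
  a warning; negative published alphas are storable but refused by RBE
  operations.

## Reproduction of published tables

`reproduce_tables()` recomputes every table cell that is derivable from
printed inputs (kill probabilities, survival fractions, RBE, DER and
relative alpha increases) and compares at half a unit in the last printed
digit. Cells that miss only because their *inputs* are printed rounded
(for example a DER computed from a two-digit mean specific energy) are
reported `flagged` rather than failed; quantities that require the
unavailable Monte Carlo track data (the published `delta_xi` and
distance-model `a` values, and the Table-2 RBE column, which is not
recoverable from its own printed inputs) are `skipped` with the reason.
For ranged quantities the printed value is compared against the interval
spanned by the two experimental-`xi` limit pairings. Hypothetical
concentration rows are recomputed by scaling the base-row `delta_xi`
linearly in NP count, which is exact under the model.

## Problem sizes

The test-suite and example simulations use `1e4` events for
scenario-ordering and pipeline checks, 2000–4000 point clouds for the
estimator properties, and 40–80 toy tracks per energy for reference
curves. These sizes give Monte-Carlo standard errors comfortably below the
asserted tolerances while keeping a full run in tens of seconds; all
stochastic tests fix their seeds.

## Known limitations

- Transport constants (`lambda`, `mu`), the published `delta_xi` and
  distance-model `a` values are consumed as constants; reproducing them
  requires a photon/electron transport code.
- The toy generator cannot reproduce published proximity-function or
  nucleus-spectrum curves quantitatively, only their qualitative features.
- The published A549 low-concentration `p1` range and the Table-2 RBE
  column are not derivable from printed inputs by any scheme we could
  validate, and are skipped, not approximated.
- Uncertainty propagation in `infer_p1()` is first-order quadrature of
  independent uncertainties; the original analysis did not state its
  scheme.

## A short worked example

```{r example, eval = FALSE}
row <- bomb_experiments("Hela_AuNP_220kVp")
p1Gy <- ionization_params("AuNP", "220kVp")$p1Gy
fit <- infer_p1(row$alpha_np - row$alpha, p1Gy, row$n_per_cell)
fit$p1                     # ~1.73e-3 kill probability per ionization

b <- bomb_params(p1Gy, row$n_per_cell, p1 = fit$p1)
predict_scaling(b, lq_params(row$alpha, row$beta), factor = 2,
                dose_np_Gy = 2)   # RBE ~2.02 at doubled uptake

cfg <- analysis_config(scenario = "nuclear_membrane", n_events = 1e4,
                       seed = 1)
res <- run_pipeline(cfg)
res$der; res$delta_xi; res$rbe
```
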