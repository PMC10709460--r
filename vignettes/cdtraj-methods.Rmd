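---
title: "Methods: conformational and thermodynamic analysis of cyclodextrin host-guest trajectories"
author: "cdtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational and thermodynamic analysis of cyclodextrin host-guest trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdtraj)
```

# Scope and data model

`cdtraj` analyses coordinate trajectories of a macrocyclic host (a
cyclodextrin: a ring of glucose units whose three oxygen tiers — the primary
hydroxyl rim O6, the glycosidic middle rim O1, and the secondary hydroxyl
rim O3 — define a truncated-cone cavity) optionally containing an elongated
guest such as cholesterol and a water bath. It does not run molecular
dynamics: it consumes trajectories (multi-model PDB or concatenated GRO) plus
a topology annotation that names the three ordered rim rings, the guest
atoms and its hydroxyl oxygen, water oxygens, and donor/hydrogen/acceptor
lists. All coordinates are held in nm (PDB Angstrom are converted on read),
times in ps, energies in kJ/mol.

Rim rings must be supplied already ordered around the macrocycle. Ring order
is required for polygon areas and cannot be inferred reliably from distorted
frames, so the package never guesses it. Boxes are orthorhombic and all
distances use per-axis minimum-image wrapping; the solvated cubic boxes this
kind of study uses need nothing more general.

Summary statistics are computed over a *tail window*: the contiguous final
`ceiling(fraction * N)` frames (default fraction 0.10, matching the
convention of averaging over the last 10% of a production run). Frame counts
rather than time stamps are used so the window is deterministic even when
the start time is unknown.

# Rim geometry

For each rim the package reports:

* **Area**: the ring points are projected onto their least-squares plane
  (SVD of the centred coordinates) and the area of the projected polygon is
  computed with the shoelace formula. A self-intersecting projection —
  possible only for a badly distorted rim — still returns the shoelace value
  but warns.
* **Circularity** $\Omega$: the ratio of the smallest to the largest
  characteristic chord. The default *cross-ring* convention compares, for
  each atom, its maximal-separation partners across the ring (chords
  $i \to i+\lfloor n/2 \rfloor$ and $i \to i+\lceil n/2 \rceil$), so a
  regular $n$-gon scores exactly 1. The *literal* all-pairs reading is
  available as an option, but it bounds a regular heptagon at
  $\sin(\pi/7)/\sin(3\pi/7) \approx 0.445$, which is incompatible with
  near-unity circularities commonly reported for 7-rings; this is why
  cross-ring is the default.
* **Heights**: $h_{12}$ and $h_{16}$ are the distances between the centres
  of mass of the O1 ring and the SHR / PHR rings respectively (mass-weighted
  when masses are annotated, uniform otherwise), and $h = h_{12} + h_{16}$
  holds exactly when the three rim centroids are collinear.
* **Cavity volume** $V_C$: modelled as two conical frustums sharing the
  middle rim,
  $$V_C = \frac{h_{16}}{3}\left(A_{PHR} + A_{MID} + \sqrt{A_{PHR}A_{MID}}\right)
        + \frac{h_{12}}{3}\left(A_{SHR} + A_{MID} + \sqrt{A_{SHR}A_{MID}}\right).$$
  The frustum model uses exactly the quantities the rim analysis already
  produces, degenerates to a cylinder ($2Ah$) for equal areas and to a cone
  ($Ah/3$) when an outer rim closes, and is monotone in every input. A
  convex-hull volume of the three rims can be computed externally as a
  sanity bracket; the frustum model is the declared estimator, and absolute
  cavity volumes from other geometric definitions are not comparable beyond
  their common scale.

The cavity *axis* is the unit vector from the SHR centroid to the PHR
centroid and the cavity *centre* is the midpoint of that segment — a
deterministic, frame-local definition.

# Guest binding state and orientation

A frame is classified `inserted` when the guest centre of geometry lies
within `d_insert` (default 0.35 nm) of the cavity centre *and* the guest
long axis (principal eigenvector of its uniform-weight gyration tensor) is
within 45 degrees of the cavity axis; `surface` when the centre is within
`d_surface` (default 0.80 nm) without meeting the insertion criterion;
`unbound` otherwise. No community-standard numeric criterion exists for
"fully penetrated", so all three thresholds are configurable; the defaults
place the insertion sphere well inside the cavity (half the typical cavity
height) and the surface shell just beyond the rim oxygens. Orientation for
bound frames is the sign of the guest hydroxyl-oxygen position, relative to
the guest centre, projected on the PHR-pointing axis.

Centres of geometry (uniform weights) are used for the binding distance;
centres of mass are used for rim heights, which are defined through mass
centroids.

# Shape descriptors

The gyration tensor of an atom group is
$S_{ab} = \sum_i w_i (r_i - \bar r)_a (r_i - \bar r)_b / \sum_i w_i$ with
mass weights by default (uniform selectable; results for the all-oxygen
synthetic host are identical either way). Its descending eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ give

$$R_g^2 = \lambda_1 + \lambda_2 + \lambda_3, \qquad
\kappa^2 = 1 - 3\,\frac{\lambda_1\lambda_2 + \lambda_2\lambda_3 + \lambda_1\lambda_3}
                      {(\lambda_1+\lambda_2+\lambda_3)^2}, \qquad
b = \lambda_1 - \tfrac12(\lambda_2 + \lambda_3).$$

$\kappa^2$ is 0 for a fully symmetric mass distribution and 1 for an ideal
linear chain; $b$ (nm$^2$) is 0 for a sphere. A zero tensor (single point)
maps to $\kappa^2 = 0$ by continuity of the symmetric limit. $\kappa^2$ is
clamped to $[0,1]$ only against round-off excursions below $10^{-10}$;
anything larger is a genuine input error and surfaces as one. Probability
densities of descriptor series default to 50-bin normalized histograms
(Gaussian KDE selectable) because reported structure for these descriptors
typically lives between 0.1 and 0.3.

# Cavity hydration

Water positions are represented by their oxygens (the standard convention).
Shell occupancies count water oxygens in half-open, lower-inclusive radial
bins around the cavity centre, with default edges 0, 0.5, 0.8, 0.9, 1.0 nm;
the total over the full range is the exact sum of the shells on every
frame. The radial distribution function uses a single reference point per
frame (the cavity centre), $g(r) = \langle n(r)\rangle /
(\rho_{bulk} 4\pi r^2 \Delta r)$ with $\rho_{bulk}$ the box-average water
density, and refuses $r_{max}$ beyond half the smallest box edge.

Standard errors of all windowed means use block averaging with 5 contiguous
blocks — an estimator that remains honest for autocorrelated series, which
per-frame MD observables always are.

# Hydrogen bonds

The geometric criterion is the conventional one: donor–acceptor distance
$\le$ 0.35 nm and H–D–A angle $\le$ 30 degrees, both configurable. Bonds
are labelled by the group pair of donor and acceptor (water–CD,
water–guest, CD–guest, CD–CD, water–water); with a single host molecule per
box, "CD–CD" means bonds internal to the macrocycle. Lifetimes come in two
definitions: *continuous* (default) — the mean length of uninterrupted
on-episodes times the frame spacing, appropriate for episode-scale
lifetimes of tens of ps — and *intermittent* — the integral of the
normalized existence autocorrelation up to its first decay below $1/e$.
Episodes touching the trajectory boundary are counted but flagged as
censored; a bond never present has an undefined (NA) lifetime, never 0.

# Free-energy estimators

**Thermodynamic integration.** $\Delta G = \int_0^1 \langle \partial
H/\partial\lambda\rangle\, d\lambda$ by trapezoidal quadrature of per-window
sample means over the (possibly non-uniform) $\lambda$ grid; the trapezoid
is exact for integrands affine in $\lambda$ and reaches 0.1% accuracy for
smooth integrands on a 25-point schedule. Simpson's rule is intentionally
not the default: $\lambda$ schedules are usually non-uniform.

**Bennett acceptance ratio.** $\Delta G$ solves
$$\sum_F f\!\big(\beta(W_F - \Delta G + M)\big) =
  \sum_R f\!\big(\beta(W_R + \Delta G - M)\big), \qquad
  M = kT \ln(n_F/n_R),$$
with $f$ the logistic function, by safeguarded Newton iteration on the
strictly monotone residual (bisection fallback, relative step tolerance
$10^{-12}$). The residual has opposite infinite-sample limits, so a unique
root always exists; failure to converge numerically is reported as poor
forward/reverse overlap. Exchanging the forward and reverse sample sets
negates the estimate — the antisymmetry that holds for work samples in the
Crooks convention used throughout (forward work for decoupling, reverse
work for recoupling). Per-adjacent-pair estimates over a $\lambda$ ladder
sum exactly to the total.

**Uncertainty.** All estimator standard errors are seeded bootstraps with
200 resamples — estimator-agnostic and reproducible. An optional per-window
discard fraction handles unequilibrated initial samples.

**Thermodynamic cycle.** The binding free energy composes the two
decoupling legs of the double-decoupling cycle as
$\Delta G_{bind} = \Delta G_{decouple,water} - \Delta G_{decouple,complex}$,
so binding that makes decoupling harder from the complex is favourable
(negative). The convention is recorded in the result's metadata because
cycle sign conventions vary across the literature. No restraint corrections
are applied or implied.

**Dipole moment.** $|\sum_i q_i r_i|$ converted at 1 e nm = 48.0321 D. For
net-charged groups, whose dipole is origin-dependent, the origin is the
absolute-charge-weighted centre; this choice is documented in the function
and only affects charged selections.

# Free-energy landscapes

The 2-D landscape over (RMSD, $R_g$) is the Boltzmann inversion
$F = -kT\ln(P/P_{max})$ of a 60x60 histogram over the observed range padded
by 5%, so the global minimum is exactly 0 and empty bins are masked (NA),
never assigned a finite value. RMSD uses Kabsch superposition: weighted
centroid removal and the optimal proper rotation from the SVD of the
covariance with determinant $+1$ enforced, checked in the test suite
against an independent quaternion-method implementation. The reference
structure is user-supplied (an energy-minimized frame is the natural
choice); frame 1 is the default.

Basins and barriers come from a watershed sweep over the occupied bins in
ascending $F$ with 4-connectivity: a bin with no lower processed neighbour
seeds a basin, and the level at which two basins first join is their
barrier (the minimax path level on the discrete grid). Finite-sample
histograms carry shallow noise dips and disconnected fringe islands, so two
filters are provided: `depth_threshold` reports only minima below a level,
and `min_prominence` absorbs basins whose prominence (merge level minus
minimum) is below a threshold. For well-sampled landscapes at 310 K a
prominence floor of order 1 kJ/mol (well below the thermal energy
kT = 2.577 kJ/mol times ln of any meaningful population ratio) removes
noise without touching physical basins. No kernel smoothing or reweighting
is applied by default.

# The synthetic generator and what it does (not) emulate

Because trajectories of this kind are rarely deposited, every analysis
stage is validated against synthetic systems with known ground truth:

* `make_cd_ring()` builds three stacked oxygen rims. The default radii and
  offsets realize rim areas of 1.10 / 0.83 / 1.32 nm$^2$ and heights
  $h_{16}$ = 0.33 nm, $h_{12}$ = 0.22 nm — the parent beta-cyclodextrin
  scale; `ring_spec_methylated()` realizes the smaller methylated-derivative
  scale (1.05 / 0.70 / 1.08 nm$^2$, heights 0.22 / 0.12 nm). Ellipticity
  factors distort individual rims; Gaussian jitter (default fixture value
  0.01 nm) emulates thermal disorder.
* `make_binding_trajectory()` moves a rigid 8-bead rod (~1.7 nm, one end
  tagged as the hydroxyl oxygen) along a scripted path: `direct_insert`
  (axial approach from 1.5 nm off the secondary rim — the conventional
  starting separation), `surface_then_insert` (a horizontal dwell lying
  across the secondary rim, then a 10-frame upright rotation — the
  two-stage pathway reported for the methylated host, scaled down), or
  `never_bind`. The ground-truth ledger records the noise-free per-frame
  state, orientation and insertion frame; classifiers are tested against
  this ledger, never against re-derived quantities.
* `make_water_bath()` places exact per-shell counts using inverse-CDF
  radial sampling ($r^3$ uniform), so uniform density within each shell is
  exact, not approximate.
* `make_bar_samples()` draws forward work from
  $N(\Delta G + \sigma^2/2kT,\ \sigma^2)$ and reverse work from
  $N(-\Delta G + \sigma^2/2kT,\ \sigma^2)$ — the unique Gaussian pair
  satisfying the Crooks fluctuation relation in distribution, so a
  consistent estimator must recover the planted $\Delta G$.
* `make_hbond_episodes()` plants non-overlapping on-episodes with a ledger.

All generators are bitwise reproducible from their seeds and restore the
caller's RNG stream.

What the synthetic systems deliberately lack: force-field energetics, water
 -water structure, guest flexibility, and hydrogen-atom detail beyond what
bond detection needs. Tests passing on them therefore demonstrate that the
*estimators* are correct (geometry closed forms, planted-parameter
recovery, oracle equivalence), not that any particular physical system
behaves a certain way. Directional patterns asserted on fixtures (a smaller
ring spec shrinks $V_C$; inserting the guest empties the innermost shell;
elongation drives $\kappa^2$ toward 1) check that the descriptors move the
way the underlying geometry dictates.

# Problem sizes and numerical choices

The validation suite uses 150-200-frame trajectories (dt = 10 ps), baths of
order $10^3$-$10^4$ points, $10^4$ work samples per direction with 100-200
bootstrap resamples, and $10^5$ collective-variable draws for landscapes —
sizes chosen so every stochastic recovery test has comfortable statistical
margins while the whole suite runs in minutes on a laptop. Tie-breaking and
degenerate-input conventions: half-open lower-inclusive radial bins;
eigenvalues sorted descending with round-off clamping at $10^{-12}$ of the
leading magnitude; collinear point sets are an error for plane fits and
superposition but a valid ($\kappa^2 = 1$) input for shape descriptors;
empty trajectories, zero-width shells with nonzero counts, and overlapping
planted episodes are errors, not silent repairs.

# Known limitations

* The cavity volume is a geometric model; it is faithful to the rim
  quantities but not comparable in absolute terms to probe-based or
  grid-based cavity detection.
* The intermittent lifetime estimator truncates at the first $1/e$
  crossing rather than fitting a decay model; for strongly intermittent
  bonds it underestimates long-time contributions.
* RMSD after superposition is not a metric; no triangle-type inequality is
  asserted or used.
* The pipeline aggregates externally supplied energy series but never
  evaluates force-field energies, soft-core potentials, or enhanced-sampling
  reweighting.
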