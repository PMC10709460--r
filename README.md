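# cdtraj

Trajectory analysis for cyclodextrin host–guest inclusion complexes.

Cyclodextrins — cyclic glucose oligomers whose three oxygen tiers (primary
hydroxyl rim O6, glycosidic middle rim O1, secondary hydroxyl rim O3) form a
hydrophobic truncated-cone cavity — are workhorse drug carriers, and
molecular-dynamics studies of how a guest such as cholesterol enters and
reshapes them all need the same analyses: macrocycle conformation, guest
binding kinetics and orientation, cavity hydration, hydrogen bonding,
alchemical free energies, and conformational free-energy landscapes.
`cdtraj` packages those analyses for computational chemists who have
trajectories (or want to validate analysis code without any), with a
synthetic-system generator that plants known ground truth for every stage.

## What it computes

**Rim geometry** (per frame, summarized over a tail window): rim areas by
least-squares-plane projection + shoelace formula; circularity
Ω = min/max characteristic chord (cross-ring convention by default, so a
regular n-gon scores 1); inter-rim heights h₁₂, h₁₆ from mass centroids; and
a two-frustum cavity volume

    V_C = h₁₆/3 · (A_PHR + A_MID + √(A_PHR·A_MID))
        + h₁₂/3 · (A_SHR + A_MID + √(A_SHR·A_MID)).

**Binding classification**: per-frame state (unbound / surface / inserted)
from the guest COG distance to the cavity centre and the alignment of the
guest long axis with the cavity axis; orientation from the axial projection
of the guest hydroxyl oxygen.

**Shape descriptors**: gyration-tensor eigenvalues λ₁ ≥ λ₂ ≥ λ₃ with
Rg² = λ₁+λ₂+λ₃, relative shape anisotropy
κ² = 1 − 3(λ₁λ₂+λ₂λ₃+λ₁λ₃)/(λ₁+λ₂+λ₃)² and asphericity
b = λ₁ − (λ₂+λ₃)/2, plus probability densities.

**Hydration**: shell-wise water-oxygen counts around the cavity centre
(default shells 0–0.5, 0.5–0.8, 0.8–0.9, 0.9–1.0 nm) and the radial
distribution function g(r).

**Hydrogen bonds**: geometric criterion (r(D,A) ≤ 0.35 nm, H–D–A ≤ 30°),
counts per group pair (water–CD, water–guest, CD–guest, CD–CD), and
continuous or intermittent lifetimes.

**Free energies**: thermodynamic integration (trapezoid over the λ grid of
⟨∂H/∂λ⟩), the Bennett acceptance ratio estimator with bootstrap errors, and
the double-decoupling cycle ΔG_bind = ΔG_dec,water − ΔG_dec,complex.

**Landscapes**: Kabsch-superposition RMSD, 2-D free-energy surfaces
F = −kT ln(P/P_max) over (RMSD, Rg), and watershed basin/barrier detection.

## Worked example

A synthetic parent-cyclodextrin-scale host with thermal jitter and a
scripted guest insertion at frame 50 (200 frames, dt = 10 ps):

```r
library(cdtraj)

spec <- ring_spec(jitter_sd = 0.01, seed = 1)              # 7-unit macrocycle
script <- binding_script("direct_insert", "O_toward_PHR",
                         insertion_frame = 50, seed = 2)
sys <- make_binding_trajectory(spec, script, n_frames = 200)

win <- tail_window(sys$trajectory, 0.10)                    # last 10%
geo <- rim_geometry(sys$trajectory, sys$topology, window = win)
geo$summary
#>    descriptor  mean       se
#> 1       A_PHR 1.097 0.003031
#> 2       A_MID 0.834 0.003237
#> 3       A_SHR 1.319 0.003098
#> 4   omega_MID 0.949 0.002694
#> ...
#> 8         h16 0.326 0.001376
#> 10        V_C 0.551 0.000996
```

The rim areas (1.10 / 0.83 / 1.32 nm²), heights (0.22 / 0.33 nm) and the
resulting cavity volume (0.55 nm³) recover the geometry the ring spec
planted. Binding classification finds the scripted event:

```r
cls <- classify_binding(sys$trajectory, sys$topology)
which(cls$state == "inserted")[1]
#> [1] 39        # the scripted path first satisfies the criterion at frame 39
table(cls$state)
#> inserted  surface  unbound
#>      162       15       23
```

Shape descriptors of the host over the same window give κ² = 0.109 ± 0.002
— the near-spherical regime — and a BAR estimate on Crooks-consistent work
samples planted at −77.49 kJ/mol recovers it within one standard error:

```r
s <- make_bar_samples(-77.49, sigma_w = 5, kT = 2.577, n_forward = 1e4, seed = 3)
bar_estimate(s, kT = 2.577, seed = 4)
#> BAR free energy: -77.4550 +/- 0.0401 kJ/mol
```

`run_all(validate_config("config.yml"))` drives every stage over one
trajectory and writes per-frame and summary TSV tables plus a JSON run
report with file checksums.

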