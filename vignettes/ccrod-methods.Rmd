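---
title: "Models and methods behind ccrod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccrod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrod)
```

`ccrod` analyses how two Laing distal myopathy mutations in the
β-cardiac myosin rod — the proline substitution A1603P and the
single-residue deletion K1617del — perturb the coiled coil, the
filaments it assembles into, and its packing into sarcomeres. This
vignette records the models, the tunable parameters, the synthetic-data
design, and the places where a genuine design choice had to be made.

## The coiled-coil generator

A two-chain coiled coil is generated from a generalized Crick
parameterization. Each chain's Cα atoms lie on a minor helix of radius
2.26 Å that winds about a supercoil axis of radius 4.9 Å. Three rates
govern the geometry, all in degrees per residue:

* the intrinsic helix rate `ω_α = 360 / residues_per_turn`
  (`residues_per_turn = 3.617` by default);
* the in-frame helix phase rate of the active motif, `ω_1 = 360·N/L`
  for a motif of `L` residues carrying `N` helical turns;
* the supercoil twist `ω_0 = ω_α − ω_1`, i.e. whatever the motif's
  phase rate cannot supply is absorbed by winding the whole helix
  about the supercoil axis.

For the canonical 7-residue, 2-turn motif this gives
`ω_0 = −3.327 °/residue`: the familiar left-handed supercoil. A skip
residue is accommodated by replacing four heptads with one 29-residue
motif still carrying 8 turns, which drives `ω_0` to almost zero — the
local unwinding expected at myosin's skip residues. A deletion is the
mirror case: a 27-residue, 8-turn motif over-winds its span
(`ω_0 ≈ −7.1 °/residue`). The axial rise is fixed at 1.495 Å per residue
along the supercoil axis. Between motifs the phase rate is blended with
a logistic ramp of width `smoothing_b × motif length` (default
`b = 0.03`, which makes transitions essentially one residue wide); the
parameter exists so that stiffer or softer transitions can be explored,
but results at desk scale are insensitive to it below ~0.1.

Backbone N, C and O atoms are placed from the cylindrical offsets of an
ideal α-helix built from internal coordinates (φ = −57.8°, ψ = −47.0°),
so the generated backbones score 100% helical under the dihedral
windows below. No side chains are built; analyses that need them
(solvent accessibility of real side chains, salt bridges) accept
externally packed all-atom ensembles.

**Strand placement.** The builder's 210° parameter is interpreted as the
helix self-rotation phase, applied identically to both chains, with
chain B generated by an exact 180° rotation of the supercoil phase.
The alternative reading — 210° as the azimuthal angle between the two
helix axes — would break the C2 symmetry that parallel two-stranded
coiled coils exhibit, so it was rejected; with the chosen convention
equal sequences give a dimer that superposes onto itself under a 180°
rotation to machine precision.

**Numbering.** All per-residue outputs use wild-type numbering.
A deletion removes the residue but never renumbers: K1617del models
carry an explicit gap at 1617, and windowed metrics use physical
(sequential) neighbours while flagging windows that span the gap.

## Register and schedules

Heptad letters propagate cyclically from anchors (E1604 = "d" for the
rod segment studied here). A skip residue pauses the propagation for
one step: the skip is labelled `skip` and the register downstream is
offset by one position — which is precisely why four heptads plus the
skip make a 29-residue motif. In skip-del mode the schedule walker
emits the non-canonical motif once at least one full heptad flanks the
skip or deletion on each side; a skip and a deletion closer than one
motif span cannot be scheduled and raise an error. The
canonical-throughout mode emits only 7-residue motifs, which is how the
quasi-canonical deletion model (K1617del-c) is built: the register
shifts of the skip (+1) and the deletion (−1) cancel.

## Ensemble metrics

* **D_com** — distance between the centroids of seven consecutive Cα
  atoms of each chain, per residue; ≈ 2 × major radius for an ideal
  model, undefined at the three terminal residues.
* **Heptad length** — distance between the 7-residue windowed mean Cα
  positions centred at i and i+7 (≈ 10.5 Å for a straight helix with a
  1.5 Å rise). The statement of the windowed average is ambiguous
  between averaging positions and averaging distances; both are
  implemented and agree to three decimals on ideal geometry, with the
  windowed-positions form the default.
* **Inter-heptad angle** — the interior angle at residue i between the
  directions to residues i−7 and i+7; 180° when straight, and reported
  as the interior angle (not its deviation) because bends *decrease*
  it, matching how the mutants are described.
* **Helicity** — fraction of (residue, frame) pairs with φ ∈ [−100°,
  −30°] and ψ ∈ [−80°, −5°]. The exact windows of the original
  dihedral-based method are not recorded, so these are package
  defaults and are configurable.
* **RSA** — Shrake–Rupley accessible surface (probe 1.4 Å, 960 golden-
  spiral test points, Chothia-style element radii) of each residue's
  side-chain atom set, with Cα counted as side chain. The reference
  maximum is conformer-specific: the residue's own atoms are rigidly
  transplanted (superposed on N/CA/C) into an extended Gly-X-Gly
  backbone built from internal coordinates and re-scored with the same
  engine. This makes "RSA of X in extended Gly-X-Gly = 1" an identity
  rather than a table lookup, at the cost that distorted conformers can
  exceed 1 slightly. Frames are subsampled (default: one frame per
  10 ps of trajectory time when time stamps allow).
* **Salt bridges** — charge centres are Lys NZ, Arg NH1/NH2 midpoint,
  Asp OD1/OD2 midpoint, Glu OE1/OE2 midpoint; a pair is bridged below
  4 Å, and occupancy is its bridged-frame fraction. The Arg centre uses
  the NH midpoint rather than CZ as the closer locus of formal charge.
* **RMSD/RMSF/clustering** — Kabsch superposition (mass-unweighted);
  RMSF about an iteratively re-superposed mean structure (tolerance
  1e−4 Å; strongly bent ensembles converge geometrically and may need
  several hundred iterations, so the pipeline raises the iteration cap);
  clustering is the deterministic leader algorithm at an 8 Å Cα RMSD
  cutoff — the cutoff is the method's stated parameter, the algorithm
  choice is ours, and the implementation is structured so a gromos-style
  average-linkage variant can be swapped in.

## CD quantification

MRE = raw(mdeg) × MRW / (10 × path(cm) × conc(g/L)). Percent helix is
100 × |MRE₂₂₂|/36,000, treating the reference as a magnitude and
clipping at 120% with a warning above 100%; no chain-length correction
is applied since none is recorded for the reference value. The 222/208
ratio reads each wavelength at the nearest sample and interpolates when
the grid is off by more than half a step. Melts are normalized to 100%
folded at 10 °C and 0% at 80 °C, then fitted with a two-state logistic
`100 / (1 + exp((T − Tm)/w))` — "sigmoidal" is all the data demand, and
post-normalization baselines are flat by construction, so slopes are
fixed at zero.

## Sarcomere line scans

For a motor-domain-tagged myosin the intensity along a myofibril drops
twice per sarcomere: at the sarcomere boundary (I-band/Z-disc, where
myosin is absent) and in the central bare zone at the M-line. The
boundary minima are the darker of the two, so segmentation takes the
deepest local minima at approximately periodic spacing (period from the
autocorrelation peak; boundary detection runs on a quarter-period
smoothed copy so flat noisy stretches give a unique minimum) as window
boundaries, and the alignment (M-line) minimum is the deepest point
between the window's two principal intensity peaks. A configuration
flag instead treats the deepest minima themselves as M-lines, for
stains whose dominant minimum is central. Averaging is two-level —
sarcomeres within a myofibril first, then across myofibrils — matching
a design in which the myofibril is the experimental unit; a pooled mode
exists but is never the default. Peaks are the largest local maxima on
each side of the aligned minimum, refined to sub-sample precision by a
least-squares parabola over ±3 samples; no pre-smoothing is applied,
noise being handled by the averaging.

## Synthetic data: what it emulates, and what it does not

Each generator reproduces the statistical structure its analysis
assumes, with presets pinned to the study's printed summary statistics:

* **Ensembles** (`gen_ensemble`): rigid rotation of the rod's distal
  half about a random transverse axis at the hinge (default residue
  1603), plus isotropic Gaussian jitter (0.15 Å). In end-to-end-target
  mode the bend angle is solved by bisection so each frame matches a
  draw from Normal(μ, σ) — WT 23.9 ± 0.5 nm, K1617del 23.4 ± 0.5 nm,
  K1617del-c 23.7 ± 0.4 nm. A bend can only shorten the rod, so draws
  above the straight length (24.36 nm for the 164-residue model) are
  clamped; the draw distribution is recentred analytically so the
  *delivered* ensemble mean equals the requested one.
* **CD** (`gen_cd`): Gaussian-composite helix and coil bases — not
  measured basis sets — with the helix basis scaled to exactly −36,000
  at 222 nm and a 222/208 ratio above 1, and the coil minimum near
  198 nm. Scenario helix fractions (WT 0.95, K1617del 0.75, A1603P
  0.55) encode the reported qualitative ordering, not measured values.
* **Melts** (`gen_melt`): the two-state logistic at 1 °C steps,
  10–85 °C; scenario midpoints 48/50/50 °C.
* **Filaments** (`gen_filaments`): lengths and widths from
  Normal(μ, SEM·√n) truncated above zero and recentred so the truncated
  mean equals μ — WT 431 ± 34 nm (n = 34) and 18.4 ± 0.4 nm (n = 72),
  A1603P 208 ± 16 nm (n = 24) and 25 ± 1 nm (n = 31); bundling flags
  Bernoulli per image field (K1617del 0.70, WT 0.19). The 50:50
  mixtures draw from a single intermediate population (printed means
  390/22 nm) rather than a bimodal mix, matching the reported
  intermediate phenotype. K1617del's own length/width presets are
  plausible interpolations (shorter and wider than WT), as no numbers
  are printed for them.
* **Line scans** (`gen_linescans`): per sarcomere (period 2.0 μm), two
  Gaussian peaks of width 0.15–0.2 μm flanking the M-line at
  ±separation/2 plus a central M-line accumulation term, on a constant
  baseline, sampled at 0.02 μm. The default separation of 0.7 μm
  matches the scale at which the two fluorescent stripes are resolved;
  the bare-zone width itself (~0.16 μm) is the natural separation when
  peak widths are set near the optical limit, and the parameter
  recovery tests exercise both regimes. Mutant presets raise the
  M-line amplitude (A1603P 0.3, K1617del 0.35 vs WT 0.1) and lower
  K1617del's peak amplitude to 0.7, reproducing the reported orderings
  by construction.
* **Solubility** (`gen_solubility`): a rising logistic in NaCl with
  half-solubility at 250 mM for WT and K1617del and 150 mM for A1603P,
  expressing that the proline mutant stays soluble at lower salt.

What passing these closed loops shows is that each analysis recovers
the parameters of data generated under its own assumptions at realistic
noise; it does not show that the analyses are robust to everything real
data contain — anisotropic thermal motion, correlated backbone
fluctuations, instrument baselines, uneven staining, or photobleaching
are all outside the generators.

## Problem sizes and numerical choices

The test suite and drivers run 164-residue dimers, ensembles of 40–200
frames, populations of 24–72 filaments, 200 image fields and 12
myofibrils per construct — sizes chosen so the full chain re-runs in
minutes while keeping every estimator in its working regime
(e.g. 2 × SEM population checks, binomial intervals at n = 200).
Key tolerances: melt fits converge from a 50%-crossing start with
bounded parameters; the mean-structure superposition stops at 1e−4 Å;
cluster membership uses strict `<` against the cutoff; the 222/208
reader treats a |MRE₂₀₈| below 1e−9 as undefined; peak/min ratios with
a near-zero minimum are reported capped with a flag rather than as
infinities. Degenerate inputs (flat line scans, melts with equal
anchors, all-frame equilibration cuts, schedules that do not tile) all
raise informative errors rather than propagating NaN.

## Known limitations

The builder produces backbone-only idealized models: no side-chain
packing, no energetics, and the per-residue metrics on synthetic
ensembles inherit the rigid-hinge simplification — real trajectories
bend everywhere, not at one residue. The salt-bridge and RSA analyses
are only as good as the all-atom input they are given. The sequence
shipped with the package is a synthetic stand-in that fixes every
residue identity the analyses depend on and fills the remainder with a
register-consistent pattern; analyses that depend on the full true
sequence (e.g. charge-block periodicity along the whole rod) should
supply their own.
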