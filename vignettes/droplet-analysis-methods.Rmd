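---
title: "Methods: analysis of coarse-grained lipid droplet trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysis of coarse-grained lipid droplet trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletmetrics)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic-data validation does
and does not establish.

## The system and the data model

The object of study is a spheroidal lipoprotein-like particle: a compact
droplet of neutral lipids (cholesteryl ester, CE; triglyceride, TG)
surrounded by a polar shell (POPC, lyso-type PPC, free cholesterol CHOL),
optionally belted by apolipoprotein chains. A coarse-grained trajectory of
such a particle is represented as a topology (a tibble, one row per bead:
molecule id, species, bead name, moiety; residue annotations and a
hydrophobicity class for protein beads) plus an `n_frames x n_beads x 3`
coordinate array with strictly increasing frame times.

Internal units are nm and ns everywhere; readers convert on ingest (PDB
Å are divided by 10). Bead ids are dense `1..N` in file order. Times can
be multiplied by 4 on reading — the conventional mapping from
coarse-grained simulation time to effective (real) time — and the
trajectory records whether that scaling has been applied. Species and
moiety assignment is driven by an editable mapping table
(`default_bead_map()`, also shipped as `inst/extdata/bead_map.tsv`), never
hard-coded in the parsers, because CG bead naming varies across
topologies.

Coordinates are assumed to describe whole (unwrapped) molecules: the
particle is compact and far from box walls, so periodic imaging is not
re-done. A guard (`check_unwrapped()`) rejects molecules whose per-axis
extent exceeds 5 nm (configurable) as likely wrapped; protein chains are
exempt by default since an apolipoprotein belt legitimately spans the
particle.

Molecule centers of mass are uniform-weighted by default, with an optional
per-bead mass vector. Uniform weighting is the default because CG bead
masses are nearly uniform and the weighting convention for the reference
analyses is not fixed by any external constraint; the option records the
choice explicitly.

## Radial structure

`radial_density()` histograms distances of beads (or molecule COMs) from
the particle COM and divides time-averaged counts by the spherical shell
volume `(4/3)π(r₊³ − r₋³)`. The particle COM excludes water always and
protein by default — the reference point is the lipid droplet itself; both
choices are arguments. The default bin width of 0.1 nm resolves the ~1 nm
wide intermediate region. Integrated counts return species totals exactly
(a normalization test enforced on every fixture).

Regions are assigned by molecule-COM radius with half-open intervals:
`r < r₁` core, `r₁ ≤ r < r₂` intermediate, `r ≥ r₂` surface, defaults
`(3, 4)` nm. The half-open convention is arbitrary at a measure-zero set
but fixed for reproducibility.

`composition()` reports counts and mol%. The denominator includes the
protein chains by default because that convention reproduces the reference
composition table of the studied system (53.9 / 2.1 / 25.3 / 10.2 / 8.1
mol% for 260/10/122/49/39 lipids + 2 chains); the lipid-only denominator
is one flag away.

## Orientational order and conformations

The local director on a spheroidal particle is the *effective normal*: the
unit vector from the particle COM to the midpoint of the molecular axis.
The molecular axis is a named bead pair (data, not code:
`default_axis_definitions()`), drawn tail-to-head — for CHOL from the
chain-attached end of the ring to the hydroxyl-adjacent ring bead, and
analogously for the CE ring. Order is quantified by the second Legendre
polynomial `S = <(3cos²θ − 1)/2>`, accumulated into radial bins by the
*axis midpoint* distance (consistent with the effective-normal definition;
binning by molecule COM would mix in the offset between COM and ring).
`S` spans `[−0.5, 1]`: the P2 form is adopted because tangentially ordered
surface molecules must be able to produce negative values near −0.5, which
only P2 among the standard order measures provides. Bins with fewer than
50 samples (default) are flagged unreliable rather than dropped.

Axes are treated as directed vectors, not nematic ± directors, because the
sterol axis has a chemically defined head; chain–chain angle distributions
therefore keep the full `[0°, 180°]` range. Angle distributions are
normalized to unit mass; zero-length vectors are excluded with a counted
warning. The CE conformation map is the joint normalized histogram of
(ring vs normal, ring vs oleate chain), filtered by the region of the ring
midpoint.

## Diffusion from jump lengths

For a species and lag τ (an integer multiple of the frame interval — any
other lag is an error naming the nearest valid ones), jump lengths are the
Euclidean norms `|x(t+τ) − x(t)|` of molecule-COM displacements over all
overlapping frame pairs. Surface jumps are chord lengths, not geodesics;
with steps bounded well below the particle radius the chord–geodesic
discrepancy is below 1% and is accepted.

Two candidate free-diffusion jump-length densities are least-squares
fitted to the normalized histogram (100 bins by default):

- 2D: `P₂d(r) = r/(2Dτ) · exp(−r²/4Dτ)`
- 3D: `P₃d(r) = 4πr² (4πDτ)^(−3/2) · exp(−r²/4Dτ)`

These are the standard Gaussian-propagator forms for lateral and isotropic
free diffusion. Each fit is a one-parameter optimization over `log₁₀ D`
(Brent search over ±2 decades around the moment estimate
`D₀ = <r²>/(2dτ)` — the moment initialization makes convergence failures
practically impossible; a degenerate all-zero sample is an explicit
error). The lower-residual model decides the dimensionality and supplies
`D`; both residuals are always reported. At least 500 jumps (configurable)
are required.

`diffusion_vs_lag()` repeats the fit over a lag grid and flags a *plateau*
when `D(τ)` varies by less than 10% (relative range) over the final half
of the grid — the diagnostic for having reached the hydrodynamic
(long-time) limit, which for these particles means lags of order 100 ns.
For region-filtered estimates a molecule is assigned by its region at the
*start* frame of each pair; molecules crossing regions during the lag are
not excluded. This is the simplest reproducible rule; it slightly mixes
regions at the boundaries and is flagged as a package convention.

For cross-dimension comparison, `normalized_profile()` scales each
coefficient by `2d` (the MSD-slope convention, so the scaled value is the
slope of the mean squared displacement); an identity scale is available
since the comparison convention is not externally fixed.

## Contacts, lifetimes, RMSF

All contact machinery uses a strict cutoff (`distance < 0.8 nm`, i.e.
8 Å); strict-vs-closed affects a measure-zero set and is documented here
once. Neighbor searches use a cell list (cubic cells of edge `cutoff`,
27-cell neighborhoods) and are required — by test — to agree exactly with
the all-pairs brute force, which is retained as `method = "brute"`.

A lipid is *annular* in a frame iff any of its beads is within the cutoff
of any protein bead. Lifetime statistics apply the gap-tolerance rule: a
non-contact gap strictly shorter than `tolerance_frames` (default 10)
does not break the surrounding contact interval. Gaps at the series ends
are never bridged. Intervals touching either trajectory end are censored:
excluded from the default means (they are lower bounds, not observations)
but reported, and means including them are also returned, since the
censoring convention is a genuine free choice. Tolerances 0 and 1 are
equivalent (a gap of zero frames cannot occur in a frame-sampled series),
and mean lifetime is non-decreasing in the tolerance — both are tested
properties.

Per-residue contact profiles divide pooled (lipid bead, protein bead)
pair counts by the number of residues of that type in the protein content
of the topology ("normalized per residue"); a hydrophobic/hydrophilic
rollup uses the same normalization per class. The hydrophobicity table
(Trp, Phe, Val, Leu, Ile, Met, Ala hydrophobic; the rest hydrophilic) is
editable data; Tyr and His sit near the interfacial-hydrophobicity
borderline and are kept hydrophilic by default.

RMSF is computed per protein backbone bead after a least-squares
rigid-body superposition (Kabsch) of each frame's selection onto the
first frame, jointly over all selected beads. Alignment defaults to on
because the droplet tumbles freely and unaligned RMSF measures rotation,
not flexibility; with fewer than 3 beads the rotation is underdetermined
and alignment is an error.

## SASA

Shrake–Rupley with a deterministic Fibonacci lattice (960 points per bead
by default; doubling the count changes a single-bead area by < 0.5%).
The probe radius defaults to 0.56 nm — the atomistic 0.14 nm water probe
scaled for the 4-to-1 CG water mapping. Bead radii default to 0.235 nm
(half the standard 0.47 nm CG bead diameter) and are overridable per bead
name; the reference bead-radius table is not published, so the
hydrophobic/hydrophilic split on real systems should be read
qualitatively. Occluders are all non-water beads — lipids bury protein
surface — while the selection only restricts whose area is reported. A
lattice point exactly on an occluder's expanded sphere counts as buried
(with an epsilon absorbing rounding), which makes coincident equal-radius
beads occlude each other completely, the correct degenerate limit.

## The synthetic generator: what it emulates, and what it does not

`build_droplet()` realizes the reference composition with species-specific
placement: TG/CE (and 15% of CHOL by default) uniform in the core ball,
POPC/PPC (and 85% of CHOL) at uniform radii in the surface shell, protein
chains as bead circles just inside the particle radius. Molecules are
placed in antipodal pairs so the particle COM sits at the origin by
construction — a variance-reduction choice that removes COM jitter from
placement tests without affecting any per-molecule statistic. Ring lipids
are anchored by their ring-axis midpoint (the quantity radial binning
uses), other species by their COM, so prescribed radii and orientations
are recovered exactly up to sampling noise.

Axis orientations are drawn from a Maier–Saupe-type density
`∝ exp(λ cos²θ) sinθ` with λ solved by bracketed root finding on
`[−50, 50]` (tolerance 1e−6 in `S`) so that `<P2>` hits the per-region
target (defaults: core 0, intermediate 0.7, surface 0.6 — disordered
melt, strong radial ordering in the crossover shell, slightly weaker at
the surface). Any distribution achieving the target order would do; this
single-parameter family is simply a convenient, documented choice. The
boundary targets ±(0.5, 1) are degenerate distributions and are rejected.

Dynamics are rigid-body translations: surface molecules follow
tangent-plane Brownian steps re-projected onto their own sphere
(`sqrt(4 D dt) ≤ 0.2 R` enforced, keeping curvature bias below fitting
tolerance), core molecules isotropic Gaussian steps with radial reflection
at the core boundary. Default coefficients are 1e−3 nm²/ns at the surface
and ten-fold slower in the core, the characteristic surface-to-core
contrast of such particles. Contact processes are alternating exponential
dwells (defaults 146/175 ns contact/non-contact — the reported dwell
scales of the studied system) discretized at the frame interval.

What passing recovery tests shows: the estimators are unbiased at the few
percent level on data whose generating process matches their model
assumptions, and the bookkeeping (censoring, merging, binning,
normalization) is exact. What it does not show: behavior on real CG
trajectories with correlated molecule motion, anomalous diffusion at
short lags, orientation–position coupling, protein flexibility, or
non-exponential dwell processes. The generator makes no attempt at
physical forces or realistic absolute dynamics.

## Problem sizes and determinism

Every generator draw flows from a single integer seed; fixed-seed runs
are bit-reproducible, and the pipeline writes byte-identical TSVs for
identical configurations. The validation suite uses: 1e5 axis samples for
order recovery (tolerance ±0.02), 100 walkers × 1e4 steps for diffusion
recovery (±5%, correct dimensionality), 100 replicates × 1e4 jumps per
dimensionality for model selection (≥ 99/100), 1e6 frames × 10–20
telegraph series for lifetime recovery (±5%), and ≤ 500-bead fixtures for
exact neighbor-search equality. These sizes were chosen so each property
is tested well inside its expected statistical resolution.

## Interface conventions

Every analysis takes the trajectory first and returns a tibble (or a
small S3 object with `tidy()`/`glance()` methods and an `autoplot()`),
so calls chain with the pipe. The pipeline (`run_pipeline()` with a
`run_config()` or YAML file) writes one TSV per analysis plus a JSON
manifest holding every parameter, the seed and the package version —
sufficient to reproduce any output. The package is driven from R; the
function surface plus the configuration file *is* the command-line story,
with `scripts/acceptance.R` as the scripted entry point for end-to-end
recomputation.

## Known limitations

- XTC trajectories are not read (no reader available in this stack);
  DCD and multi-frame GRO are the supported trajectory dialects.
- Reflection at the core boundary is radial (not specular); for the step
  sizes permitted by the preconditions the difference is negligible.
- The per-residue contact normalization uses residue multiplicity over
  all protein chains present; with identical chains this equals the
  per-chain sequence multiplicity up to a constant factor.
- Radius-of-gyration values on real HDL are validated only against
  analytic fixtures (point sets, cubes, uniform balls), not against a
  published reference value.
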