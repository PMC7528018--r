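---
title: "Methods: rigid-body fitting into negative-stain EM maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigid-body fitting into negative-stain EM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `stainfit`, the meaning and
rationale of every tunable parameter, the scope of the synthetic-data
generator, the numerical choices, and the known limitations. Code chunks are
illustrative and not evaluated when the vignette is built.

## 1. The model

A low-resolution (negative-stain) EM map is treated as a sampled scalar
field $\rho_\mathrm{exp}(\mathbf{x})$ on a regular grid. An atomic model
placed with a rigid transform $T = (R, \mathbf{t})$, $R \in SO(3)$, is
converted to a simulated density by Gaussian splatting:

$$
\rho_\mathrm{sim}(\mathbf{x}) \;=\; \sum_a w_a \,
\exp\!\left(-\frac{\lVert \mathbf{x} - T\mathbf{x}_a \rVert^2}{2\sigma^2}\right),
\qquad \sigma = f_\sigma \cdot \text{resolution},
$$

with atomic-mass weights $w_a$ and the conventional width factor
$f_\sigma = 0.225$ (so the kernel FWHM ≈ 0.53 × resolution, the choice used
by standard simulate-map tools; `simulation_params(sigma_factor=)`). The
envelope of a map normalized to unit maximum is the set of voxels with
value strictly above a threshold (default **0.06**), after removing
speckle: only the largest 6-connected component of the experimental
envelope is kept (`clean_envelope`, the standard "hide dust" step). With
i.i.d. voxel noise at 5 % of the map maximum, ~11 % of empty voxels cross
the 0.06 threshold as isolated islands; these dominated envelope surfaces
and diluted the Chamfer contrast between mirrors, which is why dust removal
is applied to the *experimental* envelope throughout the scoring pipeline
while `binarize()` itself stays a pure thresholding primitive.

### Fit metrics

Each placement is scored with four complementary metrics (`score_fit`):

* **overlap** — $\sum_v \rho_\mathrm{exp}^\mathrm{(norm)}(v)\,\rho_\mathrm{sim}(v)$
  over the grid, with the *raw* (unnormalized) simulated density. Using a
  per-placement normalized model map would divide by the simulated maximum,
  which varies with sub-voxel position and biases the score toward
  placements whose atoms fall between grid points.
* **ccc** — cross-correlation about zero,
  $\sum \rho_\mathrm{exp}\rho_\mathrm{sim} / \sqrt{\sum\rho_\mathrm{exp}^2 \sum\rho_\mathrm{sim}^2}$,
  restricted to the experimental envelope.
* **chamfer** — symmetrized mean nearest-neighbour distance between the
  surface voxels (6-neighbourhood boundary) of the experimental and
  simulated envelopes; the only metric sensitive to *shape* rather than
  mass coincidence.
* **envelope** — Dice coefficient
  $2|A\cap B|/(|A|+|B|)$ of the two envelopes.

## 2. Global fitting

`global_fit(map, body, fit_config())` implements exhaustive one-body
fitting:

1. **Placements** — `n_placements` random starts: rotations uniform on
   $SO(3)$ (normalized Gaussian quaternions), centroids uniform over the
   bounding box of the cleaned experimental envelope.
2. **Local optimization** — greedy coordinate ascent on the 6 rigid
   parameters against the *blurred* experimental map interpolated at the
   transformed atom positions (equivalent to the map-product overlap up to
   trilinear interpolation). Optimization is **coarse-to-fine**: a first
   ascent against a 3×-wider Gaussian objective, then against the target
   width. With a few hundred starts, the narrow-kernel landscape traps
   placements in local maxima (measured: one mirror of an achiral test case
   stuck at ccc 0.52 instead of 0.92); the two-stage ascent removed every
   such failure. Step sizes start at 0.4 rad / 2 voxels and halve on
   failure down to 0.02 of a voxel.
3. **Coverage filter** — placements with less than `coverage_min` (default
   **0.30**) of their simulated envelope inside the experimental envelope
   are discarded, removing fits that only graze the density.
4. **Clustering** — surviving fits are greedily clustered in descending
   optimizer score; a fit joins an existing representative if within
   `cluster_rot_deg` *and* `cluster_trans` of it. Defaults are the tight
   setting (**3° / 2 Å**, many near-duplicate representatives); the loose
   setting used for handedness and assembly work is **30° / 15 Å** (few,
   well-separated representatives). With 2 000 starts on the default case
   these yield on the order of hundreds vs. tens of representatives — the
   package's desk-scale analogue of the high/low clustering regimes of
   production runs with $10^5$ placements.
5. **Scoring** — the four metrics are computed for the representatives
   only, and the ensemble is sorted by overlap. Clustering consumes a
   single score either way and the representative is the best fit under
   the optimized score, so scoring thousands of raw fits before merging
   them away would change nothing but the runtime; this ordering is a
   deliberate design choice.

The result is a classed `fit_ensemble` with `print`, `summary`,
`as.data.frame` and `plot` methods; `fit_significance` reports a z-score of
the top fit against the remaining representatives.

## 3. Handedness determination

`assess_handedness` fits the body (or bodies) into the map and into its
x-mirrored copy and applies a deliberately conservative decision rule
(`decide_handedness`): a mirror is chosen only if

* its best fit beats the other mirror under **all four metrics** by more
  than a **1 % relative margin**, and
* within that mirror the **same representative** tops every metric.

Anything weaker is reported as `"ambiguous"`. The margin was fixed a
priori: optimizer and discretization noise between reruns is well below
1 %, while genuine handedness gaps on resolvable cases are several times
larger, so the margin separates the two regimes without tuning.

## 4. Two-body assembly and crosslink validation

`combine_fits` forms the Cartesian product of two bodies' representatives,
removes pairs whose Cα–Cα clash fraction (contacts closer than
`clash_radius` = **4 Å**) exceeds `clash_max`, and re-scores each survivor
as a union model against the experimental map. The default
`clash_max = 0.2` reflects the placement precision a ~30 Å map admits:
representatives deviate from the optimum by several ångström, so
near-optimal pairs *graze* (measured clash fractions ≈ 0.07 on the default
case) while genuinely interpenetrating pairs score 0.25–0.6; a tighter cap
rejects the good pairs together with the bad ones.

`rank_combined` orders survivors by mean rank across the four metrics
(Chamfer negated) and, when a crosslink table is supplied, reorders the top
`window` fraction (default the top decile) by crosslink satisfaction — the
restraints refine the density ranking rather than override it.

The crosslink module reads xQuest-style tables, filters by ld score
(**inclusive**, `ld >= 40`), maps each link to the minimum Cα–Cα distance
over all chain copies, and flags violations above **35 Å** (the DSS
spacer-arm + side-chain allowance measured between Cα atoms). The mapping
totals always satisfy
$n_\mathrm{violated} \le n_\mathrm{mapped} \le n_\mathrm{pass} \le n_\mathrm{input}$.
Interface sizes are quantified by Shrake–Rupley SASA (golden-spiral
quadrature, 960 points/atom, Bondi radii, 1.4 Å probe):
$\mathrm{BSA} = \mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(A \cup B)$.

## 5. The synthetic generator and study conditions

`make_two_body_case(synthetic_params())` builds the package's default
benchmark, fixed once as a study condition:

* two 60-residue Cα-only toy chains (3.8 Å virtual bonds; a helical
  segment with 1.5 Å rise and 100°/residue — helical fraction 0.5 —
  followed by a self-avoiding random walk), docked to a minimum
  inter-chain distance of ~6.5 Å;
* a joint map and two per-body maps at **30 Å resolution, 4 Å voxels,
  noiseless** by default, plus the x-mirrored joint map;
* a planted crosslink table: 21 satisfied + 4 violated links above the ld
  threshold (25 mapped, satisfaction 0.84), 10 sub-threshold decoys, and 3
  monolinks that must be rejected at parse time.

The problem sizes (60 residues, 2 000 placements, 100 optimization steps)
are the package's own desk-scale choices: they preserve the structure of
the production-scale problem (≈300-residue domains, $10^5$ placements)
while keeping the full pipeline under a few minutes per stage on one core.

**Handedness cases are generated at 8 Å (2 Å voxels)** rather than 30 Å
because an idealized α-helix is effectively achiral once blurred far beyond
its ~2.3 Å radius: its hand is resolvable only when the Gaussian width is
comparable to the helix radius. Chiral cases use an 80 %-helical chain;
achiral controls use a planar chain (all atoms in a plane, hence exactly
superimposable on its mirror), for which the correct answer is
"ambiguous". Benchmark maps carry i.i.d. Gaussian voxel noise at 5 % of
the maximum.

### Identifiability at 30 Å, and what "recovery" means

Two same-size bodies 30 Å apart merge into one blob at 30 Å resolution. A
measured consequence: on the *joint* map, the truth pose of a single body
is not the global optimum of any metric — a placement straddling the merged
density scores higher. Single-body recovery is therefore assessed against
each body's *own* simulated map (the classic self-fit), while the joint map
is the input for handedness, combined fits and crosslink ranking, where the
truth *pair* is the optimum. Even there, single-body fits are displaced
toward the partner density and orientation-degenerate, so combined-fit
recovery is asserted on body **centroids** (location) — the same
location-without-orientation conclusion this kind of combined fitting is
designed to reach.

## 6. Numerical and format choices

* **MRC2014 I/O** is implemented in the package (no installed R package
  reads MRC): mode 2 float32 plus integer modes, both the origin-word and
  nstart conventions on write, machine-stamp endianness handling, and
  crystallographic axis permutations rejected explicitly.
* **Map blurring** uses FFT separable Gaussian convolution with
  zero-padding; interpolation is trilinear (C++).
* **Rotations** are represented as proper rotation matrices
  ($\det R = +1$ enforced; reflections rejected), serialized as
  quaternions; superposition uses a proper-only Kabsch SVD.
* PDB and mmCIF reading goes through `bio3d` (highest-occupancy altloc
  kept, waters excluded); a minimal `atom_site` mmCIF *writer* is included
  because `bio3d` has none.
* The numeric core (splatting, interpolation, coordinate ascent, Chamfer
  nearest neighbour with projection search, clash fractions, SASA,
  connected components) is in Rcpp.

## 7. Limitations

* Noise is i.i.d. Gaussian per voxel — no stain granularity, uneven stain
  depth, flattening, or missing-wedge anisotropy.
* Bodies are strictly rigid; no flexible linkers or conformational
  sampling.
* The optimizer is a greedy coordinate ascent; the coarse-to-fine schedule
  removes the failure modes we observed at these problem sizes, but it is
  not a global optimizer and relies on the multi-start layer.
* Handedness is only decidable when the map resolution resolves chiral
  features of the bodies; at 30 Å with small helical bodies the correct
  output is "ambiguous", which the decision rule is designed to produce
  rather than guess.
* Crosslink mapping uses Cα–Cα distances, not side-chain (NZ–NZ) distances
  or solvent-accessible surface paths.
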