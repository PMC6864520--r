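---
title: "Foveated self-similarity descriptors for multi-modal deformable registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveated self-similarity descriptors for multi-modal deformable registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Aligning two 3D medical volumes of different modalities (T1 against T2
MR, CT against MR, and so on) is hard for two reasons: intensities are
not comparable across modalities — the same tissue can be bright in one
scan and dark in the other, and the relationship need not even be
monotone — and a non-rigid deformation model has an enormous number of
unknowns (three per voxel: over 50 million for a 256³ volume,
`countFieldVariables(c(256, 256, 256))`).

`fmindreg` addresses both with a structural representation, the foveated
modality-independent neighborhood descriptor (FMIND). Each voxel is
described not by its intensity but by how similar its local patch is to
the patches of its six neighbours. That self-similarity pattern is a
property of local image *structure* and survives intensity remapping, so
the multi-modal problem becomes a mono-modal one: minimise the mean
absolute difference (SAD) between the two volumes' descriptor fields.

## The descriptor

**Foveation.** Patch comparisons use a space-variant blur modelled on
retinal acuity: the patch centre is sampled with a near-delta kernel
(base standard deviation `sigma0 = 1/(2π)` voxels) and peripheral
offsets `u` of the 5×5 in-plane support are sampled with elliptical
Gaussian kernels that widen with `|u|` and, for elongation `rho > 1`,
stretch along the radial direction `∠u + theta`. The foveated distance
between two fixation points is the squared Euclidean distance between
their foveated patches.

Two discretisation choices are ours, because the printed construction
leaves the exact constants open. First, the kernel scale grows as
`sigma(u) = sigma0 · (1 + 2|u|)`; a slower growth leaves the nearest
peripheral kernels so narrow that an integer grid cannot represent an
elongation of 2 at all (the realised second-moment anisotropy of a
point-sampled kernel at `|u| = 1` is badly wrong). Second, kernels are
integrated over pixel cells (supersampling) and each axis scale is then
numerically calibrated so the *discrete* along/across-axis standard
deviation ratio matches `rho`; the test suite verifies the realised
ratio to within a few percent and the radial alignment to within 5°.
Kernels are truncated at `3·√rho·sigma(u)` and L1-normalised, so
foveating a constant image is an exact no-op.

**FMIND.** For search offsets `r` in the 3D six-neighbourhood,

    FMIND(I, x, r) = (1/n) · exp( − d_FOV(I, x, x+r) / V_FOV(I, x) )

where `V_FOV` is the mean foveated distance over the whole patch support
(including the zero offset) and `n` normalises the per-voxel channel
maximum to exactly 1. Two numerical guards matter: `V_FOV` is floored at
`1e-6` times the squared intensity range so flat regions do not divide
by zero, and the exponentials are computed as
`exp(−(d − d_min)/V)` — algebraically identical to dividing by the
maximum, but immune to underflow when `d ≫ V` (which genuinely occurs
next to strong edges in noise-free synthetic volumes). Intensities are
rescaled to [0, 1] per volume first, so all thresholds are transferable
across modalities. Patches are 2D (axial by default, selectable with
`planeAxis`) while the search window is 3D; the similarity of two
volumes at a voxel, `SAD_F`, is the mean absolute difference of their
six descriptor channels and lies in [0, 1).

## The transformation model and its optimisation

The deformation is a cubic B-spline free-form deformation (FFD) on a
vertex lattice with one margin ring (default spacing 8 voxels, a
choice that balances flexibility against cost at the 64³ scale we
test at). Volumes are warped backwards
with trilinear interpolation and edge clamping.

Registration is discrete: each control vertex chooses among axis-aligned
candidate displacements `{0} ∪ {±k·quantum·e_axis}` (default 4 steps of
1 voxel), minimising a first-order MRF energy — per-vertex data terms
plus an L1 smoothness on neighbouring vertex labels with weight
`lambda`, normalised by the vertex count. The data term of a vertex
integrates `SAD_F` between the reference descriptors and the float
descriptors resampled through the current field plus the candidate
displacement, weighted by the vertex's B-spline basis over its support
(the candidate is held constant over the support — the standard
first-order approximation of discrete FFD registration). The descriptor
field of the float image is warped channel-wise rather than recomputed
after every candidate warp; the two agree exactly at zero displacement,
and the slow recompute path exists for validation.

One scaling decision deserves emphasis: the data term is an *integral*
over the support region, not a mean. `lambda = 0.01` is calibrated to
that scale; pairing it with a support-normalised mean (a factor of
`spacing³ ≈ 512` smaller) makes the smoothness term dominant and visibly
over-smooths the recovered field. The exported `dataCost()` returns the
normalised per-vertex mean (the natural interpretable quantity); the
pipeline's energy model uses the unnormalised sum.

The minimiser is expansion moves: the L1 label cost is a metric, so each
binary "switch to label α or keep" subproblem is submodular and solved
exactly as a max-flow min-cut (igraph backend); an ICM fallback is
available via `solver = "icm"`. Labels are visited in order of
increasing L1 magnitude with ties broken toward lower index, and a move
is accepted only if it strictly lowers the energy, so the energy trace
is non-increasing and exact ties bias toward the identity. Two
deterministic starts are tried (all-zero and per-vertex data argmin) and
sweeps begin from the better one. Outer cycles (default 5) re-densify
the grid and accumulate the chosen labels into the vertex displacements.
Because labels are axis-aligned, a vertex can move along only one axis
per cycle; the first `quantumHold = 3` cycles therefore run at the full
quantum so moves can compose along all three axes, and the remaining
cycles halve the quantum for sub-voxel refinement. Each additional
composition cycle measurably improves recovery of oblique smooth warps
in the test conditions.

## The spatial constraint

Before optimisation, the vertex set G is split into static and dynamic
subsets from the initial similarity map: around each vertex a cubic
patch of radius `rlp = 7` voxels is inspected, `con` counts voxels with
`1 − SAD_F > delta` (`delta = 0.8`), and the vertex is frozen static
when `con/|LP| > epsilon` (`epsilon = 0.9`, strict inequalities as in
the defining pseudocode). Only dynamic vertices carry optimisation
variables; static ones stay at zero but remain in the smoothness term,
so the frozen boundary regularises its neighbours. The union of the
dynamic vertices' B-spline supports is the automatic registration mask.
Two boundary conventions are ours: clipped patches use the clipped voxel
count in the ratio, and margin-ring vertex positions are clamped into
the volume so they are judged by the nearest image content (this keeps
the two limiting cases exact: identical volumes freeze every vertex,
uniformly dissimilar maps free every vertex). The partition is computed
once from the initial map by default; `refreshPartition` recomputes it
each cycle from the partially warped float.

Raising `delta` or `epsilon` can only grow the dynamic set — both tests
and the acceptance script check this monotonicity — the qualitative
behaviour behind choosing 0.8/0.9 as the stable operating point.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `rho` | 2 | — | kernel elongation; 1 = isotropic |
| `theta` | 0 | rad | kernel angular offset |
| `patchShape` | 5×5 | voxels | foveated patch support (in-plane) |
| `lambda` | 0.01 | — | smoothness weight on the integral-scale data term |
| `rlp` | 7 | voxels | partition patch radius |
| `delta` | 0.8 | — | similarity threshold (on `1 − SAD_F`) |
| `epsilon` | 0.9 | — | static factor |
| `gridSpacing` | 8 | voxels | FFD vertex spacing |
| `labelQuantum`, `labelSteps` | 1, 4 | voxels | discrete displacement sampling |
| `maxCycles`, `quantumHold` | 5, 3 | — | outer cycles; full-quantum cycles before halving |

The first block are the method's standard parameterisation; the rest
are this package's documented choices. A two-level pyramid (block-mean ×2
downsampling, coarse solve, field upsampling and composition) switches
on automatically above 64 voxels per axis; all tests and the acceptance
script run single-level at 64³ and below.

## What the synthetic generator emulates — and what it does not

`simulateCase()` builds the full evaluation setup with no downloads: a
phantom of sigmoid-edged ellipsoids (≈1.5-voxel boundary transitions)
carrying two-scale intensity texture (a correlated ≈1.5-voxel field plus
voxel-scale heterogeneity), a second "modality" produced by a voxelwise
intensity remap plus modality-specific Gaussian noise, a ground-truth
warp as a linear combination of Gaussian radial basis functions scaled
to a 4-voxel peak, and automatic landmarks drawn from top-decile
gradient-magnitude voxels with a minimum mutual distance.

The texture is not decoration. Self-similarity descriptors respond to
misalignment only where images carry structure at the scale of the
displacement; a smooth blob phantom is far blander than any clinical
scan, and on one the partition — correctly — finds nothing to register.
The two texture scales stand in for the shared anatomical detail real
multi-modal pairs have in common. RBF widths (16 voxels) are chosen
large relative to the grid spacing so the FFD can represent the warp.

The pair is assembled so the ground truth is exactly the field the
registration should output: the *reference* is the phantom pulled
through the true field and the *float* is the remapped phantom. Pulling
the float through the true field reproduces the reference geometry
voxel for voxel, the unregistered TRE equals the mean true displacement
magnitude at the landmarks, and no field inversion is needed anywhere in
the evaluation.

The default remap is contrast inversion — the archetypal multi-modal
relationship. The non-monotone band remap is implemented and tested as a
stress mode, but it scrambles voxel-scale texture ordering and with it
the premise any self-similarity descriptor relies on; results under it
say more about the remap than about the method. What passing synthetic
tests do *not* show: behaviour under anatomically realistic contrast,
bias fields, ultrasound speckle, resampling artefacts, or deformations
outside the FFD's representable family.

## TRE evaluation

`evaluateTRE()` samples the true and estimated displacement vectors
trilinearly at each landmark and reports the mean (and sd) Euclidean
norm of their difference — voxel units by default, millimetres via
`voxelSize`. A `mode = "composition"` alternative measures how far the
composite of the estimated and true warps misses the identity, which is
the right quantity when a ground-truth field is defined in the opposite
direction to ours.

## Numerical choices and degenerate inputs

Mirror (half-sample symmetric) folding handles all descriptor boundary
work, including fixation points pushed outside the volume; warping
clamps to the volume edge instead, which is the better behaviour for
resampling. Constant volumes rescale to all zeros and produce all-ones
descriptors; identical inputs take the all-static early exit and return
the identity with a warning in the report. Degenerate grids (volumes
smaller than one spacing) still carry the full margin ring. All
randomness is confined to the synthetic module and flows through
explicit seeds with the caller's RNG state restored; registration itself
is deterministic, which the suite verifies bit-exactly. Problem sizes in
the tests — 64³ volumes, 11³ grids, 2×2×2 exhaustive MRF instances —
are chosen so every oracle comparison (naive descriptor transcription,
Algorithm-style partition loop, exhaustive labelling enumeration)
remains feasible.

## Known limitations

- Axis-aligned label sampling reaches oblique displacements only through
  cycle composition and quantum refinement, not within a single solve.
- The partition is as good as the descriptor contrast: texture-free
  regions under true deformation are (by design) frozen, which bounds
  recovery there to what the surrounding spline support interpolates.
- No rigid/affine pre-alignment, no diffeomorphic guarantee, no field
  inversion; volumes must share a shape (resampling is out of scope).
- NIfTI-1 is the only volume format (plain or gzipped); MetaImage is not
  read.
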