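# fmindreg

Non-rigid registration of multi-modal 3D volumes in R, built on the
foveated modality-independent neighborhood descriptor (FMIND).

## The problem and the method

Multi-modal volumes (T1/T2 MR, CT/MR, CT/PET) cannot be aligned by
comparing intensities: the mapping between modalities is unknown and
often non-monotone. FMIND sidesteps intensity entirely by describing
each voxel through its *foveated self-similarity*: the patch at `x` is
compared with the patches at its six neighbours under a retina-like
space-variant blur (near-delta at the patch centre, radially elongated
Gaussian kernels of elongation ρ toward the periphery), and

```
FMIND(I, x, r) = (1/n) · exp( − d_FOV(I, x, x+r) / V_FOV(I, x) ),   r ∈ R
```

with `d_FOV` the foveated patch distance, `V_FOV` its mean over the
patch support and `n` normalising the per-voxel maximum to 1. The mean
absolute difference between two volumes' descriptor vectors (`SAD_F`)
is the similarity measure; it is near zero wherever local structure
agrees, whatever the intensities do.

Registration minimises a first-order MRF energy over a cubic B-spline
free-form deformation grid: per-vertex data terms integrate `SAD_F`
under candidate discrete displacements, an L1 smoothness (weight
λ = 0.01) couples neighbouring vertices, and expansion moves (max-flow)
minimise the labelling. A descriptor-driven spatial constraint divides
the control vertices into *static* and *dynamic* sets beforehand —
a vertex is frozen when more than ε = 90% of the voxels in its local
patch (radius 7) have similarity `1 − SAD_F > δ = 0.8` — shrinking the
optimisation to the regions that actually deform and yielding an
automatic registration mask with no segmentation or manual input.
Accuracy is evaluated as landmark target registration error (TRE): the
mean Euclidean difference between ground-truth and estimated
displacements at landmark positions.

A synthetic module generates complete desk-scale evaluation cases
(textured multi-modal phantom pairs, Gaussian-RBF ground-truth warps,
automatic landmarks), so the whole pipeline is exercisable without any
external data.

## Worked example

```r
library(fmindreg)

case <- simulateCase(syntheticSpec(seed = 11))   # 64³ multi-modal pair, 4-voxel warp
before <- evaluateTRE(case$landmarks, case$trueField,
                      identityField(dim(case$reference)))
res <- registerFMIND(case$reference, case$float)
after <- evaluateTRE(case$landmarks, case$trueField, res@field)

res@report$partition
before
after
```

```
List of 3
 $ total  : num 1331
 $ static : int 660
 $ dynamic: int 671

TRE: mean 1.888 +/- 0.870 voxels over 30 landmarks
TRE: mean 0.306 +/- 0.208 voxels over 30 landmarks
```

The partition froze 660 of 1331 control vertices (the undeformed and
structure-free regions), and registration reduced the mean landmark TRE
from 1.89 to 0.31 voxels — the float volume, although its intensities
are an inverted, noisy remap of the reference's, is pulled back onto the
reference geometry. `res@warped` holds the warped float volume,
`res@field` the dense displacement field, and `res@report` the
parameters, partition counts and non-increasing per-cycle energy traces.

## Documentation

The methods vignette (`vignettes/fmind-registration.Rmd`) describes the
descriptor construction and its discretisation, the MRF model and data
term scaling, the partition's boundary conventions, what the synthetic
generator does and does not emulate, and known limitations.
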