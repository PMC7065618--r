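# octalesion

Automatic skin-lesion-area determination for basal cell carcinoma (BCC)
from OCT angiography (OCTA) volumes, for researchers working on
quantitative cutaneous microvasculature imaging.

OCTA renders flowing blood as bright tubular structures in a 3D volume.
`octalesion` enhances and segments those vessels, reduces them to a
medial-axis skeleton, decomposes the skeleton into trees and branches, and
evaluates seven quantitative vascular parameters inside regions of
interest (ROIs):

* **NT** — number of independent vascular trees,
* **NB** — number of branches,
* **VD** — vascular density, the fraction of ROI voxels occupied by
  skeleton (dimensionless),
* **MR** — mean vessel radius from the anisotropic Euclidean distance
  transform (mm),
* **DM** — distance metric, en-face path length over endpoint chord
  (= 1 for a straight vessel),
* **ICM** — inflection count metric, DM × number of curvature-sign flips,
* **SOAM** — sum of angles metric, total 3D turning angle per unit path
  length (rad/mm).

A grid of 2.5 × 2.5 × 0.3 mm ROIs with 30 % overlap turns per-ROI VD into
an en-face heat map (overlaps averaged). A lesion is flagged when the
standard deviation of the VD values painted on the skeleton exceeds
4 × 10⁻⁵; the subtype follows from the number of distinct areas above 75 %
of the heat-map maximum (one focal high-density blob = superficial BCC,
several = nodular BCC); the lesion area is extracted by direct
thresholding (sBCC) or by iterative low-VD thresholding (start 20 % above
the nonzero minimum, grow by 30 %; nBCC), refined with a disk of radius
20 px, and finally reported against a healthy reference ROI placed as far
from the lesion as possible.

## Worked example

Everything is testable without patient data through the seeded phantom
generator, which builds an OCTA-like volume (layered capillary bed, PSF
blur, correlated speckle) with exact ground truth:

```r
library(octalesion)

phantom <- make_phantom(phantom_spec("sbcc", seed = 1))  # superficial BCC
result  <- run_pipeline(phantom$volume, pipeline_config(seed = 1))
result
#> <lesion_result> present=TRUE subtype=sBCC vd_std=0.000186
#>   lesion centroid (y, x) = (2.36, 2.36) mm
#>   lesion:  <vascular_params> NT=6 NB=147 VD=0.0016095 MR=0.03848 mm DM=1.229 ICM=0.845 SOAM=16.76 rad/mm (n=75)
#>   healthy: <vascular_params> NT=7 NB=53 VD=0.0010129 MR=0.0475 mm DM=1.102 ICM=0.909 SOAM=6.402 rad/mm (n=37)
```

Reading the output: the painted-VD standard deviation (1.9 × 10⁻⁴) is far
above the 4 × 10⁻⁵ lesion-free limit, so a lesion is present; the areas at
≥ 75 % of the heat-map maximum form a single focal blob, so the lesion is
superficial; the detected lesion centroid lies within a tenth of a
millimetre of the simulated lesion center (2.30, 2.30); and the lesion ROI
is denser (VD 0.0016 vs 0.0010), richer in branches (NB 147 vs 53) and has
finer vessels (MR 0.038 vs 0.048 mm) than the healthy reference — the
directions reported clinically for sBCC. (SOAM values on voxel paths run
higher than values from smooth centerline fits; the analytic behavior of
the metric itself is pinned by the tortuosity tests.)

Volumes can also be read from disk (`read_volume()`: multi-page TIFF,
NIfTI-1, or raw binary with a JSON sidecar) and the whole pipeline is
scriptable:

```sh
Rscript inst/cli/octa-lesion.R simulate --kind sbcc --seed 1 --out phantom/
Rscript inst/cli/octa-lesion.R run --input phantom/phantom.tif --out results/
```

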