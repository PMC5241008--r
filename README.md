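# tmjfuse

Fusion of temporomandibular joint (TMJ) MRI and cone-beam CT (CBCT), and
quantification of how reproducibly the joint's structures can be
reconstructed in 3-D.

The TMJ's articular disc is only visible on MRI, while the condylar head
and glenoid fossa are only sharply delineated on CBCT.  `tmjfuse`
registers the two volumes rigidly into one coordinate system, segments
the osseous structures by Hounsfield thresholding and the disc from
manual per-slice contours, exports unsmoothed STL surface models, and
measures intra-observer reproducibility between two segmentation sessions
with symmetric surface distances and the Dice similarity index.  A
deterministic digital TMJ phantom reproduces the acquisition geometry
(0.25 mm isotropic CBCT; 3 mm MR slices with 0.3 mm inter-slice gaps) so
every stage is testable without patient data.

## Method at a glance

Registration maximises mutual information between the fixed CBCT volume
*U* and the moving MR volume *V* under a rigid/similarity transform *T*:

    MI(X, Y) = sum_{x,y} p(x,y) log2[ p(x,y) / (p(x) p(y)) ]
    T-hat    = argmax_T  MI(U, V ∘ T)

with `p(x,y)` the joint intensity histogram of the overlapping voxels
(64 equal-width bins per axis).  The default similarity is the
overlap-invariant normalised form `NMI = (H(X) + H(Y)) / H(X, Y)`.  The
optimiser is Powell's conjugate-direction method (derivative-free, line
maximisation by Brent's method) in two stages: a coarse pass on a
4x-subsampled grid, then a fine full-resolution pass.

Reproducibility of two models *M1*, *M2* of one structure is summarised
by the perpendicular surface distances (RMSD: root mean square; MD:
maximum, over pooled nearest point-to-triangle distances both ways) and

    DSI(M1, M2) = 2 |M1 ∩ M2| / (|M1| + |M2|)

## Worked example

```r
library(tmjfuse)

ph  <- generatePhantom(phantomSpec())      # CBCT + MR pair, truth known
reg <- registerVolumes(ph$ct, ph$mr)       # two-stage NMI registration
reg@transform
#> SimilarityTransform (intrinsic x-y-z Euler, LPS mm)
#>   rotation (deg):     2.980597, -1.979496,  4.819513
#>   translation (mm):   4.002138, -2.997291,  2.001869
#>   scale: 1   center (mm):  0,  0, -6
```

The phantom's ground truth is (4, -3, 2) mm and (3, -2, 5) degrees, so
registration recovers the pose to within 0.2 degrees and 0.01 mm here.
Continuing to segmentation and comparison:

```r
bone  <- thresholdSegment(ph$ct, 300, 1000)   # osseous HU window
s1    <- perturbMask(ph$masks$condyle, 0.15, seed = 1)  # "session 1"
s2    <- perturbMask(ph$masks$condyle, 0.15, seed = 2)  # "session 2"
compareModels(s1, s2)
#> ComparisonReport 'condyle' (symmetric distances)
#>   RMSD 0.0769 mm, MD 0.6124 mm, DSI 0.9903
#>   volumes (voxels): A 39189, B 39218, overlap 38824
```

RMSD/MD are in mm on the CBCT grid; a DSI of 0.99 means the two
sessions overlap on 99% of their combined volume (1 = identical masks).

Summarising a reproducibility table (one row per joint and structure,
as shipped in `inst/extdata/tmj_reproducibility.csv`, the per-joint
values of a published ten-joint intra-observer study):

```r
df <- read.csv(system.file("extdata", "tmj_reproducibility.csv",
                           package = "tmjfuse"))
summarizeReproducibility(df)
```

which appends the mean/SD summary row per structure (condyle
RMSD 0.10 mm, MD 1.94 mm, DSI 0.98; fossa 0.22 / 2.01 / 0.96; disc
0.31 / 3.62 / 0.80 at the table's truncated precision).

A command-line front end covering the same steps
(`register`, `fuse`, `segment`, `mesh`, `compare`, `stats`, `phantom`,
`run`) is installed at `inst/cli/tmjfuse`.

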