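# reconsim

Exact in-silico estimation of how much of a deep microsurgical site a ring
of narrow-baseline cameras can reconstruct in 3D.

Common-main-objective (CMO) surgical microscopes force any camera array to
share one front lens, capping the stereo baseline at the lens diameter
(20–30 mm at ~400 mm working distance). `reconsim` models such a system as
`M` ideal pinhole cameras placed equidistantly on a ring of diameter `d` at
working distance `h`, all confocal on a reference point `F`, and computes —
in continuous space, by polygon clipping rather than rendering — the subset
of a triangle mesh visible to at least `T` cameras:

```
R = ⋃_i ⋃_{l ∈ C(L_i, T)} ⋂_{c ∈ l} φ_i(c)
```

where `φ_i(c)` is the part of face `F_i` visible to camera `c` (after
backface culling, FOV clipping, and subtraction of merged occluder images),
`L_i` the cameras seeing any part of `F_i`, and `C(L_i, T)` the T-subsets
of `L_i`. A point visible to at least `T = 2` cameras is treated as
reconstructable; the result is the geometric upper bound for any
photogrammetric method under those optics. Reconstructable areas `Ar(M)`
are swept over camera counts, normalized to a 360-camera benchmark ring
(one camera per 0.26 mm of arc), and summarized by multi-phase exponential
saturation fits.

The package includes a parametric generator of deep operative-corridor
meshes (circular and deformed-elliptical channels, 50–100 mm deep, with
optional bottom relief, a spanning artery, or a wall overhang), binary and
ASCII STL I/O with watertightness validation, and a Monte-Carlo
ray-casting oracle used by the tests to verify the exact pipeline.

## Worked example

```r
library(reconsim)

# a 50 mm deep, 25 mm wide circular corridor with bottom relief,
# centred on the camera focal point
site <- make_channel_site(channel_spec(anatomy = "flat_relief",
                                       segments = 36, wall_bands = 5,
                                       z_offset = -25))
validate_mesh(site)$watertight
#> [1] TRUE

ring <- make_ring_setup(M = 4, d = 30, h = 400, fov = c(36, 24))
ring
#> ring_setup: 4 cameras, d = 30 mm, h = 400 mm, aperture-to-focus 400.281 mm
#>   FOV 36 x 24 mm in the focal plane

rec <- reconstructable_subset(site, ring, T = 2)
rec
#> reconstruction: M = 4 , T = 2
#>   reconstructable faces: 696 | area: 4012.6143 mm^2
#>   by tag: anatomy= 505.274, top_surface= 289.275, wall=3218.065
```

About 4000 mm² of the site are visible to at least two of the four
cameras: most of the channel wall, the bottom anatomy, and the part of the
block's top surface inside the combined field of view. Sweeping camera
counts and normalizing to the 360-camera benchmark:

```r
sw <- run_camera_sweep(site, counts = c(2, 4, 6, 8, 16, 32, 64, 128, 256, 360))
sw$table[, c("n", "norm", "delta_pct", "norm_excl_top")]
```

shows the saturation pattern that motivates the design question: the step
from two to four cameras roughly quintuples the reconstructable area of
the deep channel, eight cameras pass 95% of the benchmark even after
excluding the clinically irrelevant top surface, and further cameras add
fractions of a percent. `fit_decay()` summarizes the curve as a negative
two- or three-phase exponential approach to a plateau, and
`report_sweep()` writes the tables, fit figure and run log.

A thin command-line front end is installed with the package
(`inst/scripts/reconsim`):

```sh
Rscript inst/scripts/reconsim make-mesh --cross-section circular \
    --diameter 25 --depth 50 --anatomy spanning_artery --out site.stl
Rscript inst/scripts/reconsim sweep --mesh site.stl --d 30 --h 400 \
    --T 2 --fov 36x24 --out results/
```

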