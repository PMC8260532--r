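# trident3d

Sensorless 2D→3D reconstruction of freehand photoacoustic tomography
(PAT) scans from an optical fiducial pattern.

## The idea

Handheld PAT probes produce 2D cross-sections; the 3D context is lost
unless every slice's pose is known.  Instead of external tracking,
`trident3d` decodes the pose from the image itself: a printed absorbing
**trident** (an isosceles triangle plus its bisector) is placed on the
skin and imaged at a wavelength where its ink absorbs strongly (default
750 nm), while the tissue target is imaged at a second wavelength
(850 nm).  Every slice cuts the trident's three lines in three bright
peaks.  With $d_l$ and $d_r$ the in-image distances from the central peak
to its neighbours and $\gamma$ the pattern half-opening angle, the slice
tilt and offset in the pattern frame follow in closed form:

$$\tan\alpha = \frac{1}{\tan\gamma}\frac{d_l-d_r}{d_l+d_r}, \qquad
a_0 = \frac{(d_l+d_r)\cos\alpha + (d_l-d_r)^2/(d_l+d_r)}{2\tan\gamma}$$

Each accepted slice is rigidly mapped into the pattern frame
(`Translate(0,0,a0) ∘ RotY(α) ∘ Translate(−x_c,−y_c,0)`) and averaged
onto a voxel grid (nearest-voxel assignment, exact mean per voxel).
Reconstruction quality is quantified with point-to-point ICP against a
reference model (fiducial registration error, RMS) and with a slice-based
mean vessel distance (MVD) across repeat scans.  A built-in simulator
renders synthetic scans with exact ray–line intersection geometry and
ground-truth poses for validation.

## Worked example

Simulate a 60-slice careful sweep over the N-wire calibration phantom,
decode every pose, compound the volume and register it to the known wire
model — either from R or from the shell via the `exec/trident3d`
dispatcher:

```sh
trident3d simulate   --n-slices 60 --seed 7 -o demo_scan
trident3d reconstruct -i demo_scan -o demo_rec
trident3d validate   --mode fre --volume demo_rec/volume.nii.gz \
                     --model demo_scan/truth_model.ply -o report.json
```

which prints

```
[trident3d] wrote 60 slices (nwire phantom, careful mode, seed 7) to demo_scan
[trident3d] 60/60 slices accepted
[trident3d] volume 201x151x60 written to demo_rec
[trident3d] FRE 0.1514 mm after 3 ICP iterations
```

All 60 slices pass the pose gates, and the reconstructed wire cloud
registers to the reference model with an RMS error of 0.15 mm — the
floor set by the 0.2 mm pixels and the 0.4 mm wire diameter.  The same
workflow in R:

```r
library(trident3d)
pattern <- patternSpec()               # 20 mm opening over 50 mm extent
ph   <- makeNWirePhantom()
scan <- simulateScan(ph, trajectoryConfig("careful", 60, c(12, 38), seed = 7))
poses <- stackPoses(scanSlices(scan), pattern)
acc  <- which(poses$accepted)
trs  <- lapply(acc, function(i)
  poseToTransform(probePose(poses$alpha_deg[i] * pi / 180, poses$a0_mm[i],
                            poses$x_c_mm[i], poses$y_c_mm[i])))
vol   <- compoundVolume(scanSlices(scan)[acc], trs)
cloud <- thresholdSegment(vol, 0.5, relative = TRUE)
icpRegister(cloud, phantomModel(ph))$fre
#> [1] 0.1514338
```

Single-slice pose decoding is equally direct:

```r
estimatePose(4.2, 3.8, pattern)
#> ProbePose: alpha = 14.036 deg, a0 = 19.453 mm, centre (0.000, 0.000) mm
```

## Layout

* `R/` — pose estimation (`pattern.R`, `slice.R`), simulator
  (`simulate.R`), compounding (`compound.R`), metrics (`metrics.R`),
  I/O (`io.R`), CLI (`cli.R`); S4 classes in `AllClasses.R`.
* `src/` — compiled brute-force nearest-neighbour kernel for ICP.
* `vignettes/trident-tomography.Rmd` — the methods vignette: model,
  conventions, parameter choices, simulator scope, limitations.
* `tests/testthat/` — unit, property and end-to-end tests.
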