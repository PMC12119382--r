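# stereoframe

Frame-based stereotactic planning from head CT, for neurosurgical
researchers and for anyone validating frame workflows without access to
commercial planning stations. The package covers the complete chain from a
frame CT to settable frame coordinates:

1. **Fiducial detection.** A Leksell-type frame carries two lateral N-shaped
   localizer plates whose rods are bright in CT. From four rough user seeds
   on any axial slice, layerwise max-intensity tracking refines each seed to
   the rod maximum within a 21 × 21-voxel window, then follows the rod
   upward slice by slice until the window maximum drops below 500 HU; the
   last position is the rod vertex. The four vertices are labelled
   LA/RA/LP/RP by quadrant, so seed order never matters.
2. **Frame registration.** The detected vertices are rigidly aligned to the
   canonical vertex positions — Leksell (195, 160, 40), (5, 160, 40),
   (195, 40, 40), (5, 40, 40); RAS (∓95, ±60, 60) with the frame centre
   (100, 100, 100) at the RAS origin — using the Kabsch SVD solution
   constrained to proper rotations. The fiducial registration error (RMSE)
   is reported and flagged above 1 mm.
3. **Coordinate conversion.** After registration, image coordinates convert
   to frame coordinates by `(X, Y, Z) = (100 − R, 100 + A, 100 − S)`
   (generalized to a configurable frame centre).
4. **Trajectory angles.** For a target T and entry E in registered RAS, the
   arc angle is `|acos((Er − Tr)/‖E − T‖)|` and the ring angle is
   `90° − atan2(Ea − Ta, Es − Ts)` wrapped to [0°, 180°), which reduces to
   the classical single-argument arctangent form whenever `Es − Ts > 0`.
5. **Validation machinery.** A synthetic CT phantom generator (posed
   N-plates, head ellipsoid, optional partial-volume smoothing and noise,
   known ground truth), plus agreement statistics — per-axis deviations,
   paired t-tests, Bland–Altman bias and 95 % limits of agreement — for
   comparing plan sets.

Volumes load from NIfTI (`.nii`/`.nii.gz`) or from an uncompressed DICOM
series directory (LPS → RAS handled internally).

## Worked example

Plan a trajectory on a synthetic phantom whose frame pose is known exactly:

```r
library(stereoframe)

pose <- rigid_transform(rotation_euler(8, -5, 12), c(10, -6, 8), tol = 1e-6)
ph   <- generate_phantom(phantom_config(pose = pose, noise_sigma = 30,
                                        smooth_fwhm_mm = 2, rng_seed = 42))
seeds <- perturb_seeds(ph$truth, n_sets = 1, max_offset = 5, rng_seed = 42)[[1]]

fids <- detect_fiducials(ph$volume, seeds)
reg  <- register_frame(fids)
reg
#> Frame registration
#>   RMSE: 0.366 mm
#>   per-fiducial residuals (mm):
#>    LA    RA    LP    RP
#> 0.383 0.353 0.394 0.329

target <- apply_transform(pose, c(12, -8, 21))   # lesion centre, scanner RAS
entry  <- apply_transform(pose, c(40, 35, 80))   # skin entry, scanner RAS
plan_trajectory(target, entry, reg)
#> Stereotactic trajectory plan
#>   Leksell target (X, Y, Z): (87.8, 92.0, 79.6) mm
#>   arc angle : 69.0 deg
#>   ring angle: 53.8 deg
#>   trajectory length: 78.2 mm
#>   registration RMSE: 0.37 mm
```

The true target sits at Leksell (88, 92, 79): the planned coordinates are
within 0.6 mm despite the oblique pose, 30 HU of noise and deliberately
misplaced seeds. The RMSE line is the fiducial registration error; values
above 1 mm indicate the seeds should be re-placed.

A thin command-line wrapper with subcommands `phantom`, `detect`,
`register`, `plan`, `evaluate` and `all` is installed at
`inst/cli/stereoframe`:

```sh
Rscript inst/cli/stereoframe plan --volume ct.nii.gz --seeds seeds.csv \
    --target 10,-8,21 --entry 40,35,80 --out run1
```

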