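# Shared phantom fixtures, generated once per test run and cached.
# All phantoms are desk-scale 1 mm grids; the "pv" variants add the
# partial-volume (Gaussian) acquisition model so rod cross-sections have a
# peaked profile like real CT, which is what sub-voxel accuracy checks need.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, make) {
  if (!exists(name, .fixture_cache)) assign(name, make(), .fixture_cache)
  get(name, .fixture_cache)
}

# noiseless binary phantom at the canonical pose
phantom_identity <- function() {
  cached("identity", function() generate_phantom(phantom_config()))
}

# noiseless partial-volume phantom at the canonical pose
phantom_identity_pv <- function() {
  cached("identity_pv",
         function() generate_phantom(phantom_config(smooth_fwhm_mm = 2)))
}

# noisy binary phantom at the canonical pose (sigma 30 HU)
phantom_identity_noisy <- function() {
  cached("identity_noisy",
         function() generate_phantom(phantom_config(noise_sigma = 30,
                                                    rng_seed = 11L)))
}

# partial-volume phantom at a representative oblique pose
phantom_posed_pv <- function() {
  cached("posed_pv", function() {
    pose <- rigid_transform(rotation_euler(10, 10, 5), c(12, -8, 15),
                            tol = 1e-6)
    generate_phantom(phantom_config(pose = pose, smooth_fwhm_mm = 2))
  })
}

# small smooth analytic volume for interpolation tests
smooth_test_volume <- function(dims = c(40, 44, 36), spacing = 1.5) {
  aff <- diag(c(spacing, spacing, spacing, 1))
  aff[1:3, 4] <- -spacing * (dims - 1) / 2
  i <- (0:(dims[1] - 1)) * spacing + aff[1, 4]
  j <- (0:(dims[2] - 1)) * spacing + aff[2, 4]
  k <- (0:(dims[3] - 1)) * spacing + aff[3, 4]
  vox <- outer(outer(100 * sin(i / 25), 80 * cos(j / 20), "+"),
               60 * sin(k / 15), "+")
  ct_volume(vox, aff)
}

expect_points_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(as.numeric(a) - as.numeric(b))), tol)
}
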