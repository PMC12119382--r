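# Layerwise max-intensity tracking against phantom ground truth.

# independent in-plane argmax oracle: scan the clipped window exhaustively
# with explicit loops, applying the smallest-(i, j) tie rule
oracle_refine <- function(v, i, j, k, radius) {
  best <- c(NA, NA); best_hu <- -Inf
  for (ii in max(0, i - radius):min(v$dims[1] - 1, i + radius)) {
    for (jj in max(0, j - radius):min(v$dims[2] - 1, j + radius)) {
      hu <- v$voxels[ii + 1, jj + 1, k + 1]
      if (hu > best_hu) { best_hu <- hu; best <- c(ii, jj) }
    }
  }
  c(i = best[1], j = best[2], k = k)
}

test_that("seed refinement finds the in-plane maximum with the tie rule", {
  ph <- phantom_identity_pv()
  v <- ph$volume
  base <- perturb_seeds(ph$truth, n_sets = 1, max_offset = 0)[[1]]
  # a seed already on the rod-centre voxel stays put
  on_rod <- base["LA", ]
  expect_equal(refine_seed(v, on_rod), oracle_refine(v, on_rod[["i"]],
                                                     on_rod[["j"]],
                                                     on_rod[["k"]], 10))
  # offset seeds agree with the exhaustive oracle
  for (off in list(c(7, 0), c(-5, 6), c(0, -7), c(4, 4))) {
    seed <- on_rod + c(off, 0)
    expect_equal(refine_seed(v, seed),
                 oracle_refine(v, seed[["i"]], seed[["j"]], seed[["k"]], 10))
  }
  # a uniform-intensity window resolves ties to the lowest (i, j)
  flat <- ct_volume(array(7, dim = c(30, 30, 5)), diag(4))
  expect_equal(refine_seed(flat, c(i = 15, j = 15, k = 2)),
               c(i = 5, j = 5, k = 2))
})

test_that("tracking follows a rod to its top and stops at the threshold", {
  ph <- phantom_identity_pv()
  v <- ph$volume
  truth <- ph$truth
  # start on the RA rod, 60 slices below its top: the vertex lands within
  # 1 voxel of ground truth
  mid <- perturb_seeds(ph$truth, n_sets = 1, max_offset = 0)[[1]]["RA", ]
  top_k <- track_vertex(v, refine_seed(v, mid))$path
  top_k <- top_k[nrow(top_k), ]
  start_low <- refine_seed(v, c(i = top_k[["i"]], j = top_k[["j"]],
                                k = top_k[["k"]] - 60))
  tr <- track_vertex(v, start_low)
  expect_lt(sqrt(sum((tr$vertex - truth$vertices["RA", ])^2)),
            max(v$spacing) + 1e-9)
  expect_gte(tr$peak_hu_at_vertex, 500)
  # path is monotone toward superior with bounded in-plane drift
  ks <- tr$path[, "k"]
  expect_true(all(diff(ks) == 1))
  drift <- abs(diff(tr$path[, c("i", "j")]))
  expect_lte(max(drift), 10)
  # restarting at the found vertex terminates immediately on the same voxel
  vtop <- tr$path[nrow(tr$path), ]
  again <- track_vertex(v, vtop)
  expect_equal(nrow(again$path), 1)
  expect_equal(as.numeric(again$path[1, ]), as.numeric(vtop))
  expect_identical(again$vertex, tr$vertex)
})

test_that("a seed below the intensity threshold is rejected", {
  ph <- phantom_identity()
  v <- ph$volume
  base <- perturb_seeds(ph$truth, n_sets = 1, max_offset = 0)[[1]]
  expect_error(track_vertex(v, base["LA", ], threshold = 5000),
               "seed rejected")
  # an air seed is rejected at the default threshold too
  expect_error(track_vertex(v, c(i = 5, j = 5, k = 100)), "seed rejected")
})

test_that("detection labels all four vertices correctly near ground truth", {
  ph <- phantom_identity_pv()
  seeds <- perturb_seeds(ph$truth, n_sets = 1, max_offset = 5,
                         rng_seed = 21)[[1]]
  fids <- detect_fiducials(ph$volume, seeds)
  expect_setequal(rownames(fids$ras), c("LA", "RA", "LP", "RP"))
  err <- sqrt(rowSums((fids$ras - ph$truth$vertices)^2))
  expect_lt(max(err), max(ph$volume$spacing) + 1e-9)
  # detection is deterministic: identical volume + seeds, identical output
  expect_identical(detect_fiducials(ph$volume, seeds)$ras, fids$ras)
})

test_that("quadrant labels survive a 15-degree frame rotation", {
  pose <- rigid_transform(rotation_euler(0, 0, 15), c(0, 0, 0), tol = 1e-6)
  ph <- cached("rot15", function()
    generate_phantom(phantom_config(pose = pose, smooth_fwhm_mm = 2)))
  seeds <- perturb_seeds(ph$truth, n_sets = 1, max_offset = 5,
                         rng_seed = 4)[[1]]
  fids <- detect_fiducials(ph$volume, seeds)
  err <- sqrt(rowSums((fids$ras - ph$truth$vertices)^2))
  expect_lt(max(err), 2)  # per-label pairing correct, voxel quantization only
})

test_that("detection validates its inputs", {
  ph <- phantom_identity()
  seeds <- perturb_seeds(ph$truth, n_sets = 1, max_offset = 0)[[1]]
  expect_error(detect_fiducials(ph$volume, seeds[1:3, ]), "exactly 4")
  # all four seeds on the same rod collapse to one refined voxel
  same <- seeds[rep(1, 4), ]
  expect_error(detect_fiducials(ph$volume, same), "same voxel")
})

test_that("seed files round-trip through CSV and JSON", {
  seeds <- list(c(i = 10, j = 20, k = 5), c(i = 30, j = 40, k = 5),
                c(i = 50, j = 60, k = 5), c(i = 70, j = 80, k = 5))
  f <- tempfile(fileext = ".csv")
  write_seeds(seeds, f)
  expect_equal(read_seeds(f), seeds)
})
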