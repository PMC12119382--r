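# Arc/ring angle computation and trajectory planning.

test_that("arc angle closed-form cases are exact", {
  o <- c(0, 0, 0)
  expect_equal(arc_angle(o, c(10, 0, 0)), 0)
  expect_equal(arc_angle(o, c(0, 0, 10)), 90)
  expect_equal(arc_angle(o, c(7, 7, 0)), 45)
  expect_equal(arc_angle(o, c(-10, 0, 0)), 180)
})

test_that("ring angle closed-form cases are exact", {
  o <- c(0, 0, 0)
  expect_equal(ring_angle(o, c(0, 0, 10)), 90)
  expect_equal(ring_angle(o, c(0, 5, 5)), 45)
  expect_equal(ring_angle(o, c(0, 10, 0)), 0)
  expect_equal(ring_angle(o, c(0, -5, 5)), 135)
})

test_that("ring matches the single-argument arctangent on its domain", {
  withr::with_seed(31, {
    t <- matrix(runif(3000, -80, 80), ncol = 3)
    d <- matrix(runif(3000, -50, 50), ncol = 3)
    d[, 3] <- abs(d[, 3]) + 1e-3   # Es - Ts > 0
    e <- t + d
    for (r in seq_len(nrow(t))) {
      printed <- 90 - atan((e[r, 2] - t[r, 2]) / (e[r, 3] - t[r, 3])) *
        180 / pi
      expect_lt(abs(ring_angle(t[r, ], e[r, ]) - printed), 1e-9)
    }
  })
})

test_that("angles are direction-consistent and pose-invariant", {
  withr::with_seed(37, {
    for (rep in 1:50) {
      t <- runif(3, -80, 80); e <- runif(3, -80, 80)
      if (sqrt(sum((e - t)^2)) < 1) next
      # reversing the direction complements the arc angle
      expect_equal(arc_angle(t, e) + arc_angle(e, t), 180,
                   tolerance = 1e-9)
      # both angles are invariant to scaling the vector and translating
      lam <- runif(1, 0.1, 5); shift <- runif(3, -40, 40)
      e_scaled <- t + lam * (e - t)
      expect_equal(arc_angle(t, e), arc_angle(t + shift, e_scaled + shift),
                   tolerance = 1e-9)
      v <- e - t
      if (sqrt(v[2]^2 + v[3]^2) > 1) {
        expect_equal(ring_angle(t, e),
                     ring_angle(t + shift, e_scaled + shift),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("degenerate trajectories are rejected", {
  expect_error(arc_angle(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  expect_error(ring_angle(c(0, 0, 0), c(10, 0, 0)), "parallel to the R axis")
})

identity_registration <- function(spec = frame_spec()) {
  register_frame(reference_vertices(spec)$ras, spec)
}

test_that("planning composes registration, conversion and angles", {
  spec <- frame_spec()
  reg <- identity_registration(spec)
  plan <- plan_trajectory(c(0, 0, 0), c(0, 0, 80), reg, spec)
  expect_equal(unname(plan$target_leksell), c(100, 100, 100))
  expect_equal(plan$arc_deg, 90)
  expect_equal(plan$ring_deg, 90)
  expect_equal(plan$trajectory_length_mm, 80)
  # Leksell coordinates come from the registered target, bit for bit
  expect_identical(plan$target_leksell,
                   leksell_from_ras(plan$target_ras, spec))
  expect_error(plan_trajectory(c(1, 1, 1), c(1, 1, 1), reg, spec),
               "degenerate")
})

test_that("planning applies the registration transform before the formulas", {
  spec <- frame_spec()
  pose <- rigid_transform(rotation_euler(8, -6, 12), c(10, -5, 8),
                          tol = 1e-6)
  # detected = posed reference vertices, so registration recovers pose^-1
  det <- apply_transform(pose, reference_vertices(spec)$ras)
  rownames(det) <- reference_vertices(spec)$labels
  reg <- register_frame(det, spec)
  target_frame <- c(10, 20, 30)   # canonical-frame RAS position
  entry_frame <- c(15, 45, 75)
  plan <- plan_trajectory(apply_transform(pose, target_frame),
                          apply_transform(pose, entry_frame), reg, spec)
  expect_points_equal(plan$target_ras, target_frame, 1e-8)
  expect_equal(unname(plan$target_leksell),
               unname(leksell_from_ras(target_frame, spec)),
               tolerance = 1e-8)
  expect_equal(plan$arc_deg, arc_angle(target_frame, entry_frame),
               tolerance = 1e-8)
  expect_equal(plan$ring_deg, ring_angle(target_frame, entry_frame),
               tolerance = 1e-8)
})

test_that("plan export round-trips and is self-consistent", {
  spec <- frame_spec()
  reg <- identity_registration(spec)
  plan <- plan_trajectory(c(5, -10, 15), c(25, 30, 75), reg, spec)
  report <- tempfile(fileext = ".json")
  geometry <- tempfile(fileext = ".obj")
  export_plan(plan, spec, report, geometry)
  back <- read_plan(report)
  expect_equal(unname(back$target_leksell), unname(plan$target_leksell))
  expect_equal(back$arc_deg, plan$arc_deg)
  expect_equal(back$ring_deg, plan$ring_deg)
  expect_equal(back$trajectory_length_mm, plan$trajectory_length_mm)
  # angles in the report agree with recomputation from the stored points
  expect_equal(back$arc_deg, arc_angle(back$target_ras, back$entry_ras),
               tolerance = 1e-12)
  expect_equal(back$ring_deg, ring_angle(back$target_ras, back$entry_ras),
               tolerance = 1e-12)
  # geometry: 1 trajectory segment + 10 wireframe segments
  lines <- readLines(geometry)
  expect_equal(sum(grepl("^l ", lines)), 11)
})
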