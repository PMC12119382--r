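# Kabsch alignment: construct-then-recover, optimality, reflection guard.

# independent 6-parameter rigid fit by general-purpose optimization
optim_rigid_rmse <- function(source, target) {
  cost <- function(par) {
    R <- rotation_euler(par[1], par[2], par[3])
    mapped <- sweep(source %*% t(R), 2, par[4:6], "+")
    sqrt(mean(rowSums((mapped - target)^2)))
  }
  fit <- stats::optim(rep(0, 6), cost, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit <- stats::optim(fit$par, cost, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit$value
}

test_that("identical point sets give the identity transform", {
  rv <- reference_vertices()$ras
  t <- kabsch_transform(rv, rv)
  expect_lt(max(abs(t$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(t$translation)), 1e-12)
})

test_that("a known pose is recovered exactly", {
  rv <- reference_vertices()$ras
  pose <- rigid_transform(rotation_euler(0, 0, 30), c(5, -3, 7), tol = 1e-6)
  src <- apply_transform(pose, rv)
  rec <- kabsch_transform(src, rv)
  inv <- invert_transform(pose)
  expect_lt(max(abs(rec$rotation - inv$rotation)), 1e-9)
  expect_lt(max(abs(rec$translation - inv$translation)), 1e-9)
})

test_that("random rigid poses are recovered to numerical precision", {
  rv <- reference_vertices()$ras
  withr::with_seed(17, {
    for (rep in 1:25) {
      ang <- runif(3, -30, 30)
      tr <- runif(3, -50, 50)
      pose <- rigid_transform(rotation_euler(ang[1], ang[2], ang[3]), tr,
                              tol = 1e-6)
      src <- apply_transform(pose, rv)
      rec <- kabsch_transform(src, rv)
      comp <- compose_transform(rec, pose)
      expect_lt(max(abs(comp$rotation - diag(3))), 1e-9)
      expect_lt(max(abs(comp$translation)), 1e-9)
    }
  })
})

test_that("rigid transforms preserve pairwise distances", {
  withr::with_seed(23, {
    pts <- matrix(runif(60, -100, 100), ncol = 3)
    t <- rigid_transform(rotation_euler(12, -7, 33), c(4, 8, -2), tol = 1e-6)
    mapped <- apply_transform(t, pts)
    d0 <- as.matrix(dist(pts))
    d1 <- as.matrix(dist(mapped))
    expect_lt(max(abs(d1 - d0)), 1e-9)
    # round trip through the inverse
    back <- apply_transform(invert_transform(t), mapped)
    expect_lt(max(abs(back - pts)), 1e-9)
  })
})

test_that("Kabsch beats random rigid maps and matches an optimizer", {
  rv <- reference_vertices()$ras
  withr::with_seed(29, {
    for (rep in 1:3) {
      src <- rv + matrix(rnorm(12, 0, 2), 4, 3)
      t <- kabsch_transform(src, rv)
      mapped <- apply_transform(t, src)
      k_rmse <- sqrt(mean(rowSums((mapped - rv)^2)))
      # Monte-Carlo lower-bound check against 1000 random rigid transforms
      for (mc in 1:1000) {
        ang <- runif(3, -180, 180); tr <- runif(3, -30, 30)
        rnd <- rigid_transform(rotation_euler(ang[1], ang[2], ang[3]), tr,
                               tol = 1e-6)
        m <- apply_transform(rnd, src)
        expect_gte(sqrt(mean(rowSums((m - rv)^2))) + 1e-12, k_rmse)
      }
      # nonlinear least-squares refinement cannot do better
      expect_lt(abs(k_rmse - optim_rigid_rmse(src, rv)), 1e-6)
    }
  })
})

test_that("mirrored input still yields a proper rotation", {
  rv <- reference_vertices()$ras
  # make the set non-planar so the mirror is not a rotation in disguise
  src <- rv; src[1, 3] <- src[1, 3] + 40
  tgt <- src
  src[, 1] <- -src[, 1]  # reflect through the r = 0 plane
  t <- kabsch_transform(src, tgt)
  expect_equal(det(t$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(crossprod(t$rotation) - diag(3))), 1e-9)
})

test_that("degenerate configurations are rejected", {
  line <- cbind(seq(0, 30, 10), seq(0, 60, 20), seq(0, 90, 30))
  expect_error(kabsch_transform(line, line), "degenerate")
  rv <- reference_vertices()$ras
  expect_error(kabsch_transform(rv[1:2, ], rv[1:2, ]), "at least 3")
  expect_error(kabsch_transform(rv, rv[1:3, ]), "equal counts")
})

test_that("frame registration reports residuals, RMSE and the warning", {
  spec <- frame_spec()
  rv <- reference_vertices(spec)$ras
  reg0 <- register_frame(rv, spec)
  expect_equal(reg0$rmse_mm, 0, tolerance = 1e-12)
  expect_false(reg0$warning)
  # displace one vertex by 5 mm: the optimal-fit RMSE must match an
  # independent nonlinear fit and trip the 1 mm warning
  det5 <- rv; det5["LA", 3] <- det5["LA", 3] + 5
  reg5 <- register_frame(det5, spec)
  expect_true(reg5$warning)
  expect_equal(reg5$rmse_mm, optim_rigid_rmse(det5, rv), tolerance = 1e-5)
  expect_equal(reg5$rmse_mm,
               sqrt(mean(reg5$per_fiducial_residual_mm^2)))
  # label pairing is required
  bad <- rv; rownames(bad) <- c("A", "B", "C", "D")
  expect_error(register_frame(bad, spec), "labels")
})

test_that("registration results serialize to JSON", {
  spec <- frame_spec()
  rv <- reference_vertices(spec)$ras
  det <- rv; det["RP", 1] <- det["RP", 1] + 2
  reg <- register_frame(det, spec)
  f <- tempfile(fileext = ".json")
  write_registration_json(reg, f)
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(x$rmse_mm, reg$rmse_mm)
  expect_equal(unlist(x$per_fiducial_residual_mm),
               reg$per_fiducial_residual_mm)
  expect_equal(x$matrix, transform_matrix(reg$transform),
               ignore_attr = TRUE)
})
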