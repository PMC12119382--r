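# Agreement statistics: distances, per-axis deviations, Bland-Altman.

test_that("identical sets give zero distances and flagged t statistics", {
  withr::with_seed(41, a <- matrix(runif(30, 90, 110), ncol = 3))
  pa <- point_agreement(a, a)
  expect_true(all(pa$distances == 0))
  expect_true(all(is.na(pa$per_axis$t)))
  aa <- angle_agreement(a[, 1], a[, 1])
  expect_true(all(aa$abs == 0))
  expect_true(is.na(aa$t))
})

test_that("a constant offset is reported exactly", {
  withr::with_seed(43, a <- matrix(runif(30, 90, 110), ncol = 3))
  b <- sweep(a, 2, c(1, 0, 0), "-")   # B = A - (1, 0, 0)
  pa <- point_agreement(a, b)
  expect_true(all(abs(pa$distances - 1) < 1e-12))
  expect_equal(pa$per_axis$signed_mean, c(1, 0, 0))
  expect_equal(pa$per_axis$abs_mean, c(1, 0, 0))
  # angles: A - B sign convention
  aa <- angle_agreement(a[, 1], a[, 1] + 0.5)
  expect_equal(unname(aa$signed_stats[["mean"]]), -0.5)
  expect_equal(unname(aa$abs_stats[["mean"]]), 0.5)
})

test_that("distance agrees with per-axis differences case by case", {
  withr::with_seed(47, {
    a <- matrix(rnorm(60, 100, 5), ncol = 3)
    b <- a + matrix(rnorm(60, 0, 0.5), ncol = 3)
  })
  pa <- point_agreement(a, b)
  expect_equal(pa$distances, sqrt(rowSums(pa$signed_diff^2)))
  # reordering cases leaves the summary statistics unchanged
  perm <- sample(nrow(a))
  pa2 <- point_agreement(a[perm, ], b[perm, ])
  expect_equal(pa2$distance_stats, pa$distance_stats)
  expect_equal(pa2$per_axis$abs_mean, pa$per_axis$abs_mean)
})

test_that("mean Euclidean distance matches the chi-distribution closed form", {
  # per-axis iid N(0, sigma): the distance is sigma * chi(3), whose mean is
  # sigma * 2 * sqrt(2/pi); verify the package statistic against both the
  # closed form and a fresh Monte-Carlo draw
  sigma <- 0.4
  closed_form <- sigma * 2 * sqrt(2 / pi)   # ~0.638 mm
  withr::with_seed(53, {
    a <- matrix(rnorm(3 * 86, 100, 5), ncol = 3)
    b <- a + matrix(rnorm(3 * 86, 0, sigma), ncol = 3)
    pa <- point_agreement(a, b)
    mc <- mean(sqrt(rowSums(matrix(rnorm(3 * 2e5, 0, sigma), ncol = 3)^2)))
  })
  se <- sigma * sqrt(3 - 8 / pi) / sqrt(86)
  expect_lt(abs(pa$distance_stats[["mean"]] - closed_form), 3 * se)
  expect_lt(abs(mc - closed_form), 0.005)
})

test_that("paired-t p-values are uniform under the null", {
  withr::with_seed(59, {
    p <- replicate(200, angle_agreement(rnorm(86, 0, 0.3),
                                        rnorm(86, 0, 0.3))$p)
  })
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Bland-Altman limits follow bias +/- 1.96 SD", {
  expect_error(bland_altman(0.3), "at least 2")
  # constant differences collapse the limits onto the bias
  ba_const <- bland_altman(rep(0.25, 10))
  expect_equal(ba_const$bias, 0.25)
  expect_equal(ba_const$loa_low, 0.25)
  expect_equal(ba_const$loa_high, 0.25)
  withr::with_seed(61, d <- rnorm(86, -0.1, 0.5))
  ba <- bland_altman(d)
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(d))
  # percentile bootstrap of the limits brackets the formula on Gaussian data
  withr::with_seed(67, {
    boots <- replicate(2000, {
      s <- sample(d, replace = TRUE)
      c(mean(s) - 1.96 * sd(s), mean(s) + 1.96 * sd(s))
    })
  })
  expect_lt(abs(ba$loa_low - mean(boots[1, ])), 0.05)
  expect_lt(abs(ba$loa_high - mean(boots[2, ])), 0.05)
})

test_that("the combined report wires points and angles together", {
  withr::with_seed(71, {
    n <- 20
    a <- data.frame(case = paste0("c", 1:n),
                    x = rnorm(n, 100, 10), y = rnorm(n, 100, 10),
                    z = rnorm(n, 100, 10),
                    arc = runif(n, 30, 150), ring = runif(n, 30, 150))
    b <- a
    b[, c("x", "y", "z")] <- b[, c("x", "y", "z")] +
      matrix(rnorm(3 * n, 0, 0.4), ncol = 3)
    b$arc <- b$arc + rnorm(n, 0, 0.3)
    b$ring <- b$ring + rnorm(n, 0, 0.2)
  })
  rep <- agreement_report(a, b[sample(n), ])  # order must not matter
  expect_equal(rep$n, n)
  expect_equal(rep$arc$bland_altman$bias, mean(a$arc - b$arc))
  f <- tempfile(fileext = ".json")
  write_agreement_json(rep, f, text_path = tempfile(fileext = ".txt"))
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(x$sd_denominator, "n-1")
  expect_equal(x$arc$bland_altman$bias, rep$arc$bland_altman$bias)
  # mismatched case IDs are a pairing error
  bad <- b; bad$case[1] <- "zz"
  expect_error(agreement_report(a, bad), "pair")
  expect_error(point_agreement(matrix(0, 3, 3), matrix(0, 4, 3)), "paired")
})
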