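# SEA/SEAc closed forms, hull areas, and the ellipse-overlap integrator

test_that("SEA and SEAc follow the closed forms", {
  # identity sample covariance -> SEA = pi, constructed exactly
  e <- niche_ellipse(c(0, 0), diag(2), n = 10)
  expect_equal(e$SEA, pi)
  expect_equal(e$SEAc, pi * 9 / 8)

  e2 <- niche_ellipse(c(0, 0), diag(c(2, 0.5)), n = 30)
  expect_equal(e2$SEA, pi)   # det = 1

  # from samples: covariance is the n-1 sample covariance
  set.seed(41)
  xy <- cbind(stats::rnorm(50), stats::rnorm(50))
  se <- standard_ellipse(xy)
  expect_equal(se$SEA, pi * sqrt(det(stats::cov(xy))), tolerance = 1e-12)
  expect_equal(se$SEAc / se$SEA, 49 / 48, tolerance = 1e-12)
  expect_gt(se$SEAc, se$SEA)

  expect_error(standard_ellipse(xy[1:2, ]), "at least 3")
  col <- cbind(1:5, 2 * (1:5))
  expect_true(standard_ellipse(col)$degenerate)
  expect_equal(standard_ellipse(col)$SEA, 0)
})

test_that("SEA from bivariate-normal samples converges to pi*sqrt(det(Sigma))", {
  set.seed(42)
  Sigma <- matrix(c(2, 0.7, 0.7, 1), 2)
  L <- chol(Sigma)
  xy <- matrix(stats::rnorm(2e4), ncol = 2) %*% L
  expect_equal(standard_ellipse(xy)$SEA, pi * sqrt(det(Sigma)),
               tolerance = 0.05 * pi * sqrt(det(Sigma)))
})

test_that("total_area matches shoelace fixtures and is hull-monotone", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(as.numeric(total_area(square)), 1.0)
  expect_equal(as.numeric(total_area(rbind(square, c(0.5, 0.5)))), 1.0)
  tri <- rbind(c(0, 0), c(2, 0), c(0, 2))
  expect_equal(as.numeric(total_area(tri)), 2.0)

  expect_true(attr(total_area(rbind(c(0, 0), c(1, 1))), "degenerate"))
  expect_equal(as.numeric(total_area(cbind(1:4, 1:4))), 0)

  set.seed(43)
  pts <- cbind(stats::rnorm(20), stats::rnorm(20))
  ta <- as.numeric(total_area(pts))
  for (i in 1:5) {
    extra <- rbind(pts, c(stats::rnorm(1, 0, 2), stats::rnorm(1, 0, 2)))
    expect_gte(as.numeric(total_area(extra)) + 1e-12, ta)
    pts <- extra
    ta <- as.numeric(total_area(pts))
  }
})

test_that("ellipse_overlap reproduces the circle-lens closed form", {
  e1 <- niche_ellipse(c(0, 0), diag(2), n = 100)
  e2 <- niche_ellipse(c(1, 0), diag(2), n = 100)
  lens <- 2 * pi / 3 - sqrt(3) / 2
  iou <- lens / (2 * pi - lens)
  expect_equal(ellipse_overlap(e1, e2, scale = "sea"), iou, tolerance = 0.005)

  expect_equal(ellipse_overlap(e1, e1), 1)
  far <- niche_ellipse(c(100, 0), diag(2), n = 100)
  expect_equal(ellipse_overlap(e1, far), 0)
  expect_error(ellipse_overlap(e1, niche_ellipse(c(0, 0), diag(c(1, 0)), n = 5)),
               "degenerate")
})

test_that("overlap is symmetric and invariant under common affine maps", {
  e1 <- niche_ellipse(c(0, 0), matrix(c(2, 0.5, 0.5, 1), 2), n = 40)
  e2 <- niche_ellipse(c(1.2, 0.4), matrix(c(1, -0.3, -0.3, 1.5), 2), n = 25)
  ov <- ellipse_overlap(e1, e2)
  expect_equal(ellipse_overlap(e2, e1), ov, tolerance = 0.005)

  A <- matrix(c(1.3, 0.4, -0.2, 0.9), 2)
  b <- c(5, -3)
  ov_t <- ellipse_overlap(affine_transform(e1, A, b), affine_transform(e2, A, b))
  expect_equal(ov_t, ov, tolerance = 0.005)
})

test_that("niche_metrics assembles per-group metrics and a symmetric overlap matrix", {
  set.seed(44)
  iso <- rbind(
    make_iso("charr", stats::rnorm(30, -28, 0.8), stats::rnorm(30, 7, 0.6)),
    make_iso("trout", stats::rnorm(30, -25, 1.2), stats::rnorm(30, 10, 0.9)),
    make_iso("whitefish", stats::rnorm(30, -27.5, 0.9), stats::rnorm(30, 7.2, 0.6)))
  nm <- niche_metrics(iso)
  expect_setequal(nm$metrics$group, c("charr", "trout", "whitefish"))
  expect_true(all(nm$metrics$SEAc > nm$metrics$SEA))
  expect_true(all(nm$metrics$TA > nm$metrics$SEAc))  # hull bounds the core ellipse here
  expect_equal(nm$overlap, t(nm$overlap))
  expect_equal(diag(nm$overlap), c(charr = 1, trout = 1, whitefish = 1))
  # overlapping charr/whitefish clouds vs separated trout
  expect_gt(nm$overlap["charr", "whitefish"], 0.2)
  expect_lt(nm$overlap["charr", "trout"], 0.1)
})
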