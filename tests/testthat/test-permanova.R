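# Bray-Curtis + PERMANOVA against independent oracles (closed-form ANOVA,
# exhaustive enumeration, and vegan where available)

test_that("bray_curtis matches hand values and stays in [0, 1]", {
  m <- rbind(a = c(80, 20, 0), b = c(40, 40, 20))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.4)
  expect_equal(diag(unclass(d)), c(a = 0, b = 0))
  expect_equal(attr(d, "similarity")["a", "b"], 60)

  ident <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(bray_curtis(ident)[1, 2], 0)
  disjoint <- rbind(c(1, 0), c(0, 5))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)
  expect_error(bray_curtis(rbind(c(1, 1), c(0, 0))), "all-zero")
})

test_that("bray_curtis agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  set.seed(21)
  m <- matrix(stats::runif(60, 0, 10), nrow = 10)
  expect_equal(unclass(bray_curtis(m))[lower.tri(diag(10))],
               as.numeric(vegan::vegdist(m, "bray")), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Euclidean one-way pseudo-F equals the classical ANOVA F", {
  set.seed(22)
  for (rep in 1:5) {
    y <- stats::rnorm(30)
    g <- factor(rep(c("a", "b", "c"), each = 10))
    pt <- permanova(as.matrix(stats::dist(y)), data.frame(g = g), "g",
                    n_perm = 19, seed = rep)
    expect_equal(pt$pseudo_F[1], classical_F(y, g), tolerance = 1e-8)
    expect_equal(pt$df, c(2L, 27L, 29L))
  }
})

test_that("multi-factor sequential pseudo-F agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(23)
  fac <- expand.grid(A = c("x", "y", "z"), B = c("u", "v"),
                     stringsAsFactors = FALSE)
  fac <- fac[rep(1:6, each = 3), ]
  m <- matrix(stats::runif(nrow(fac) * 6, 0, 10), nrow = nrow(fac))
  d <- bray_curtis(m)
  pt <- permanova(d, fac, c("A", "B", "A:B"), n_perm = 19, seed = 1)
  va <- vegan::adonis2(stats::as.dist(d) ~ A + B + A:B, data = fac,
                       permutations = 19, by = "terms")
  expect_equal(pt$pseudo_F[1:3], va$F[1:3], tolerance = 1e-8)
  expect_equal(pt$SS[1:4], va$SumOfSqs[1:4], tolerance = 1e-8)
})

test_that("exhaustive enumeration reproduces the brute-force permutation p", {
  set.seed(24)
  y <- c(0.3, 1.9, -0.6, 4.2, 5.0, 3.6)
  g <- factor(rep(c("a", "b"), each = 3))
  pt <- permanova(as.matrix(stats::dist(y)), data.frame(g = g), "g",
                  n_perm = 999)
  expect_true(attr(pt, "exhaustive"))
  expect_equal(pt$perms[1], 720L)

  # oracle: enumerate every relabelling, classical F each time
  f_obs <- classical_F(y, g)
  perms <- t(apply(expand.grid(rep(list(1:6), 6)), 1, as.integer))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6L), ]
  f_star <- apply(perms, 1, function(p) classical_F(y[p], g))
  p_exact <- mean(f_star >= f_obs - 1e-8)
  expect_equal(pt$p_perm[1], p_exact, tolerance = 1e-12)
})

test_that("SS decomposition, determinism and degenerate inputs behave", {
  set.seed(25)
  fac <- expand.grid(A = c("x", "y", "z"), B = c("u", "v", "w"),
                     stringsAsFactors = FALSE)
  fac <- fac[rep(1:9, each = 2), ]
  m <- matrix(stats::runif(nrow(fac) * 6, 0, 10), nrow = nrow(fac))
  d <- bray_curtis(m)
  pt <- permanova(d, fac, c("A", "B", "A:B"), n_perm = 99, seed = 7)
  expect_equal(sum(pt$SS[1:4]), pt$SS[pt$term == "Total"], tolerance = 1e-8)

  pt2 <- permanova(d, fac, c("A", "B", "A:B"), n_perm = 99, seed = 7)
  expect_identical(pt$p_perm, pt2$p_perm)

  # all rows identical: undefined test, not p = 0
  same <- matrix(rep(c(1, 2, 3), 8), nrow = 8, byrow = TRUE)
  dd <- bray_curtis(same + 0)
  ptd <- permanova(dd, data.frame(g = factor(rep(1:2, each = 4))), "g",
                   n_perm = 19)
  expect_true(attr(ptd, "degenerate"))
  expect_true(is.na(ptd$pseudo_F[1]))
  expect_true(is.na(ptd$p_perm[1]))

  # residual df 0: the saturated term is refused
  one_per_cell <- fac[!duplicated(fac), ]
  m1 <- m[!duplicated(fac), ]
  expect_error(permanova(bray_curtis(m1), one_per_cell, c("A", "B", "A:B"),
                         n_perm = 9),
               "residual degrees of freedom")
})

test_that("permutation p is super-uniform under an exchangeable null", {
  set.seed(26)
  hits <- 0L
  n_sim <- 60
  for (i in seq_len(n_sim)) {
    y <- stats::rnorm(18)
    g <- factor(rep(1:3, each = 6))
    pt <- permanova(as.matrix(stats::dist(y)), data.frame(g = g), "g",
                    n_perm = 199, seed = 1000 + i)
    if (pt$p_perm[1] <= 0.05) hits <- hits + 1L
  }
  # binomial(60, <=0.055) stays well under this bound with high probability
  expect_lte(hits / n_sim, 0.15)
  expect_gte(hits / n_sim, 0)
})
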