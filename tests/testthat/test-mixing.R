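# mixing model: forward moments, source selection, sampler behaviour

test_that("mixture_moments applies concentration weighting exactly", {
  tf0 <- tef(mean_C = 0, sd_C = 0, mean_N = 0, sd_N = 0)
  src <- data.frame(name = c("s1", "s2"),
                    mu_C = c(10, 0), sd_C = c(0, 0),
                    mu_N = c(10, 0), sd_N = c(0, 0),
                    q_C = c(0.5, 0.1), q_N = c(0.2, 0.2), n = 5L)
  mom <- mixture_moments(c(0.5, 0.5), src, tf0)
  # carbon weight of source 1: 0.5*0.5 / (0.5*0.5 + 0.5*0.1) = 5/6
  expect_equal(mom$m_C, 10 * 5 / 6, tolerance = 1e-12)
  # nitrogen concentrations equal -> plain mixture
  expect_equal(mom$m_N, 5, tolerance = 1e-12)

  # equal concentrations reduce to the unweighted linear mixture + TEF
  tf <- tef()
  srcq <- separated_sources()
  srcq$q_C <- 0.45; srcq$q_N <- 0.09
  p <- c(0.2, 0.5, 0.3)
  mom2 <- mixture_moments(p, srcq, tf)
  expect_equal(mom2$m_C, sum(p * (srcq$mu_C + tf$mean_C)), tolerance = 1e-12)
  expect_equal(mom2$m_N, sum(p * (srcq$mu_N + tf$mean_N)), tolerance = 1e-12)
  expect_equal(mom2$s2_C, sum(p^2 * (srcq$sd_C^2 + tf$sd_C^2)), tolerance = 1e-12)
})

test_that("select_sources applies the per-species source sets and pooling", {
  set.seed(31)
  groups <- c("zooplankton", "profundal_invertebrates", "littoral_invertebrates",
              "benthic_invertebrates")
  iso <- do.call(rbind, lapply(groups, function(g)
    make_iso(g, d13C = stats::rnorm(6, -28), d15N = stats::rnorm(6, 5))))
  iso <- rbind(iso,
               make_iso("whitefish_prey", stats::rnorm(5, -29), stats::rnorm(5, 8.5)),
               make_iso("charr_prey", stats::rnorm(5, -29), stats::rnorm(5, 8.8)),
               make_iso("juvenile_trout_prey", stats::rnorm(5, -27), stats::rnorm(5, 9)))
  cfg <- analysis_config()
  tr <- select_sources("trout", iso, cfg)
  expect_setequal(tr$name, c("fish", "benthic_invertebrates", "zooplankton"))
  expect_equal(tr$n[tr$name == "fish"], 15L)   # pooled 5 + 5 + 5
  ch <- select_sources("charr", iso, cfg)
  expect_setequal(ch$name, c("profundal_invertebrates",
                             "littoral_invertebrates", "zooplankton"))
  expect_error(select_sources("pike", iso, cfg), "no source set")
  cfg2 <- cfg
  cfg2$source_sets$charr <- c("zooplankton", "mystery_prey")
  expect_error(select_sources("charr", iso, cfg2), "absent")
})

test_that("a consumer sitting on one TEF-corrected source is identified", {
  src <- separated_sources()
  src$sd_C <- 0.01; src$sd_N <- 0.01
  tf <- tef(sd_C = 0, sd_N = 0)
  cons <- data.frame(d13C = rep(src$mu_C[1] + tf$mean_C, 10),
                     d15N = rep(src$mu_N[1] + tf$mean_N, 10))
  fit <- suppressWarnings(fit_mixing_model(cons, src, tf, chains = 2,
                                           iterations = 4000, burn_in = 1000,
                                           seed = 2))
  expect_gt(mean(fit$draws[, 1]), 0.95)
})

test_that("identical sources give back the prior (symmetry)", {
  src <- separated_sources()[1:2, ]
  src$mu_C <- -27; src$mu_N <- 6; src$sd_C <- 1; src$sd_N <- 1
  src$q_C <- 0.45; src$q_N <- 0.09
  set.seed(33)
  cons <- data.frame(d13C = stats::rnorm(20, -26, 1.2),
                     d15N = stats::rnorm(20, 9.2, 1.2))
  fit <- suppressWarnings(fit_mixing_model(cons, src, chains = 2,
                                           iterations = 6000, burn_in = 1500,
                                           seed = 3))
  expect_gt(mean(fit$draws[, 1]), 0.45)
  expect_lt(mean(fit$draws[, 1]), 0.55)
})

test_that("draws live on the simplex and fits are reproducible by seed", {
  src <- separated_sources()
  cons <- draw_consumers(15, c(0.6, 0.3, 0.1), src, seed = 5)
  fit <- suppressWarnings(fit_mixing_model(cons, src, chains = 2,
                                           iterations = 2000, burn_in = 500,
                                           seed = 4))
  expect_true(all(fit$draws >= 0))
  expect_equal(unname(rowSums(fit$draws)), rep(1, nrow(fit$draws)),
               tolerance = 1e-9)
  fit2 <- suppressWarnings(fit_mixing_model(cons, src, chains = 2,
                                            iterations = 2000, burn_in = 500,
                                            seed = 4))
  expect_identical(fit$draws, fit2$draws)
  fit3 <- suppressWarnings(fit_mixing_model(cons, src, chains = 2,
                                            iterations = 2000, burn_in = 500,
                                            seed = 5))
  expect_false(identical(fit$draws, fit3$draws))
})

test_that("input contracts are enforced", {
  src <- separated_sources()
  cons <- draw_consumers(5, c(0.5, 0.3, 0.2), src, seed = 6)
  expect_error(fit_mixing_model(cons, src[1, , drop = FALSE]), "at least 2")
  src_na <- src; src_na$q_C[2] <- NA
  expect_error(fit_mixing_model(cons, src_na), "concentrations")
  expect_error(fit_mixing_model(cons, src, chains = 1), "chains")
})

test_that("summarize_posterior reports mean with ordered 5-95 percentiles", {
  fake <- structure(list(draws = matrix(rep(c(0.5, 0.3, 0.2), each = 100),
                                        ncol = 3,
                                        dimnames = list(NULL, c("a", "b", "c")))),
                    class = "mixing_posterior")
  s <- summarize_posterior(fake)
  expect_equal(s$mean, c(0.5, 0.3, 0.2))
  expect_equal(s$p5, s$mean)
  expect_equal(s$p95, s$mean)

  two <- structure(list(draws = rbind(c(1, 0, 0), c(0, 1, 0))),
                   class = "mixing_posterior")
  expect_equal(summarize_posterior(two)$mean, c(0.5, 0.5, 0))

  set.seed(34)
  rnd <- structure(list(draws = matrix(stats::runif(300), ncol = 3)),
                   class = "mixing_posterior")
  s2 <- summarize_posterior(rnd)
  expect_true(all(s2$p5 <= s2$p95))
  expect_error(summarize_posterior(structure(list(draws = matrix(0, 0, 3)),
                                             class = "mixing_posterior")),
               "empty")
})
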