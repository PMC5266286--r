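# %A_i = 100 * sum(F_i) / sum(F_t): pooled sums, not a mean of percentages

test_that("prey_abundance evaluates the pooled-sum formula", {
  fish <- rbind(
    make_fish("A", cats = c(benthic_invertebrates = 40, pleuston = 20)),
    make_fish("B", cats = c(cladoceran_zooplankton = 20)))
  pr <- prey_abundance(fish)
  expect_equal(unname(pr$proportions),
               c(0, 0.25, 0, 0.50, 0.25, 0))
  expect_equal(pr$n_fish, 2L)

  # empty stomachs contribute nothing
  with_empty <- rbind(fish, make_fish("C", cats = c()))
  expect_equal(prey_abundance(with_empty)$proportions, pr$proportions)
  expect_equal(prey_abundance(with_empty)$n_fish, 2L)

  # single fish, one category -> indicator profile
  one <- make_fish("D", cats = c(fish = 35))
  expect_equal(unname(prey_abundance(one)$proportions), c(0, 0, 0, 0, 0, 1))

  # all-empty is its own error, distinct from "no fish"
  expect_error(prey_abundance(make_fish("E", cats = c())), "all stomachs")
  expect_error(prey_abundance(fish[0, ]), "no fish")
})

test_that("pooled %A_i equals the fullness-weighted mean of per-fish compositions", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    fish <- do.call(rbind, lapply(seq_len(n), function(i) {
      cats <- stats::setNames(stats::runif(6, 0, 15), prey_categories())
      make_fish(paste0("F", i), cats = cats)
    }))
    pr <- prey_abundance(fish)
    ft <- fish$total_fullness
    per_fish <- as.matrix(fish[prey_categories()]) / ft
    weighted <- colSums(per_fish * (ft / sum(ft)))
    expect_equal(pr$proportions, weighted, tolerance = 1e-10)
    expect_equal(sum(pr$proportions), 1, tolerance = 1e-9)
  }
})

test_that("%A_i is invariant to common rescaling of all fullness values", {
  set.seed(8)
  fish <- do.call(rbind, lapply(1:5, function(i)
    make_fish(paste0("F", i),
              cats = stats::setNames(stats::runif(6, 0, 10), prey_categories()))))
  pr <- prey_abundance(fish)
  scaled <- fish
  sc <- 0.37
  scaled[c("total_fullness", prey_categories())] <-
    scaled[c("total_fullness", prey_categories())] * sc
  expect_equal(prey_abundance(scaled)$proportions, pr$proportions,
               tolerance = 1e-12)
})

test_that("empty_stomach_proportion computes percentages per group", {
  fish <- do.call(rbind, c(
    lapply(1:8, function(i) make_fish(paste0("N", i), cats = c(fish = 10))),
    lapply(1:2, function(i) make_fish(paste0("E", i), cats = c()))))
  expect_equal(unname(empty_stomach_proportion(fish)), 20)
  full <- fish[1:8, ]
  expect_equal(unname(empty_stomach_proportion(full)), 0)
  empty <- fish[9:10, ]
  expect_equal(unname(empty_stomach_proportion(empty)), 100)
})

test_that("cell_mean_matrix emits populated cells and reports omissions", {
  set.seed(9)
  fish <- do.call(rbind, lapply(seq_len(27 * 2), function(i) {
    d <- expand.grid(species = species_levels(), habitat = habitat_levels(),
                     month = month_levels(), stringsAsFactors = FALSE)[((i - 1) %% 27) + 1, ]
    make_fish(paste0("F", i), species = d$species, habitat = d$habitat,
              month = d$month,
              cats = stats::setNames(stats::runif(6, 1, 10), prey_categories()))
  }))
  m <- cell_mean_matrix(fish)
  expect_equal(nrow(m), 27L)
  expect_equal(nrow(attr(m, "omitted")), 0L)
  expect_equal(unname(rowSums(m)), rep(1, 27), tolerance = 1e-9)

  # drop one cell -> 26 rows plus an omission note
  drop <- !(fish$species == "trout" & fish$habitat == "pelagic" & fish$month == "June")
  m26 <- cell_mean_matrix(fish[drop, ])
  expect_equal(nrow(m26), 26L)
  om <- attr(m26, "omitted")
  expect_equal(om$reason, "no fish")
  expect_equal(om$species, "trout")

  # a two-fish cell equals prey_abundance of that pair
  pair <- fish[fish$species == "charr" & fish$habitat == "littoral" &
                 fish$month == "June", ]
  expect_equal(unname(m["charr.littoral.June", ]),
               unname(prey_abundance(pair)$proportions))
})
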