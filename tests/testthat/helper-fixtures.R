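# In-code fixtures shared across test files. Everything is built
# programmatically; no data files.

# one fish row; `cats` is a named vector over (a subset of) prey categories
make_fish <- function(id = "F1", species = "charr", habitat = "littoral",
                      month = "June", year = 2005L, tl = 20, wt = 100,
                      maturity = "unknown", gear = "survey", cats = c()) {
  row <- data.frame(fish_id = id, species = species, habitat = habitat,
                    month = month, year = year, total_length = tl,
                    weight = wt, maturity = maturity, gear_class = gear,
                    total_fullness = sum(cats), stringsAsFactors = FALSE)
  for (cat in prey_categories()) {
    row[[cat]] <- if (cat %in% names(cats)) unname(cats[cat]) else 0
  }
  row
}

make_fish_table <- function(...) do.call(rbind, list(...))

make_effort <- function(habitat = "littoral", month = "June", year = 2005L,
                        net_area = 100, nights = 1L, gear = "survey") {
  data.frame(habitat = habitat, month = month, year = year,
             net_area = net_area, nights = nights, gear_class = gear,
             stringsAsFactors = FALSE)
}

make_iso <- function(group, d13C, d15N, pct_C = 45, pct_N = 9, habitat = NA) {
  n <- max(length(d13C), length(d15N))
  data.frame(sample_id = paste0(group, "_", seq_len(n)), group = group,
             habitat = habitat, d13C = d13C, d15N = d15N,
             pct_C = pct_C, pct_N = pct_N, stringsAsFactors = FALSE)
}

# random point on the k-simplex
runif_simplex <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

# well-separated three-source table for mixing tests (means >= 3 combined
# SDs apart on each axis pair that separates them)
separated_sources <- function() {
  data.frame(name = c("A", "B", "C"),
             mu_C = c(-32, -26, -22), sd_C = c(1, 1, 1),
             mu_N = c(3, 7, 11), sd_N = c(1, 1, 1),
             q_C = c(0.50, 0.45, 0.40), q_N = c(0.10, 0.08, 0.12),
             n = 6L, stringsAsFactors = FALSE)
}

# consumers drawn from the exact forward model at proportions p
draw_consumers <- function(n, p, sources, tf = tef(), resid = 0.3, seed = 1) {
  set.seed(seed)
  mom <- mixture_moments(p, sources, tf)
  data.frame(d13C = stats::rnorm(n, mom$m_C, sqrt(mom$s2_C + resid^2)),
             d15N = stats::rnorm(n, mom$m_N, sqrt(mom$s2_N + resid^2)))
}

# classical one-way ANOVA F, used as an independent PERMANOVA oracle
classical_F <- function(y, g) {
  stats::anova(stats::lm(y ~ g))$`F value`[1]
}
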