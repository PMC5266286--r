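# CPUE and habitat-use metrics. CPUE is fish caught per 100 m^2 of net area
# per night; habitat-use profiles are CPUE shares over the three habitats and
# feed Schoener's index as the habitat-use proportions P_xi.

#' Catch per unit effort by species, habitat and month
#'
#' CPUE is the number of fish caught per 100 m^2 of net area per night.
#' Effort is accumulated per habitat/month stratum as
#' `sum(net_area / 100 * nights)` over survey-gear deployments; supplementary
#' gear (large-mesh single nets, trap nets) is excluded from both numerator
#' and denominator. Strata with recorded effort but no catch are emitted with
#' CPUE 0 so that downstream habitat-use profiles are well defined.
#'
#' @param fish A `fish_records` data.frame (see [validate_fish_records()]).
#' @param effort An `effort_records` data.frame.
#' @param species Species to tabulate (default: the canonical three).
#' @param pool_years If `TRUE` (default) effort and catches are pooled across
#'   years; otherwise one row per species x habitat x month x year.
#' @return A data.frame with columns `species`, `habitat`, `month`
#'   (and `year` when not pooling), `n_fish`, `effort` (100-m^2-nights) and
#'   `cpue`, one row per stratum with effort.
#' @export
compute_cpue <- function(fish, effort, species = species_levels(),
                         pool_years = TRUE) {
  fish <- validate_fish_records(as.data.frame(fish))
  effort <- validate_effort_records(as.data.frame(effort))
  fish <- fish[fish$gear_class == "survey", , drop = FALSE]
  effort <- effort[effort$gear_class == "survey", , drop = FALSE]
  if (nrow(effort) == 0L) stop("no survey-gear effort records")

  keys <- if (pool_years) c("habitat", "month") else c("habitat", "month", "year")
  eff_key <- do.call(paste, c(effort[keys], sep = "\r"))
  eff <- tapply(effort$net_area / 100 * effort$nights, eff_key, sum)
  eff_tab <- unique(effort[keys])
  eff_tab$effort <- as.numeric(eff[do.call(paste, c(eff_tab[keys], sep = "\r"))])

  if (nrow(fish)) {
    fish_key <- do.call(paste, c(fish[keys], sep = "\r"))
    missing_eff <- !(fish_key %in% do.call(paste, c(eff_tab[keys], sep = "\r")))
    if (any(missing_eff))
      stop("fish caught in stratum with no effort record: ",
           paste(unique(gsub("\r", "/", fish_key[missing_eff])), collapse = "; "))
  }

  grid <- merge(data.frame(species = species, stringsAsFactors = FALSE),
                eff_tab, by = NULL)
  gkey <- do.call(paste, c(grid[c("species", keys)], sep = "\r"))
  if (nrow(fish)) {
    fkey <- do.call(paste, c(fish[c("species", keys)], sep = "\r"))
    counts <- table(fkey)
    grid$n_fish <- as.integer(ifelse(gkey %in% names(counts), counts[gkey], 0L))
    grid$n_fish[is.na(grid$n_fish)] <- 0L
  } else grid$n_fish <- 0L
  grid$cpue <- grid$n_fish / grid$effort
  grid <- grid[order(match(grid$species, species_levels()),
                     match(grid$habitat, habitat_levels()),
                     match(grid$month, month_levels())), , drop = FALSE]
  rownames(grid) <- NULL
  class(grid) <- c("cpue_table", class(grid))
  grid
}

#' Habitat-use profile of a species in a month
#'
#' Normalizes a species' CPUE across habitats into proportions summing to 1,
#' the habitat-use proportions fed to Schoener's overlap index.
#'
#' @param cpue_cells A [compute_cpue()] result.
#' @param species,month The stratum to profile.
#' @return Named numeric vector of proportions over habitats (canonical
#'   order), summing to 1.
#' @export
habitat_use_profile <- function(cpue_cells, species, month) {
  sel <- cpue_cells$species == species & cpue_cells$month == month
  if (!any(sel)) stop("no CPUE cells for ", species, " in ", month)
  cells <- cpue_cells[sel, , drop = FALSE]
  p <- stats::setNames(rep(0, length(habitat_levels())), habitat_levels())
  p[cells$habitat] <- cells$cpue
  tot <- sum(p)
  if (tot <= 0) stop("all-zero CPUE for ", species, " in ", month,
                     ": habitat-use profile undefined")
  p / tot
}

#' Per-species size summaries
#'
#' @param fish A `fish_records` data.frame.
#' @return A data.frame per species: `n`, `mean_length`, `sd_length`,
#'   `min_length`, `max_length` (cm).
#' @export
summarize_sizes <- function(fish) {
  fish <- validate_fish_records(as.data.frame(fish))
  if (nrow(fish) == 0L) stop("no fish records")
  sp <- intersect(species_levels(), unique(fish$species))
  out <- do.call(rbind, lapply(sp, function(s) {
    L <- fish$total_length[fish$species == s]
    data.frame(species = s, n = length(L), mean_length = mean(L),
               sd_length = stats::sd(L), min_length = min(L),
               max_length = max(L), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-species share of total catch biomass
#'
#' @param fish A `fish_records` data.frame with weights.
#' @return Named numeric vector of fractions summing to 1.
#' @export
biomass_share <- function(fish) {
  fish <- validate_fish_records(as.data.frame(fish))
  if (nrow(fish) == 0L) stop("no fish records")
  w <- tapply(fish$weight, fish$species, sum)
  w <- w[intersect(species_levels(), names(w))]
  stats::setNames(as.numeric(w) / sum(w), names(w))
}
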