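# Domain vocabulary shared by every module: the three-species, three-habitat,
# three-month survey design and the six fixed prey categories.

#' Controlled vocabularies of the survey design
#'
#' The analysis is organised around a fixed factorial survey design:
#' three salmonid species, three lake habitats and three ice-free-season
#' sampling months, with stomach contents scored over exactly six prey
#' categories. These helpers return the canonical, ordered level sets used
#' throughout the package.
#'
#' @return A character vector of levels, in canonical order.
#' @name vocab
NULL

#' @rdname vocab
#' @export
species_levels <- function() c("charr", "whitefish", "trout")

#' @rdname vocab
#' @export
habitat_levels <- function() c("littoral", "profundal", "pelagic")

#' @rdname vocab
#' @export
month_levels <- function() c("June", "August", "October")

#' @rdname vocab
#' @export
prey_categories <- function() {
  c("copepod_zooplankton", "cladoceran_zooplankton", "benthic_cladoceran",
    "benthic_invertebrates", "pleuston", "fish")
}

#' @rdname vocab
#' @export
maturity_levels <- function() c("immature", "male", "female", "unknown")

#' @rdname vocab
#' @export
gear_levels <- function() c("survey", "supplementary")

# tolerance for the fullness-sum invariant
.FULLNESS_TOL <- 1e-9

#' Default prey-taxon mapping table
#'
#' Maps raw stomach-content taxon labels to the six fixed prey categories:
#' (i) copepod zooplankton, (ii) cladoceran zooplankton, (iii) benthic
#' cladocerans, (iv) benthic invertebrates, (v) pleuston (surface-film
#' insects and emerging pupae) and (vi) fish. The table is editable: users
#' working in other systems can extend it with additional taxa, as long as
#' every taxon maps to exactly one category.
#'
#' @return A data.frame with columns `taxon` and `category`.
#' @export
prey_taxon_mapping <- function() {
  m <- rbind(
    cbind(c("Cyclopoida", "Calanoida"), "copepod_zooplankton"),
    cbind(c("Bosmina", "Daphnia", "Holopedium", "Bythotrephes"),
          "cladoceran_zooplankton"),
    cbind(c("Chydoridae", "Eurycercus"), "benthic_cladoceran"),
    cbind(c("Ephemeroptera", "Trichoptera", "Plecoptera", "Odonata",
            "Coleoptera", "Chironomidae"), "benthic_invertebrates"),
    cbind(c("surface_insects", "emerging_pupae", "terrestrial_insects"),
          "pleuston"),
    cbind(c("whitefish_prey", "charr_prey", "trout_prey", "fish_unidentified"),
          "fish")
  )
  data.frame(taxon = m[, 1], category = m[, 2], stringsAsFactors = FALSE)
}

.check_mapping <- function(mapping) {
  stopifnot(is.data.frame(mapping), all(c("taxon", "category") %in% names(mapping)))
  if (anyDuplicated(mapping$taxon))
    stop("prey-taxon mapping assigns a taxon to more than one category: ",
         paste(unique(mapping$taxon[duplicated(mapping$taxon)]), collapse = ", "))
  bad <- setdiff(unique(mapping$category), prey_categories())
  if (length(bad))
    stop("prey-taxon mapping uses unknown categories: ", paste(bad, collapse = ", "))
  mapping
}

.check_levels <- function(x, levels, what, rows = NULL) {
  bad <- !(x %in% levels)
  if (any(bad)) {
    where <- if (is.null(rows)) which(bad) else rows[bad]
    stop(sprintf("unknown %s label(s) %s at row(s) %s; expected one of {%s}",
                 what,
                 paste(sQuote(unique(x[bad])), collapse = ", "),
                 paste(utils::head(where, 5L), collapse = ", "),
                 paste(levels, collapse = ", ")))
  }
  invisible(x)
}

#' Validate a table of fish records
#'
#' A fish record carries the capture context (species, habitat, month, year,
#' gear class), the size measurements, and a stomach-fullness composition:
#' a total fullness on a 0--100 percent scale plus per-category fullness
#' points over the six prey categories whose sum must equal the total.
#' An empty stomach is total fullness 0 with every category 0.
#'
#' Validation is total: every violated invariant raises an error naming the
#' offending row(s); rows are never silently dropped.
#'
#' @param fish A data.frame with columns `fish_id`, `species`, `habitat`,
#'   `month`, `year`, `total_length`, `weight`, `maturity`, `gear_class`,
#'   `total_fullness` and one numeric column per prey category.
#' @return The validated data.frame, with class `fish_records` prepended.
#' @export
validate_fish_records <- function(fish) {
  req <- c("fish_id", "species", "habitat", "month", "year", "total_length",
           "weight", "maturity", "gear_class", "total_fullness",
           prey_categories())
  miss <- setdiff(req, names(fish))
  if (length(miss)) stop("fish table is missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(fish)
  rows <- seq_len(n)
  .check_levels(fish$species, species_levels(), "species", rows)
  .check_levels(fish$habitat, habitat_levels(), "habitat", rows)
  .check_levels(fish$month, month_levels(), "month", rows)
  .check_levels(fish$maturity, maturity_levels(), "maturity", rows)
  .check_levels(fish$gear_class, gear_levels(), "gear_class", rows)

  catm <- as.matrix(fish[prey_categories()])
  storage.mode(catm) <- "double"
  if (any(!is.finite(catm)) || any(catm < 0))
    stop("non-finite or negative fullness values at row(s) ",
         paste(which(apply(!is.finite(catm) | catm < 0, 1, any)), collapse = ", "))
  tf <- as.numeric(fish$total_fullness)
  if (any(!is.finite(tf) | tf < 0 | tf > 100))
    stop("total_fullness outside [0, 100] at row(s) ",
         paste(which(!is.finite(tf) | tf < 0 | tf > 100), collapse = ", "))
  bad <- abs(rowSums(catm) - tf) > .FULLNESS_TOL
  if (any(bad))
    stop(sprintf("fullness categories do not sum to total_fullness at row(s) %s (e.g. row %d: categories sum %.6g, total %.6g)",
                 paste(utils::head(which(bad), 5L), collapse = ", "),
                 which(bad)[1L], rowSums(catm)[which(bad)[1L]], tf[which(bad)[1L]]))
  if (any(fish$total_length <= 0, na.rm = TRUE))
    stop("non-positive total_length at row(s) ",
         paste(which(fish$total_length <= 0), collapse = ", "))
  if (any(fish$weight <= 0, na.rm = TRUE))
    stop("non-positive weight at row(s) ",
         paste(which(fish$weight <= 0), collapse = ", "))
  class(fish) <- unique(c("fish_records", class(fish)))
  fish
}

#' Validate a table of gill-net effort records
#'
#' One row per net deployment stratum: habitat, month, year, total net area
#' in square metres, number of nights fished and the gear class. Effort
#' records with `gear_class = "supplementary"` (large-mesh single nets and
#' trap nets used only to obtain extra stomach and isotope samples) are kept
#' in the table but excluded from CPUE denominators.
#'
#' @param effort A data.frame with columns `habitat`, `month`, `year`,
#'   `net_area`, `nights`, `gear_class`.
#' @return The validated data.frame, class `effort_records`.
#' @export
validate_effort_records <- function(effort) {
  req <- c("habitat", "month", "year", "net_area", "nights", "gear_class")
  miss <- setdiff(req, names(effort))
  if (length(miss)) stop("effort table is missing column(s): ", paste(miss, collapse = ", "))
  .check_levels(effort$habitat, habitat_levels(), "habitat")
  .check_levels(effort$month, month_levels(), "month")
  .check_levels(effort$gear_class, gear_levels(), "gear_class")
  if (any(effort$net_area <= 0))
    stop("non-positive net_area at row(s) ", paste(which(effort$net_area <= 0), collapse = ", "))
  if (any(effort$nights < 1))
    stop("nights must be >= 1 at row(s) ", paste(which(effort$nights < 1), collapse = ", "))
  class(effort) <- unique(c("effort_records", class(effort)))
  effort
}

#' Validate a table of stable-isotope samples
#'
#' One row per measurement: a group label (a consumer species or a putative
#' dietary source name), optional habitat, the delta-13C and delta-15N values
#' in per mil, and the percent carbon and nitrogen by weight needed by the
#' concentration-dependent mixing model.
#'
#' @param iso A data.frame with columns `sample_id`, `group`, `d13C`, `d15N`,
#'   `pct_C`, `pct_N` and optionally `habitat`.
#' @return The validated data.frame, class `isotope_samples`.
#' @export
validate_isotope_samples <- function(iso) {
  req <- c("sample_id", "group", "d13C", "d15N", "pct_C", "pct_N")
  miss <- setdiff(req, names(iso))
  if (length(miss)) stop("isotope table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("d13C", "d15N", "pct_C", "pct_N")) {
    v <- iso[[col]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("non-numeric or non-finite ", col, " at row(s) ",
           paste(which(!is.finite(suppressWarnings(as.numeric(v)))), collapse = ", "))
  }
  badC <- iso$pct_C <= 0 | iso$pct_C > 100
  badN <- iso$pct_N <= 0 | iso$pct_N > 100
  if (any(badC | badN))
    stop("pct_C/pct_N outside (0, 100] at row(s) ",
         paste(which(badC | badN), collapse = ", "),
         " (elemental concentrations are required by the concentration-dependent mixing model)")
  if (!"habitat" %in% names(iso)) iso$habitat <- NA_character_
  class(iso) <- unique(c("isotope_samples", class(iso)))
  iso
}

#' Trophic enrichment factors (TEF)
#'
#' Per-trophic-step isotopic enrichment between diet and consumer muscle,
#' modelled as a mean and SD per isotope. Defaults are the fractionation
#' factors used for this lake food web: Delta-15N = 3.23 +/- 0.79 permil and
#' Delta-13C = 1.03 +/- 0.29 permil.
#'
#' @param mean_C,sd_C Carbon enrichment mean and SD (permil).
#' @param mean_N,sd_N Nitrogen enrichment mean and SD (permil).
#' @return A list with class `tef`.
#' @export
tef <- function(mean_C = 1.03, sd_C = 0.29, mean_N = 3.23, sd_N = 0.79) {
  if (sd_C < 0 || sd_N < 0) stop("TEF standard deviations must be >= 0")
  structure(list(mean_C = mean_C, sd_C = sd_C, mean_N = mean_N, sd_N = sd_N),
            class = "tef")
}

#' Analysis configuration
#'
#' Bundles the knobs shared across pipeline stages: the prey-taxon mapping,
#' TEFs, per-species source sets for the mixing model, MCMC and permutation
#' settings, the Schoener overlap significance threshold, and a single seed
#' from which all randomness (MCMC, permutations, simulation) flows.
#'
#' @param mapping Prey-taxon mapping data.frame (see [prey_taxon_mapping()]).
#' @param tef A [tef()] object.
#' @param source_sets Named list, consumer species -> character vector of
#'   source group names. Defaults to the study's source selection: trout use
#'   {fish, benthic invertebrates, zooplankton}; charr and whitefish use
#'   {profundal invertebrates, littoral invertebrates, zooplankton}.
#' @param source_pools Named list, pooled source name -> raw group labels
#'   pooled into it (the "fish" source pools small whitefish, charr and
#'   juvenile trout samples).
#' @param mcmc List with `chains` (>= 2), `iterations`, `burn_in`.
#' @param n_perm Number of permutations for PERMANOVA (default 999).
#' @param overlap_threshold Schoener alpha significance threshold
#'   (default 0.60, compared with `>=`).
#' @param seed Integer master seed.
#' @return A list with class `analysis_config`.
#' @export
analysis_config <- function(mapping = prey_taxon_mapping(),
                            tef = nichepart::tef(),
                            source_sets = list(
                              trout     = c("fish", "benthic_invertebrates", "zooplankton"),
                              charr     = c("profundal_invertebrates", "littoral_invertebrates", "zooplankton"),
                              whitefish = c("profundal_invertebrates", "littoral_invertebrates", "zooplankton")),
                            source_pools = list(
                              fish = c("whitefish_prey", "charr_prey", "juvenile_trout_prey")),
                            mcmc = list(chains = 2L, iterations = 10000L, burn_in = 2000L),
                            n_perm = 999L,
                            overlap_threshold = 0.60,
                            seed = 1L) {
  .check_mapping(mapping)
  if (!inherits(tef, "tef")) stop("tef must be a tef() object")
  if (n_perm < 1) stop("permutation count must be >= 1")
  if (overlap_threshold < 0 || overlap_threshold > 1)
    stop("overlap threshold must lie in [0, 1]")
  if (mcmc$chains < 2) stop("mcmc$chains must be >= 2")
  structure(list(mapping = mapping, tef = tef, source_sets = source_sets,
                 source_pools = source_pools, mcmc = mcmc, n_perm = as.integer(n_perm),
                 overlap_threshold = overlap_threshold, seed = as.integer(seed)),
            class = "analysis_config")
}
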