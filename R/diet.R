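# Volumetric diet composition. The percent prey abundance of category i for
# a group of fish is
#     %A_i = 100 * sum(F_i) / sum(F_t)
# with F_i the per-fish fullness of category i and F_t the per-fish total
# stomach fullness; empty stomachs contribute zero to both sums. Internally
# profiles live on [0, 1]; reports multiply by 100.

.diet_profile <- function(p, n_fish, group = list()) {
  structure(list(proportions = p, n_fish = n_fish, group = group),
            class = "diet_profile")
}

#' @export
print.diet_profile <- function(x, ...) {
  cat("Diet profile (%A_i), n =", x$n_fish, "non-empty stomachs\n")
  print(round(100 * x$proportions, 1))
  invisible(x)
}

#' Pooled-sum prey abundance of a group of fish
#'
#' Computes the volumetric diet composition of a group as the pooled-sum
#' ratio per category (not the mean of per-fish percentages): component i is
#' the summed fullness of category i across fish divided by the summed total
#' fullness. The result is equal to the fullness-weighted mean of per-fish
#' compositions, and is invariant to adding empty stomachs or rescaling all
#' fullness values by a common positive constant.
#'
#' @param records A `fish_records` data.frame (already subset to the group).
#' @param group Optional named list of labels stored with the profile.
#' @return A `diet_profile`: proportions over the six ordered prey
#'   categories summing to 1, plus `n_fish`, the count of non-empty stomachs.
#' @export
prey_abundance <- function(records, group = list()) {
  records <- validate_fish_records(as.data.frame(records))
  if (nrow(records) == 0L) stop("no fish in group")
  nonempty <- records$total_fullness > 0
  if (!any(nonempty))
    stop("all stomachs in group are empty: prey abundance undefined")
  catm <- as.matrix(records[prey_categories()])
  num <- colSums(catm)
  den <- sum(records$total_fullness)
  .diet_profile(num / den, sum(nonempty), group)
}

#' Percentage of empty stomachs per group
#'
#' @param records A `fish_records` data.frame.
#' @param by Grouping column name (default `"species"`).
#' @return Named numeric vector: 100 * (#empty) / (#fish) per group.
#' @export
empty_stomach_proportion <- function(records, by = "species") {
  records <- validate_fish_records(as.data.frame(records))
  if (nrow(records) == 0L) stop("no fish records")
  g <- records[[by]]
  out <- tapply(records$total_fullness == 0, g, function(e) 100 * mean(e))
  lev <- switch(by, species = species_levels(), habitat = habitat_levels(),
                month = month_levels(), sort(unique(g)))
  out <- out[intersect(lev, names(out))]
  stats::setNames(as.numeric(out), names(out))
}

#' Cell-mean diet-profile matrix
#'
#' One diet profile per populated species x habitat x month cell (at most
#' 27 for the full factorial design), computed with [prey_abundance()].
#' Cells with no catch, or whose stomachs are all empty, are omitted from
#' the matrix and listed in the `omitted` attribute — missingness is kept
#' explicit rather than zero-filled.
#'
#' @param records A `fish_records` data.frame.
#' @param percent If `TRUE` scale rows to percent (report parity); default
#'   proportions on \[0, 1\].
#' @return A numeric matrix (rows = populated cells, columns = the six prey
#'   categories) with a `cells` attribute (data.frame of species, habitat,
#'   month, n_fish) and an `omitted` attribute (data.frame of skipped cells
#'   and the reason).
#' @export
cell_mean_matrix <- function(records, percent = FALSE) {
  records <- validate_fish_records(as.data.frame(records))
  design <- expand.grid(month = month_levels(), habitat = habitat_levels(),
                        species = species_levels(), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)[, c("species", "habitat", "month")]
  rows <- list(); cells <- list(); omitted <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    sub <- records[records$species == d$species & records$habitat == d$habitat &
                     records$month == d$month, , drop = FALSE]
    if (nrow(sub) == 0L) {
      omitted[[length(omitted) + 1L]] <- cbind(d, reason = "no fish")
    } else if (!any(sub$total_fullness > 0)) {
      omitted[[length(omitted) + 1L]] <- cbind(d, reason = "all stomachs empty")
    } else {
      pr <- prey_abundance(sub, group = as.list(d))
      rows[[length(rows) + 1L]] <- pr$proportions
      cells[[length(cells) + 1L]] <- cbind(d, n_fish = pr$n_fish)
    }
  }
  if (!length(rows)) stop("no populated cells")
  m <- do.call(rbind, rows)
  if (percent) m <- 100 * m
  cellsdf <- do.call(rbind, cells); rownames(cellsdf) <- NULL
  rownames(m) <- paste(cellsdf$species, cellsdf$habitat, cellsdf$month, sep = ".")
  attr(m, "cells") <- cellsdf
  attr(m, "omitted") <- if (length(omitted)) {
    o <- do.call(rbind, omitted); rownames(o) <- NULL; o
  } else design[0, ]
  m
}
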