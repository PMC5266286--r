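# Schoener's proportional-similarity overlap:
#   alpha = 1 - 0.5 * sum_i |P_xi - P_yi|
# applied to diet (%A_i) or habitat-use (CPUE share) proportions. alpha runs
# from 0 (no overlap) to 1 (complete overlap); values >= 0.60 are flagged as
# biologically significant by the conventional threshold.

.SIMPLEX_TOL <- 1e-6

.as_props <- function(p, arg) {
  if (inherits(p, "diet_profile")) p <- p$proportions
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0))
    stop(arg, " must be a non-negative proportion vector")
  if (abs(sum(p) - 1) > .SIMPLEX_TOL)
    stop(arg, " does not sum to 1 (sum = ", format(sum(p)), ")")
  p
}

#' Schoener's overlap index
#'
#' @param p_x,p_y Proportion vectors of equal length (or `diet_profile`
#'   objects), each non-negative and summing to 1 within 1e-6.
#' @return alpha in \[0, 1\]: 1 - 0.5 * sum(|p_x - p_y|).
#' @export
schoener_alpha <- function(p_x, p_y) {
  x <- .as_props(p_x, "p_x"); y <- .as_props(p_y, "p_y")
  if (length(x) != length(y))
    stop("profiles have different lengths (", length(x), " vs ", length(y), ")")
  a <- 1 - 0.5 * sum(abs(x - y))
  min(max(a, 0), 1)
}

#' Pairwise Schoener overlap across strata
#'
#' Computes alpha for every requested species pair in every habitat x month
#' stratum where both species have a diet profile. Strata where either
#' member is missing are not errors: they are simply absent from the result
#' and rendered as `-` by [format_overlap_table()].
#'
#' @param profiles A [cell_mean_matrix()] result, or any numeric matrix of
#'   row-profiles with a `cells` attribute giving `species`, `habitat`,
#'   `month` per row.
#' @param pairs Optional 2-column character matrix of species pairs;
#'   defaults to all unordered pairs of the canonical species.
#' @param threshold Significance threshold on alpha (compared with `>=`).
#' @return A data.frame with class `overlap_results`: `species_x`,
#'   `species_y`, `habitat`, `month`, `alpha`, `significant`.
#' @export
overlap_matrix <- function(profiles, pairs = NULL, threshold = 0.60) {
  cells <- attr(profiles, "cells")
  if (is.null(cells)) stop("profiles must carry a 'cells' attribute")
  if (is.null(pairs)) {
    sp <- species_levels()
    pairs <- t(utils::combn(sp, 2L))
  }
  res <- list()
  for (h in habitat_levels()) for (m in month_levels()) {
    for (k in seq_len(nrow(pairs))) {
      ix <- which(cells$species == pairs[k, 1] & cells$habitat == h & cells$month == m)
      iy <- which(cells$species == pairs[k, 2] & cells$habitat == h & cells$month == m)
      if (length(ix) == 1L && length(iy) == 1L) {
        a <- schoener_alpha(profiles[ix, ] / sum(profiles[ix, ]),
                            profiles[iy, ] / sum(profiles[iy, ]))
        res[[length(res) + 1L]] <- data.frame(
          species_x = pairs[k, 1], species_y = pairs[k, 2],
          habitat = h, month = m, alpha = a,
          significant = a >= threshold, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(species_x = character(), species_y = character(),
               habitat = character(), month = character(),
               alpha = numeric(), significant = logical())
  class(out) <- c("overlap_results", class(out))
  out
}

#' Lay out overlap results like a printed species-pair x habitat x month table
#'
#' Rows are species pairs grouped by habitat; columns are months; alpha is
#' printed as whole percents (`round(100 * alpha)`); strata lacking a
#' comparison show `-`.
#'
#' @param overlaps An [overlap_matrix()] result.
#' @return A data.frame with columns `habitat`, `pair`, one column per month,
#'   and `significant_months` (comma-separated months with alpha >= threshold).
#' @export
format_overlap_table <- function(overlaps) {
  sp <- species_levels()
  pairs <- t(utils::combn(sp, 2L))
  rows <- list()
  for (h in habitat_levels()) for (k in seq_len(nrow(pairs))) {
    row <- list(habitat = h,
                pair = paste(pairs[k, 1], "vs", pairs[k, 2]))
    sig <- character()
    for (m in month_levels()) {
      hit <- overlaps$species_x == pairs[k, 1] & overlaps$species_y == pairs[k, 2] &
        overlaps$habitat == h & overlaps$month == m
      if (any(hit)) {
        row[[m]] <- as.character(round(100 * overlaps$alpha[hit][1]))
        if (overlaps$significant[hit][1]) sig <- c(sig, m)
      } else row[[m]] <- "-"
    }
    row$significant_months <- paste(sig, collapse = ",")
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-year similarity check before pooling samples
#'
#' For each group present in both years, computes Schoener's alpha between
#' the two yearly profiles. Pooling the years is recommended only if every
#' checked group overlaps at or above the threshold; groups present in only
#' one year are skipped with a note.
#'
#' @param profiles_by_year A list of two named lists (one per year), each
#'   mapping group labels to proportion vectors or `diet_profile`s.
#' @param threshold Overlap threshold (default 0.60, compared with `>=`).
#' @return A list with class `year_merge_decision`: `merge` (logical),
#'   `alphas` (named vector), `failures` (groups below threshold),
#'   `skipped` (groups present in only one year).
#' @export
year_merge_check <- function(profiles_by_year, threshold = 0.60) {
  if (length(profiles_by_year) != 2L)
    stop("profiles_by_year must hold exactly two years")
  y1 <- profiles_by_year[[1]]; y2 <- profiles_by_year[[2]]
  groups <- union(names(y1), names(y2))
  common <- intersect(names(y1), names(y2))
  skipped <- setdiff(groups, common)
  if (!length(common)) stop("no group present in both years")
  alphas <- vapply(common, function(g) schoener_alpha(y1[[g]], y2[[g]]), numeric(1))
  failures <- names(alphas)[alphas < threshold]
  structure(list(merge = length(failures) == 0L, alphas = alphas,
                 failures = failures, skipped = skipped,
                 threshold = threshold),
            class = "year_merge_decision")
}

#' @export
print.year_merge_decision <- function(x, ...) {
  cat("Between-year overlap check (threshold", x$threshold, "):",
      if (x$merge) "merge years" else "do NOT merge", "\n")
  print(round(x$alphas, 3))
  if (length(x$failures)) cat("below threshold:", paste(x$failures, collapse = ", "), "\n")
  if (length(x$skipped)) cat("skipped (single year):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
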