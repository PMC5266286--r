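# Tabular readers/writers. All input tables are UTF-8 delimited text with a
# header row and decimal points; the delimiter (comma or tab) is sniffed from
# the header line so both CSV and TSV dialects parse identically.

.sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com) "\t" else ","
}

.read_delim <- function(path) {
  utils::read.table(path, header = TRUE, sep = .sniff_delim(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    strip.white = TRUE, comment.char = "", quote = "\"")
}

#' Read a fish catch table
#'
#' Reads one row per captured fish. Stomach contents may be recorded either
#' directly in the six prey-category columns, or in raw taxon columns (e.g.
#' `Bosmina`, `Daphnia`) that are aggregated into categories through the
#' prey-taxon mapping; both column kinds may be mixed and are summed.
#' Columns that are neither metadata, categories nor mapped taxa raise an
#' "unmapped taxon column" error rather than being ignored.
#'
#' @param path Path to a CSV/TSV file.
#' @param mapping Prey-taxon mapping (default [prey_taxon_mapping()]).
#' @return A validated `fish_records` data.frame with exactly one numeric
#'   column per prey category.
#' @export
read_fish_table <- function(path, mapping = prey_taxon_mapping()) {
  .check_mapping(mapping)
  raw <- .read_delim(path)
  meta <- c("fish_id", "species", "habitat", "month", "year", "total_length",
            "weight", "maturity", "gear_class", "total_fullness")
  miss <- setdiff(meta, names(raw))
  if (length(miss)) stop("fish table ", path, " is missing column(s): ",
                         paste(miss, collapse = ", "))
  content_cols <- setdiff(names(raw), meta)
  unknown <- setdiff(content_cols, c(prey_categories(), mapping$taxon))
  if (length(unknown))
    stop("unmapped taxon column(s) in ", path, ": ",
         paste(unknown, collapse = ", "),
         "; add them to the prey-taxon mapping")
  cat_of <- c(stats::setNames(prey_categories(), prey_categories()),
              stats::setNames(mapping$category, mapping$taxon))
  agg <- matrix(0, nrow(raw), length(prey_categories()),
                dimnames = list(NULL, prey_categories()))
  for (col in content_cols) {
    v <- raw[[col]]
    if (!is.numeric(v))
      stop("non-numeric fullness column ", sQuote(col), " in ", path)
    v[is.na(v)] <- 0
    agg[, cat_of[[col]]] <- agg[, cat_of[[col]]] + v
  }
  fish <- cbind(raw[meta], as.data.frame(agg))
  validate_fish_records(fish)
}

#' Read a gill-net effort table
#'
#' @param path Path to a CSV/TSV file with columns `habitat`, `month`,
#'   `year`, `net_area` (m^2), `nights`, `gear_class`.
#' @return A validated `effort_records` data.frame.
#' @export
read_effort_table <- function(path) {
  validate_effort_records(.read_delim(path))
}

#' Read a stable-isotope sample table
#'
#' @param path Path to a CSV/TSV file with columns `sample_id`, `group`,
#'   `d13C`, `d15N`, `pct_C`, `pct_N` and optionally `habitat`.
#' @return A validated `isotope_samples` data.frame.
#' @export
read_isotope_table <- function(path) {
  raw <- .read_delim(path)
  for (col in intersect(c("d13C", "d15N", "pct_C", "pct_N"), names(raw))) {
    if (!is.numeric(raw[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))
      stop("non-numeric ", col, " at row(s) ", paste(bad, collapse = ", "),
           " of ", path)
    }
  }
  validate_isotope_samples(raw)
}

#' Write a stage result to disk
#'
#' Deterministic serialization of any tabular stage result as TSV or JSON.
#' Missing entries (e.g. strata where a species pair could not be compared)
#' are rendered as `-` in TSV, matching the dash convention of the printed
#' overlap tables.
#'
#' @param results A data.frame (or coercible object).
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "-")
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame with `-` entries restored to `NA`.
#' @export
read_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "-",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# -- structured logging -------------------------------------------------------

.log_state <- new.env(parent = emptyenv())
.log_state$level <- "info"
.LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the logging threshold
#' @param level One of "debug", "info", "warn", "error".
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  .log_state$level <- match.arg(level)
  invisible(.log_state$level)
}

log_msg <- function(level, ...) {
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[.log_state$level]])
    message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                    paste0(..., collapse = "")))
  invisible(NULL)
}
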