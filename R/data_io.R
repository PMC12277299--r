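#' Read a country-level anxiety dataset from CSV
#'
#' Reads a CSV with columns `country`, `group`, `anxiety_pct` and optionally
#' `se` (per-country standard error, percentage points) and `cluster`
#' (a published cluster label carried through for reference). Rows are
#' filtered to one activity group and validated: percentages must lie in
#' \[0, 100\], standard errors must be positive, country names must be
#' non-empty and unique within the group, and at least two countries must
#' remain. Row order is preserved; it defines leaf indexing for clustering.
#'
#' @param path Path to a CSV file (UTF-8, comma-separated, header row).
#' @param group Which activity group to keep: `"low"` or `"high"`.
#'
#' @return A tibble with columns `country`, `group`, `anxiety_pct` and,
#'   when present in the file, `se` and `cluster`.
#' @export
#' @examples
#' csv <- system.file("extdata", "table1_low.csv", package = "anxclust")
#' read_anxiety_csv(csv, group = "low")
read_anxiety_csv <- function(path, group = c("low", "high")) {
  group <- match.arg(group)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "anx_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("country", "group", "anxiety_pct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "anx_schema_error"
    )
  }
  keep <- intersect(c("country", "group", "anxiety_pct", "se", "cluster"), names(raw))
  data <- dplyr::filter(raw[keep], .data$group == !!group)
  validate_anxiety(data, group = group)
}

#' Write a country-level anxiety dataset to CSV
#'
#' Inverse of [read_anxiety_csv()]: writing a validated dataset and
#' re-reading it yields an identical tibble.
#'
#' @param data A tibble as returned by [read_anxiety_csv()] or
#'   [anx_fixture()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_anxiety_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Bundled table fixtures
#'
#' The three published country-level tables shipped with the package:
#' * `"table1_low"` — 56 countries, low-physical-activity pre-exam anxiety
#'   percentages (integers) with the published five-cluster labels.
#' * `"table2_high"` — the same 56 countries, high-physical-activity
#'   percentages with the published four-cluster labels.
#' * `"table3_paired"` — 15 countries plus an OECD-average aggregate row
#'   with group means and standard errors for both activity groups and the
#'   published chi-square / difference / Z columns (display pass-through:
#'   the raw per-country sample sizes behind the chi-square values are not
#'   public, so those columns are never recomputed).
#'
#' Percentages are the printed values: integers in tables 1-2, one decimal
#' in table 3.
#'
#' @param name One of `"table1_low"`, `"table2_high"`, `"table3_paired"`.
#' @return A tibble; for the first two, in [read_anxiety_csv()] layout with
#'   a `cluster` column carrying the published assignment.
#' @export
#' @examples
#' anx_fixture("table1_low")
anx_fixture <- function(name = c("table1_low", "table2_high", "table3_paired")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "anxclust")
  if (name == "table3_paired") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    grp <- if (name == "table1_low") "low" else "high"
    read_anxiety_csv(path, group = grp)
  }
}

# Validation shared by readers and the synthetic generator. `data` must
# already be restricted to a single activity group.
validate_anxiety <- function(data, group = NULL) {
  data <- tibble::as_tibble(data)
  data$country <- trimws(as.character(data$country))
  if (nrow(data) < 2) {
    abort("a dataset needs at least 2 countries", class = "anx_validation_error")
  }
  if (any(!nzchar(data$country))) {
    abort("empty country name", class = "anx_validation_error")
  }
  dup <- data$country[duplicated(data$country)]
  if (length(dup) > 0) {
    abort(
      paste0("duplicate country within group: ", paste(unique(dup), collapse = ", ")),
      class = "anx_validation_error"
    )
  }
  x <- data$anxiety_pct
  bad <- which(!is.finite(x) | x < 0 | x > 100)
  if (length(bad) > 0) {
    abort(
      paste0(
        "anxiety_pct outside [0, 100] or non-numeric for: ",
        paste(data$country[bad], collapse = ", ")
      ),
      class = "anx_validation_error"
    )
  }
  if ("se" %in% names(data)) {
    bad_se <- which(!is.na(data$se) & (!is.finite(data$se) | data$se <= 0))
    if (length(bad_se) > 0) {
      abort(
        paste0("se must be positive for: ", paste(data$country[bad_se], collapse = ", ")),
        class = "anx_validation_error"
      )
    }
  }
  if (!is.null(group) && !all(data$group == group)) {
    abort("rows from a different activity group", class = "anx_validation_error")
  }
  data
}
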