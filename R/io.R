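# CSV interchange for the two record schemas. Column names and order are part
# of the contract so files round-trip between sessions and tools.

district_cols <- c(
  "district_id", "stunting_pct", "severe_stunting_pct", "od_pct", "imr",
  "urban_pct", "literacy_pct", "literacy_female_pct", "mpce", "calories",
  "cereal_calories", "household_size", "population"
)

child_cols <- c("psu_id", "od_household", "haz")

#' Write / read the district-level CSV
#'
#' UTF-8, comma-separated, headered; columns in the canonical order
#' `district_id, stunting_pct, severe_stunting_pct, od_pct, imr, urban_pct,
#' literacy_pct, literacy_female_pct, mpce, calories, cereal_calories,
#' household_size, population`.
#'
#' @param data District tibble (from [simulate_districts()] or compatible).
#' @param path File path.
#' @return `write_district_csv()` returns `data` invisibly;
#'   `read_district_csv()` returns a validated tibble.
#' @export
write_district_csv <- function(data, path) {
  check_columns(data, district_cols, "district data")
  readr::write_csv(data[district_cols], path)
  invisible(data)
}

#' @rdname write_district_csv
#' @export
read_district_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(out, district_cols, "district CSV")
  validate_districts(out)
  out
}

#' @rdname write_district_csv
#' @export
write_child_csv <- function(data, path) {
  check_columns(data, child_cols, "child data")
  readr::write_csv(data[child_cols], path)
  invisible(data)
}

#' @rdname write_district_csv
#' @export
read_child_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(out, child_cols, "child CSV")
  if (!all(out$od_household %in% c(0L, 1L))) {
    abort("`od_household` must be 0/1.", class = "sanistunt_data_error")
  }
  out
}

# invariant checks on a district table; errors on violation
validate_districts <- function(data) {
  pct_cols <- c(
    "stunting_pct", "severe_stunting_pct", "od_pct", "urban_pct",
    "literacy_pct", "literacy_female_pct"
  )
  for (col in pct_cols) {
    v <- data[[col]]
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      abort(sprintf("`%s` outside [0, 100].", col), class = "sanistunt_data_error")
    }
  }
  if (any(data$od_pct <= 0, na.rm = TRUE)) {
    abort("`od_pct` must be strictly positive (its log is taken).",
      class = "sanistunt_data_error"
    )
  }
  if (any(data$severe_stunting_pct > data$stunting_pct + 1e-9, na.rm = TRUE)) {
    abort("`severe_stunting_pct` exceeds `stunting_pct`.",
      class = "sanistunt_data_error"
    )
  }
  if (any(data$cereal_calories > data$calories + 1e-9, na.rm = TRUE)) {
    abort("`cereal_calories` exceeds `calories`.", class = "sanistunt_data_error")
  }
  invisible(data)
}
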