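#' Read a gridded daily temperature CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `cell_id,date,tmean_c` (ISO-8601 dates, "." decimal); an optional cells
#' file carries `cell_id` with optional `elevation_m` and `area_km2`.
#'
#' @param path Path to the grid CSV.
#' @param cells_path Optional path to the cell-metadata CSV.
#' @return A validated grid tibble with its `"cells"` attribute; errors on
#'   duplicated (cell, date) rows (naming the row), malformed dates or
#'   non-numeric temperatures.
#' @export
read_grid_csv <- function(path, cells_path = NULL) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(c("cell_id", "date", "tmean_c"), header)
  if (length(missing_cols) > 0) {
    abort(paste0("'", path, "' lacks required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      cell_id = readr::col_character(),
      date = readr::col_character(),
      tmean_c = readr::col_double()
    )
  )
  if (anyNA(raw$tmean_c)) {
    abort(paste0("Non-numeric temperature in '", path, "' (row ",
                 which(is.na(raw$tmean_c))[1], ")."))
  }
  cells <- NULL
  if (!is.null(cells_path)) {
    cells <- readr::read_csv(cells_path, col_types = readr::cols(
      cell_id = readr::col_character(), .default = readr::col_double()
    ))
  }
  validate_grid(raw, cells)
}

#' Write a grid (and optionally its cell metadata) to CSV
#'
#' @param grid A validated grid tibble.
#' @param path Output path for the daily records.
#' @param cells_path Optional output path for the cell metadata.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path, cells_path = NULL) {
  grid <- validate_grid(grid)
  readr::write_csv(grid[, c("cell_id", "date", "tmean_c")], path)
  if (!is.null(cells_path)) {
    readr::write_csv(grid_cells(grid), cells_path)
  }
  invisible(path)
}

#' Read an annual population monitoring CSV
#'
#' Expects `year` plus a density column (`density` or `density_per_h`,
#' individuals per observer-hour) and optional `species` / `region`
#' columns.
#'
#' @param path Path to the CSV.
#' @return Tibble ready for [growth_rates()].
#' @export
read_population_csv <- function(path) {
  pop <- readr::read_csv(path, show_col_types = FALSE)
  if (!"year" %in% names(pop)) {
    abort(paste0("'", path, "' lacks a `year` column."))
  }
  if (!any(c("density", "density_per_h") %in% names(pop))) {
    abort(paste0("'", path, "' lacks a `density` (or `density_per_h`) column."))
  }
  pop
}

#' Read / write an annual temperature-index CSV
#'
#' The on-disk form is `year,temp_c[,temp_ma_c]`.
#'
#' @param path Path to the CSV.
#' @return Tibble with `year`, `temp_c` and `temp_ma_c` when present.
#' @export
read_index_csv <- function(path) {
  idx <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("year", "temp_c") %in% names(idx))) {
    abort(paste0("'", path, "' must have columns `year` and `temp_c`."))
  }
  check_annual_series(idx, "temp_c", arg = path)
  idx
}

#' @rdname read_index_csv
#' @param index Index tibble to write.
#' @export
write_index_csv <- function(index, path) {
  readr::write_csv(index, path)
  invisible(path)
}
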