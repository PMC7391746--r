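#' Validate a daily temperature grid
#'
#' A temperature grid is a long tibble with one row per cell and day:
#' columns `cell_id` (character), `date` (`Date` or ISO-8601 string) and
#' `tmean_c` (daily mean temperature, degrees Celsius). Cell metadata
#' (`cell_id`, `elevation_m`, `area_km2`) travels alongside, either as the
#' `cells` argument or in the `"cells"` attribute of the grid; cells absent
#' from the metadata table default to an area of exactly 1 km2, matching
#' the ~1-km2 agro-meteorological grid the format emulates.
#'
#' @param grid Data frame of daily records (`cell_id`, `date`, `tmean_c`).
#' @param cells Optional data frame of cell metadata with column `cell_id`
#'   and optional `elevation_m`, `area_km2`.
#' @return The grid as a tibble with a validated `"cells"` attribute.
#'   Errors on duplicated (cell, date) pairs, unparseable dates, non-finite
#'   temperatures, records referencing unknown cells, or an empty grid.
#' @export
#' @examples
#' g <- tibble::tibble(
#'   cell_id = "c1",
#'   date = as.Date("2000-07-01") + 0:61,
#'   tmean_c = 24 + sin(0:61 / 10)
#' )
#' validate_grid(g)
validate_grid <- function(grid, cells = NULL) {
  if (!is.data.frame(grid)) {
    abort("`grid` must be a data frame of daily temperature records.")
  }
  needed <- c("cell_id", "date", "tmean_c")
  missing_cols <- setdiff(needed, names(grid))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`grid` is missing required column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) {
    abort("`grid` has no records; an empty grid cannot be summarised.")
  }
  grid$cell_id <- as.character(grid$cell_id)
  if (!inherits(grid$date, "Date")) {
    parsed <- as.Date(as.character(grid$date), format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      bad <- which(is.na(parsed))[1]
      abort(paste0(
        "Malformed date in `grid` row ", bad, ": '", grid$date[bad],
        "' is not an ISO-8601 (YYYY-MM-DD) date."
      ))
    }
    grid$date <- parsed
  }
  if (anyNA(grid$date)) {
    abort("`grid$date` contains missing values.")
  }
  if (!is.numeric(grid$tmean_c) || !all(is.finite(grid$tmean_c))) {
    abort("`grid$tmean_c` must be finite numeric daily mean temperatures.")
  }
  dup <- duplicated(grid[, c("cell_id", "date")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(paste0(
      "Duplicate daily record for cell '", grid$cell_id[i], "' on ",
      format(grid$date[i]), " (row ", i, "); each (cell, date) pair ",
      "may appear at most once."
    ))
  }

  cells <- cells %||% attr(grid, "cells", exact = TRUE)
  if (is.null(cells)) {
    cells <- tibble::tibble(
      cell_id = sort(unique(grid$cell_id)),
      elevation_m = NA_real_,
      area_km2 = 1
    )
  } else {
    if (!is.data.frame(cells) || !"cell_id" %in% names(cells)) {
      abort("`cells` must be a data frame with a `cell_id` column.")
    }
    cells <- tibble::as_tibble(cells)
    cells$cell_id <- as.character(cells$cell_id)
    if (anyDuplicated(cells$cell_id)) {
      abort("`cells$cell_id` must be unique.")
    }
    if (!"elevation_m" %in% names(cells)) cells$elevation_m <- NA_real_
    if (!"area_km2" %in% names(cells)) cells$area_km2 <- 1
    cells$area_km2[is.na(cells$area_km2)] <- 1
    if (any(cells$area_km2 <= 0)) {
      abort("`cells$area_km2` must be positive.")
    }
    unknown <- setdiff(unique(grid$cell_id), cells$cell_id)
    if (length(unknown) > 0) {
      abort(paste0(
        "Grid records reference cell(s) absent from `cells`: ",
        paste(head(unknown, 5), collapse = ", "), "."
      ))
    }
    cells <- cells[, c("cell_id", "elevation_m", "area_km2")]
  }
  attr(grid, "cells") <- cells
  grid
}

#' Cell metadata of a temperature grid
#'
#' @param grid A validated temperature grid (see [validate_grid()]).
#' @return Tibble with `cell_id`, `elevation_m`, `area_km2`.
#' @export
grid_cells <- function(grid) {
  cells <- attr(grid, "cells", exact = TRUE)
  if (is.null(cells)) {
    cells <- attr(validate_grid(grid), "cells", exact = TRUE)
  }
  cells
}

# July-August records with a `year` column, after completeness checks:
# every requested (cell, year) must have at least one summer record.
summer_records <- function(grid, years = NULL, cells = NULL) {
  grid <- validate_grid(grid, cells)
  cells <- grid_cells(grid)
  month <- as.integer(format(grid$date, "%m"))
  summer <- grid[month %in% c(7L, 8L), ]
  if (nrow(summer) == 0) {
    abort("`grid` contains no July-August records.")
  }
  summer$year <- as.integer(format(summer$date, "%Y"))
  if (is.null(years)) {
    years <- sort(unique(summer$year))
  }
  years <- as.integer(years)
  if (length(years) == 0) abort("`years` is empty.")
  if (length(years) > 1 && !all(diff(sort(years)) == 1L)) {
    abort("`years` must be a contiguous run of calendar years.")
  }
  have <- dplyr::distinct(summer, .data$cell_id, .data$year)
  need <- tidyr::expand_grid(cell_id = cells$cell_id, year = years)
  miss <- dplyr::anti_join(need, have, by = c("cell_id", "year"))
  if (nrow(miss) > 0) {
    abort(paste0(
      "Missing July-August data for ",
      paste(sprintf("cell '%s' in %d", head(miss$cell_id, 5),
                    head(miss$year, 5)), collapse = "; "),
      if (nrow(miss) > 5) sprintf(" (and %d more)", nrow(miss) - 5), "."
    ))
  }
  summer <- summer[summer$year %in% years, ]
  attr(summer, "cells") <- cells
  summer
}

# deterministic per-component sub-seed so that, at a fixed user seed,
# drawing more numbers for one component leaves the others untouched
sub_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  offset <- sum(codes * seq_along(codes))
  (abs(as.integer(seed)) + offset * 1009L) %% 2147483647L
}
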