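#' Dissect fire perimeters into cohorts
#'
#' Overlays all fire rectangles on the cell grid at a fine raster resolution
#' and groups pixels by their full fire history: every distinct
#' (cell, set-of-fires) combination becomes one cohort with the area fraction
#' of its cell that it occupies. Pixels never burned form the unburned
#' remainder cohort of each cell; partially overlapping fires from different
#' years produce multi-fire (reburn) cohorts. Fractions within a cell sum to
#' one by construction; the rasterization error is bounded by the pixel size
#' and checked against a brute-force counting oracle in the tests.
#'
#' @param config a [synth_config()] describing the grid.
#' @param fires fire tibble (from [gen_fire_history()], ideally already
#'   carrying severity columns via [gap_fill()] + [severity_from_dnbr()]).
#' @param res_km raster pixel edge, km (default 1).
#' @return A tibble of cohorts: `cell`, `cohort_id`, `frac`, and `fires`, a
#'   list-column holding each cohort's fire rows ordered by year (zero rows
#'   for the unburned remainder).
#' @export
build_cohorts <- function(config, fires, res_km = 1) {
  xmax <- config$nx * config$cell_km
  ymax <- config$ny * config$cell_km
  if (nrow(fires) > 0 &&
      (any(fires$x0 < -1e-9) || any(fires$x1 > xmax + 1e-9) ||
       any(fires$y0 < -1e-9) || any(fires$y1 > ymax + 1e-9))) {
    abort("fire perimeter outside the grid extent")
  }
  px <- seq(res_km / 2, xmax, by = res_km)
  py <- seq(res_km / 2, ymax, by = res_km)
  pix <- tidyr::expand_grid(x = px, y = py) %>%
    mutate(cell = cell_index(.data$x, .data$y, config))
  key <- rep("", nrow(pix))
  if (nrow(fires) > 0) {
    ord <- order(fires$year, fires$fire_id)
    for (i in ord) {
      hit <- pix$x >= fires$x0[i] & pix$x < fires$x1[i] &
        pix$y >= fires$y0[i] & pix$y < fires$y1[i]
      key[hit] <- paste(key[hit], fires$fire_id[i])
    }
  }
  pix$key <- key
  cohorts <- pix %>%
    dplyr::count(.data$cell, .data$key) %>%
    group_by(.data$cell) %>%
    mutate(frac = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    arrange(.data$cell, desc(.data$key == ""), .data$key) %>%
    mutate(cohort_id = dplyr::row_number())
  fires_of <- function(key) {
    ids <- as.integer(strsplit(trimws(key), " ")[[1]])
    out <- fires[match(ids, fires$fire_id), , drop = FALSE]
    if (length(ids) == 0L || anyNA(ids)) out <- fires[0, , drop = FALSE]
    arrange(out, .data$year)
  }
  cohorts %>%
    mutate(fires = purrr::map(.data$key, fires_of)) %>%
    select("cell", "cohort_id", "frac", "fires")
}

# cells numbered row-major from the (0,0) corner
cell_index <- function(x, y, config) {
  cx <- pmin(config$nx - 1L, floor(x / config$cell_km))
  cy <- pmin(config$ny - 1L, floor(y / config$cell_km))
  as.integer(cy * config$nx + cx + 1L)
}
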