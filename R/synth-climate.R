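#' Generate monthly climate forcing
#'
#' Builds a monthly series of air temperature (deg C), precipitation (mm),
#' vapor pressure (hPa) and cloudiness (percent) for every grid cell, plus an
#' annual atmospheric CO2 column (ppm). Each variable follows a sinusoidal
#' seasonal cycle peaking in July with additive Gaussian interannual noise
#' (one draw per cell-year-month); CO2 rises linearly. Deterministic under a
#' fixed `config$seed`: the climate stream is split from the master seed, so
#' the same config always yields the same forcing.
#'
#' @param config a [synth_config()].
#' @return A tibble with one row per (cell, year, month) and columns
#'   `cell`, `year`, `month`, `tair`, `prec`, `vapr`, `cloud`, `co2`.
#'   Precipitation and cloudiness are floored at 0 (cloud capped at 100).
#' @examples
#' clim <- gen_climate(synth_config(nx = 1, ny = 1, seed = 7))
#' @export
gen_climate <- function(config) {
  validate_synth_config(config)
  years <- config$years
  n_cell <- config$nx * config$ny
  grid <- tidyr::expand_grid(
    cell = seq_len(n_cell),
    year = years,
    month = 1:12
  )
  # seasonal phase: peak in July (month 7)
  phase <- cos(2 * pi * (grid$month - 7) / 12)
  n <- nrow(grid)
  withr::with_seed(derive_seed(config$seed, "climate"), {
    draw <- function(v) {
      v$mean + v$amp * phase + rnorm(n, 0, v$sd)
    }
    out <- grid %>%
      mutate(
        tair  = draw(config$climate$tair),
        prec  = pmax(0, draw(config$climate$prec)),
        vapr  = pmax(0, draw(config$climate$vapr)),
        cloud = pmin(100, pmax(0, draw(config$climate$cloud)))
      )
  })
  co2 <- tibble(
    year = years,
    co2 = config$co2_start + config$co2_trend * (years - years[1])
  )
  left_join(out, co2, by = "year")
}

#' Mean-seasonal climatology from a forcing table
#'
#' Averages a monthly forcing over years, per cell and month, producing the
#' repeating-year climatology used for model spin-up. CO2 is held at the
#' first-year value.
#'
#' @param forcing a forcing tibble from [gen_climate()].
#' @return A tibble with one row per (cell, month).
#' @export
climatology <- function(forcing) {
  co2_0 <- forcing$co2[which.min(forcing$year)][1]
  forcing %>%
    group_by(.data$cell, .data$month) %>%
    summarise(across(all_of(c("tair", "prec", "vapr", "cloud")), mean),
              .groups = "drop") %>%
    mutate(co2 = co2_0)
}
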