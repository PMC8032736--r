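#' Spin a cohort up to equilibrium under a repeating climatology
#'
#' Runs the monthly kernel over the mean-seasonal climatology for `years`
#' repeated years, bringing the pools to (near) steady state before the
#' transient simulation. The residual drift — the last year's absolute change
#' in total carbon relative to the stock — is attached as attribute `"drift"`
#' for diagnostics.
#'
#' @param state0 a [cohort_state()].
#' @param clim_cell climatology for one cell: 12 rows with `month`, `tair`,
#'   `prec`, `co2` (see [climatology()]).
#' @param params an [ecosys_params()].
#' @param years number of spin-up years (default 120).
#' @return The spun-up [cohort_state()] with attribute `drift`
#'   (fraction of total C per year).
#' @export
spinup <- function(state0, clim_cell, params, years = 120) {
  stopifnot(nrow(clim_cell) == 12L)
  clim_cell <- arrange(clim_cell, .data$month)
  rows <- lapply(seq_len(12), function(i) clim_cell[i, ])
  st <- state0
  c0 <- st$cveg + st$csoil
  prev_total <- c0
  drift <- NA_real_
  for (yr in seq_len(years)) {
    for (m in seq_len(12)) st <- step_month(st, rows[[m]], params)$state
    total <- st$cveg + st$csoil
    if (total > 10 * max(c0, 1)) {
      abort("spin-up diverged: total C exceeded 10x its initial value")
    }
    drift <- abs(total - prev_total) / total
    prev_total <- total
  }
  attr(st, "drift") <- drift
  st
}

#' Run one cohort through a transient period, with optional fires
#'
#' Steps the cohort monthly through the forcing years. Fires listed for the
#' cohort are applied at the start of July of their year (boreal fires peak in
#' mid-summer); after a fire the foliage and moss follow their recovery
#' curves ([foliage_recovery()], [moss_recovery()]) driven by
#' time-since-fire, and the direct emissions are booked to the fire year.
#'
#' @param state a spun-up [cohort_state()].
#' @param forcing_cell monthly forcing rows for one cell, covering contiguous
#'   years (columns `year`, `month`, `tair`, `prec`, `co2`).
#' @param params an [ecosys_params()].
#' @param fires `NULL`, or a tibble of this cohort's fires: `year`,
#'   `soil_frac`, `canopy_frac` (strictly increasing years).
#' @return A tibble with one row per year: annual sums `npp`, `rh`, `nep`,
#'   `nmin`, direct emissions `emis_veg`, `emis_soil`, `emis_total`,
#'   end-of-year stocks `cveg`, `csoil`, annual mean diagnostics `moisture`,
#'   `tsoil`, and `tsf` (years since fire at year end).
#' @export
run_cohort <- function(state, forcing_cell, params, fires = NULL) {
  forcing_cell <- arrange(forcing_cell, .data$year, .data$month)
  years <- unique(forcing_cell$year)
  if (!all(forcing_cell$month == rep(1:12, length(years)))) {
    abort("forcing must cover whole years, months 1-12")
  }
  if (!is.null(fires) && nrow(fires) > 1 &&
      any(diff(fires$year) <= 0)) {
    abort("fire years must be strictly increasing within a cohort")
  }
  ny <- length(years)
  out <- matrix(0, ny, 12,
                dimnames = list(NULL, c(
                  "npp", "rh", "nep", "nmin", "emis_veg", "emis_soil",
                  "emis_total", "cveg", "csoil", "moisture", "tsoil", "tsf"
                )))
  rows <- lapply(seq_len(nrow(forcing_cell)),
                 function(i) forcing_cell[i, ])
  st <- state
  row_i <- 0L
  for (yi in seq_len(ny)) {
    yr <- years[yi]
    acc <- c(npp = 0, rh = 0, nmin = 0, emis_veg = 0, emis_soil = 0,
             moisture = 0, tsoil = 0)
    for (m in 1:12) {
      row_i <- row_i + 1L
      if (!is.null(fires) && m == 7L && yr %in% fires$year) {
        burned <- apply_fire(st, fires[fires$year == yr, , drop = FALSE],
                             params)
        st <- burned$state
        acc["emis_veg"] <- acc["emis_veg"] + burned$emission$emis_veg
        acc["emis_soil"] <- acc["emis_soil"] + burned$emission$emis_soil
      }
      if (is.finite(st$tsf)) {
        st$fol <- foliage_recovery(st$tsf, st, params)
        st$moss <- moss_recovery(st$tsf, st, params)
      }
      stepped <- step_month(st, rows[[row_i]], params)
      st <- stepped$state
      acc["npp"] <- acc["npp"] + stepped$flux$npp
      acc["rh"] <- acc["rh"] + stepped$flux$rh
      acc["nmin"] <- acc["nmin"] + stepped$flux$nmin
      acc["moisture"] <- acc["moisture"] + st$moisture
      acc["tsoil"] <- acc["tsoil"] + st$tsoil
      if (is.finite(st$tsf)) st$tsf <- st$tsf + 1 / 12
    }
    out[yi, ] <- c(acc["npp"], acc["rh"], acc["npp"] - acc["rh"],
                   acc["nmin"], acc["emis_veg"], acc["emis_soil"],
                   acc["emis_veg"] + acc["emis_soil"],
                   st$cveg, st$csoil,
                   acc["moisture"] / 12, acc["tsoil"] / 12, st$tsf)
  }
  as_tibble(as.data.frame(out)) %>%
    mutate(year = years, .before = 1)
}
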