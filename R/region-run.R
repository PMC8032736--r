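#' Run the regional fire or no-fire scenario
#'
#' For each cell: build the mean-seasonal climatology, spin the default stand
#' up for `spinup_years` (the spun-up state is shared by all cohorts of the
#' cell and by both scenarios), then run every cohort of the cell through the
#' transient years. With `with_fire = FALSE` all fire events are ignored but
#' the run is otherwise identical, giving the paired counterfactual. Cohorts
#' are independent, so results do not depend on evaluation order.
#'
#' @param cohorts cohort tibble from [build_cohorts()]; each cohort's fires
#'   must carry `soil_frac` and `canopy_frac` (run [severity_from_dnbr()]
#'   upstream) when `with_fire = TRUE`.
#' @param forcing monthly forcing tibble from [gen_climate()].
#' @param params an [ecosys_params()].
#' @param with_fire logical: apply the cohorts' fire events?
#' @param spinup_years spin-up length (default 120).
#' @param state0 initial pre-spin-up state (default [cohort_state()]).
#' @return A tibble of per-cohort annual series: `cell`, `cohort_id`, `frac`
#'   plus the [run_cohort()] columns.
#' @export
run_scenario <- function(cohorts, forcing, params = ecosys_params(),
                         with_fire = TRUE, spinup_years = 120,
                         state0 = cohort_state(params = params)) {
  cells <- sort(unique(cohorts$cell))
  if (!all(cells %in% unique(forcing$cell))) {
    abort("forcing does not cover every cohort cell")
  }
  clim <- climatology(forcing)
  purrr::map_dfr(cells, function(cl) {
    clim_cell <- filter(clim, .data$cell == cl)
    force_cell <- filter(forcing, .data$cell == cl)
    st0 <- spinup(state0, clim_cell, params, years = spinup_years)
    ch <- cohorts[cohorts$cell == cl, ]
    purrr::map_dfr(seq_len(nrow(ch)), function(i) {
      fires <- if (with_fire) ch$fires[[i]] else NULL
      if (!is.null(fires) && nrow(fires) == 0L) fires <- NULL
      if (!is.null(fires) &&
          !all(c("soil_frac", "canopy_frac") %in% names(fires))) {
        abort("cohort fires lack combustion fractions; run severity_from_dnbr() first")
      }
      run_cohort(st0, force_cell, params, fires) %>%
        mutate(cell = cl, cohort_id = ch$cohort_id[i], frac = ch$frac[i],
               .before = 1)
    })
  })
}
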