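#' Fire-regime summary: annual counts, area, and severity trend
#'
#' Summarises a fire record into per-year fire counts, burned area, and the
#' area-weighted mean dNBR, and fits an ordinary least-squares trend of the
#' annual area-weighted dNBR against year.
#'
#' @param fires fire tibble (`year`, `area_km2`, `dnbr`); fires with missing
#'   dNBR are excluded from the severity average (gap-fill first to keep
#'   them).
#' @return An object of class `"fire_regime"`: a list with `annual` (tibble:
#'   `year`, `n_fires`, `area_km2`, `mean_dnbr`) and `trend` (the `lm` fit of
#'   `mean_dnbr ~ year`). Has [tidy()] and [glance()] methods.
#' @export
fire_regime_summary <- function(fires) {
  if (nrow(fires) == 0L) abort("empty fire record")
  annual <- fires %>%
    group_by(.data$year) %>%
    summarise(
      n_fires = dplyr::n(),
      mean_dnbr = stats::weighted.mean(.data$dnbr, .data$area_km2,
                                       na.rm = TRUE),
      area_km2 = sum(.data$area_km2),
      .groups = "drop"
    ) %>%
    select("year", "n_fires", "area_km2", "mean_dnbr")
  trend <- lm(mean_dnbr ~ year, data = annual)
  structure(list(annual = annual, trend = trend), class = "fire_regime")
}

#' @export
print.fire_regime <- function(x, ...) {
  sl <- coef(x$trend)[["year"]]
  cat("<fire_regime> ", nrow(x$annual), " years, ",
      sum(x$annual$n_fires), " fires; dNBR trend ",
      sprintf("%+.2f", sl), "/yr\n", sep = "")
  invisible(x)
}

#' @rdname fire_regime_summary
#' @param x a `fire_regime` object.
#' @param ... unused.
#' @export
tidy.fire_regime <- function(x, ...) {
  # suppressWarnings: summary.lm complains about zero-residual toy fits
  s <- suppressWarnings(summary(x$trend))$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fire_regime_summary
#' @export
glance.fire_regime <- function(x, ...) {
  tibble(
    n_years = nrow(x$annual),
    n_fires = sum(x$annual$n_fires),
    total_area_km2 = sum(x$annual$area_km2),
    dnbr_trend = coef(x$trend)[["year"]],
    r.squared = suppressWarnings(summary(x$trend))$r.squared
  )
}

severity_class <- function(dnbr) {
  cut(dnbr, breaks = c(-Inf, seq(100, 600, by = 100), Inf),
      labels = c("<100", "100-200", "200-300", "300-400",
                 "400-500", "500-600", ">=600"),
      right = FALSE)
}

# once-burned cohorts with their single fire's attributes
once_burned <- function(cohorts) {
  n_fires <- purrr::map_int(cohorts$fires, nrow)
  ob <- cohorts[n_fires == 1L, ]
  ob %>%
    mutate(
      fire_year = purrr::map_int(.data$fires, ~ as.integer(.x$year[1])),
      dnbr = purrr::map_dbl(.data$fires, ~ .x$dnbr[1]),
      class = severity_class(.data$dnbr)
    ) %>%
    select("cell", "cohort_id", "frac", "fire_year", "dnbr", "class")
}

#' Post-fire chronosequence by burn-severity class
#'
#' Re-indexes paired fire / no-fire cohort runs by years since fire and
#' averages the scenario differences within seven dNBR classes of width 100
#' (<100 up to >=600). Only once-burned cohorts enter. Carbon pools and
#' fluxes are reported as no-fire minus fire; the physical diagnostics
#' (soil moisture, soil temperature) as fire minus no-fire, so a positive
#' value always means "the fire changed it in its characteristic direction".
#' Averaging across cohorts is unweighted by default; `weighted = TRUE`
#' weights by cohort area fraction.
#'
#' @param fire_runs,nofire_runs per-cohort annual series from
#'   [run_scenario()] with and without fire.
#' @param cohorts the cohort tibble the runs were made from.
#' @param horizon maximum years since fire to keep (default 25).
#' @param weighted area-weight the class averages?
#' @return A tidy tibble: `class`, `years_since_fire`, `variable`
#'   (one of cveg, csoil, npp, rh, nep, nmin, moisture, tsoil), `diff`,
#'   `n_cohorts`.
#' @export
chronosequence <- function(fire_runs, nofire_runs, cohorts,
                           horizon = 25, weighted = FALSE) {
  ob <- once_burned(cohorts)
  if (nrow(ob) == 0L) abort("no once-burned cohorts")
  vars_nf_minus_f <- c("cveg", "csoil", "npp", "rh", "nep", "nmin")
  vars_f_minus_nf <- c("moisture", "tsoil")
  paired <- fire_runs %>%
    dplyr::inner_join(nofire_runs,
                      by = c("cell", "cohort_id", "year"),
                      suffix = c("_f", "_nf"))
  if (nrow(paired) == 0L) abort("cohorts are missing their no-fire twins")
  long <- paired %>%
    dplyr::inner_join(ob, by = c("cell", "cohort_id")) %>%
    mutate(years_since_fire = .data$year - .data$fire_year) %>%
    filter(.data$years_since_fire >= 0,
           .data$years_since_fire <= horizon)
  for (v in vars_nf_minus_f) {
    long[[v]] <- long[[paste0(v, "_nf")]] - long[[paste0(v, "_f")]]
  }
  for (v in vars_f_minus_nf) {
    long[[v]] <- long[[paste0(v, "_f")]] - long[[paste0(v, "_nf")]]
  }
  long %>%
    select(all_of(c("class", "years_since_fire", "frac_f",
                    vars_nf_minus_f, vars_f_minus_nf))) %>%
    tidyr::pivot_longer(all_of(c(vars_nf_minus_f, vars_f_minus_nf)),
                        names_to = "variable", values_to = "value") %>%
    group_by(.data$class, .data$years_since_fire, .data$variable) %>%
    summarise(
      diff = if (weighted) {
        stats::weighted.mean(.data$value, .data$frac_f)
      } else {
        mean(.data$value)
      },
      n_cohorts = dplyr::n(), .groups = "drop"
    )
}

#' Partition of fire-related emissions by severity class
#'
#' Three per-class series describing where the emitted carbon comes from:
#' \itemize{
#' \item `soil_share` — soil share of the direct (combustion) emission;
#' \item `soil_direct_share` — direct soil emission over direct soil emission
#'   plus cumulative post-fire heterotrophic respiration, by years since
#'   fire;
#' \item `direct_share` — direct emission over total emission (direct plus
#'   cumulative R_H), by years since fire.
#' }
#' Classes whose total in a denominator is zero are reported `NA`
#' (undefined), never 0. Only once-burned cohorts enter.
#'
#' @param fire_runs per-cohort annual series from [run_scenario()] with fire.
#' @param cohorts the cohort tibble the runs were made from.
#' @param horizon maximum years since fire (default 25).
#' @return A tidy tibble: `class`, `years_since_fire`, `measure`, `value`.
#' @export
emission_partition <- function(fire_runs, cohorts, horizon = 25) {
  ob <- once_burned(cohorts)
  per <- fire_runs %>%
    dplyr::inner_join(ob, by = c("cell", "cohort_id")) %>%
    mutate(years_since_fire = .data$year - .data$fire_year) %>%
    filter(.data$years_since_fire >= 0,
           .data$years_since_fire <= horizon) %>%
    group_by(.data$cell, .data$cohort_id) %>%
    arrange(.data$years_since_fire, .by_group = TRUE) %>%
    mutate(
      e_soil = .data$emis_soil[1],
      e_veg = .data$emis_veg[1],
      cum_rh = cumsum(.data$rh)
    ) %>%
    ungroup() %>%
    mutate(
      soil_share = ifelse(.data$e_soil + .data$e_veg > 0,
                          .data$e_soil / (.data$e_soil + .data$e_veg),
                          NA_real_),
      soil_direct_share = ifelse(.data$e_soil + .data$cum_rh > 0,
                                 .data$e_soil /
                                   (.data$e_soil + .data$cum_rh),
                                 NA_real_),
      direct_share = ifelse(.data$e_soil + .data$e_veg + .data$cum_rh > 0,
                            (.data$e_soil + .data$e_veg) /
                              (.data$e_soil + .data$e_veg + .data$cum_rh),
                            NA_real_)
    )
  per %>%
    select(all_of(c("class", "years_since_fire", "soil_share",
                    "soil_direct_share", "direct_share"))) %>%
    tidyr::pivot_longer(-c("class", "years_since_fire"),
                        names_to = "measure", values_to = "value") %>%
    group_by(.data$class, .data$years_since_fire, .data$measure) %>%
    summarise(value = mean(.data$value), .groups = "drop")
}

#' Indirect-to-direct emission ratio by severity class
#'
#' The cumulative total emission of the fire scenario (direct combustion plus
#' R_H accumulated since the fire) minus the cumulative total of the no-fire
#' twin (its R_H over the same years), expressed as a multiple of the direct
#' emission. A ratio of 1 means the fire's extra emissions equal the
#' combustion pulse alone; above 1, post-fire R_H adds indirect emissions;
#' below 1, suppressed R_H partly offsets the pulse. `NA` where the direct
#' emission is zero.
#'
#' @inheritParams emission_partition
#' @param nofire_runs the paired no-fire series.
#' @return A tidy tibble: `class`, `years_since_fire`, `ratio`.
#' @export
indirect_ratio <- function(fire_runs, nofire_runs, cohorts, horizon = 25) {
  ob <- once_burned(cohorts)
  paired <- fire_runs %>%
    dplyr::inner_join(nofire_runs, by = c("cell", "cohort_id", "year"),
                      suffix = c("_f", "_nf")) %>%
    dplyr::inner_join(ob, by = c("cell", "cohort_id")) %>%
    mutate(years_since_fire = .data$year - .data$fire_year) %>%
    filter(.data$years_since_fire >= 0,
           .data$years_since_fire <= horizon) %>%
    group_by(.data$cell, .data$cohort_id) %>%
    arrange(.data$years_since_fire, .by_group = TRUE) %>%
    mutate(
      direct = .data$emis_total_f[1],
      ratio = ifelse(.data$direct > 0,
                     (.data$direct + cumsum(.data$rh_f) -
                        cumsum(.data$rh_nf)) / .data$direct,
                     NA_real_)
    ) %>%
    ungroup()
  paired %>%
    group_by(.data$class, .data$years_since_fire) %>%
    summarise(ratio = mean(.data$ratio), .groups = "drop")
}
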