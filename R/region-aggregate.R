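#' Aggregate cohort series to a regional annual ledger
#'
#' Cell means are cohort values weighted by their within-cell area fractions;
#' regional totals multiply the cell mean by the cell's forested area and sum
#' over cells. Fluxes and stocks convert from g C m-2 to Tg C via
#' g C m-2 x km2 x 1e-6 = Tg C. Cumulative columns give the carbon balance:
#' `cb` is cumulative NEP and `cbf` is cumulative NEP minus cumulative direct
#' fire emissions, so `cbf = cb - cum_emis` holds identically every year.
#'
#' @param series per-cohort annual series from [run_scenario()].
#' @param config the [synth_config()] defining the grid (cell areas).
#' @param forest_frac forested fraction per cell: a single number or a tibble
#'   (`cell`, `forest_frac`). Cells with zero forest are skipped.
#' @return A regional ledger tibble, class `"regional_ledger"`: one row per
#'   year with `npp`, `rh`, `nep`, `emis` (Tg C yr-1), `cveg`, `csoil`
#'   (Tg C), `cb`, `cum_emis`, `cbf` (Tg C).
#' @export
aggregate_region <- function(series, config, forest_frac = 1) {
  frac_check <- series %>%
    dplyr::distinct(.data$cell, .data$cohort_id, .data$frac) %>%
    group_by(.data$cell) %>%
    summarise(tot = sum(.data$frac), .groups = "drop")
  if (any(abs(frac_check$tot - 1) > 1e-9)) {
    abort("cohort area fractions do not sum to 1 within a cell")
  }
  cell_area <- config$cell_km^2
  if (is.numeric(forest_frac) && length(forest_frac) == 1L) {
    ff <- tibble(cell = unique(series$cell), forest_frac = forest_frac)
  } else {
    ff <- as_tibble(forest_frac)
  }
  vars <- c("npp", "rh", "nep", "emis_total", "cveg", "csoil")
  cells <- series %>%
    group_by(.data$cell, .data$year) %>%
    summarise(across(all_of(vars), ~ sum(.x * .data$frac)),
              .groups = "drop") %>%
    left_join(ff, by = "cell") %>%
    filter(.data$forest_frac > 0)
  ledger <- cells %>%
    mutate(area_km2 = cell_area * .data$forest_frac) %>%
    group_by(.data$year) %>%
    summarise(across(all_of(vars), ~ sum(.x * .data$area_km2) * 1e-6),
              .groups = "drop") %>%
    rename(emis = "emis_total") %>%
    arrange(.data$year) %>%
    mutate(cb = cumsum(.data$nep),
           cum_emis = cumsum(.data$emis),
           cbf = .data$cb - .data$cum_emis)
  class(ledger) <- c("regional_ledger", class(ledger))
  ledger
}

#' Carbon-balance bookkeeping of paired fire / no-fire runs
#'
#' Closes the ledger identities over the whole period: the carbon balance CB
#' is the cumulative NEP of each scenario; CBF (fire scenario) subtracts
#' cumulative direct emissions; the NEP gap is CB(no fire) - CB(fire); and
#' the total reduction of ecosystem C storage attributable to fire is the
#' NEP gap plus the direct emissions.
#'
#' @param fire,nofire regional ledgers from [aggregate_region()], or lists
#'   with elements `cb` and `emissions` (final cumulative values, Tg C) —
#'   handy for bookkeeping from already-aggregated totals.
#' @return A one-row tibble: `cb_nofire`, `cb_fire`, `emissions`, `cbf_fire`,
#'   `nep_gap`, `reduction` (all Tg C).
#' @examples
#' carbon_balance(fire = list(cb = 59.0, emissions = 1769.8),
#'                nofire = list(cb = 1030.0, emissions = 0))
#' @export
carbon_balance <- function(fire, nofire) {
  pick <- function(x) {
    if (inherits(x, "regional_ledger")) {
      list(cb = x$cb[nrow(x)], emissions = x$cum_emis[nrow(x)])
    } else {
      list(cb = x$cb, emissions = x$emissions %||% 0)
    }
  }
  f <- pick(fire)
  nf <- pick(nofire)
  if (inherits(fire, "regional_ledger") &&
      inherits(nofire, "regional_ledger") &&
      !identical(fire$year, nofire$year)) {
    abort("fire and no-fire ledgers cover different years")
  }
  tibble(
    cb_nofire = nf$cb, cb_fire = f$cb, emissions = f$emissions,
    cbf_fire = f$cb - f$emissions,
    nep_gap = nf$cb - f$cb,
    reduction = (nf$cb - f$cb) + f$emissions
  )
}

#' Annualize a period total
#'
#' Divides a multi-year total by the number of years and reports one decimal,
#' the convention used for regional emission rates (Tg C yr-1).
#'
#' @param total period total (Tg C).
#' @param years number of years (> 0).
#' @return Tg C yr-1, rounded to 1 decimal.
#' @examples
#' annualize(1769.8, 31)  # 57.1
#' @export
annualize <- function(total, years) {
  if (years <= 0) abort("years must be positive")
  round(total / years, 1)
}
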