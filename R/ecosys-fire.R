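#' Apply a fire disturbance to a cohort
#'
#' Removes the combusted share of each carbon pool — canopy fraction of
#' vegetation C, soil fraction of soil organic C — and books the removals as
#' direct emissions. Nitrogen losses follow fire chemistry: N volatilizes at
#' lower temperatures than carbon chars, so soil organic N is removed
#' super-proportionally to soil C (fraction `(1 + n_volat) x soil_frac`,
#' capped at 1) and leaves with the smoke, temporarily lowering the soil
#' N:C ratio and hence net mineralization; of the N in combusted biomass a
#' fraction `n_volat` is volatilized and the remainder returns as available
#' inorganic N (the ash pulse that speeds early regrowth). Foliage fraction
#' is knocked down by the canopy fraction, the moss layer by the soil
#' fraction, and the time-since-fire clock restarts; the pre-fire foliage
#' and moss references used by the recovery curves are retained.
#'
#' @param state a [cohort_state()].
#' @param severity one-row tibble with `soil_frac` and `canopy_frac` in
#'   `[0, 1]` (e.g. from [severity_from_dnbr()]).
#' @param params an [ecosys_params()].
#' @return A list with `state` (post-fire) and `emission`, a one-row tibble:
#'   `emis_veg`, `emis_soil`, `emis_total` (g C m-2), `n_lost` (g N m-2).
#' @export
apply_fire <- function(state, severity, params) {
  sf <- severity$soil_frac[1]
  cf <- severity$canopy_frac[1]
  if (any(!is.finite(c(sf, cf))) || sf < 0 || sf > 1 || cf < 0 || cf > 1) {
    abort("combustion fractions must lie in [0, 1]")
  }
  e_veg <- cf * state$cveg
  e_soil <- sf * state$csoil
  sf_n <- min(1, (1 + params$n_volat) * sf)
  n_veg_burn <- e_veg / params$cn_veg
  st <- state
  st$cveg <- state$cveg - e_veg
  st$csoil <- state$csoil - e_soil
  st$norg <- state$norg * (1 - sf_n)
  st$navail <- state$navail + (1 - params$n_volat) * n_veg_burn
  st$fol <- state$fol * (1 - cf)
  st$fol_prefire <- state$fol_prefire
  st$fol_postfire <- st$fol
  st$moss <- state$moss * (1 - sf)
  st$moss_prefire <- state$moss_prefire
  st$moss_postfire <- st$moss
  st$tsf <- 0
  validate_state(st)
  list(
    state = st,
    emission = tibble(emis_veg = e_veg, emis_soil = e_soil,
                      emis_total = e_veg + e_soil,
                      n_lost = params$n_volat * n_veg_burn +
                        sf_n * state$norg)
  )
}

#' Post-fire foliage recovery curve
#'
#' Foliage recovers linearly for the first `fol_linear_years` years (closing
#' `fol_frac5` of the canopy gap), then follows a logistic approach to the
#' pre-fire reference; the two phases are continuous at the junction.
#'
#' @param years_since_fire years since the fire (>= 0).
#' @param state a [cohort_state()] carrying `fol_postfire` / `fol_prefire`.
#' @param params an [ecosys_params()].
#' @return Foliage fraction in `[0, 1]`.
#' @export
foliage_recovery <- function(years_since_fire, state, params) {
  stopifnot(all(years_since_fire >= 0))
  f0 <- state$fol_postfire
  fp <- state$fol_prefire
  t5 <- params$fol_linear_years
  junction <- f0 + (fp - f0) * params$fol_frac5
  sig <- function(t) 1 / (1 + exp(-params$fol_k * (t - params$fol_tm)))
  ifelse(
    years_since_fire <= t5,
    f0 + (junction - f0) * years_since_fire / t5,
    fp - (fp - junction) * (1 - sig(years_since_fire)) / (1 - sig(t5))
  )
}

#' Post-fire moss-layer recovery curve
#'
#' Exponential relaxation of the moss/organic-layer depth toward its pre-fire
#' reference with e-folding time `moss_tau`:
#' depth(t) = asymptote - (asymptote - post-fire depth) exp(-t / tau).
#'
#' @inheritParams foliage_recovery
#' @return Moss depth, cm (monotone non-decreasing in time).
#' @export
moss_recovery <- function(years_since_fire, state, params) {
  stopifnot(all(years_since_fire >= 0))
  a <- state$moss_prefire
  a - (a - state$moss_postfire) * exp(-years_since_fire / params$moss_tau)
}
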