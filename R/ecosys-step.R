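#' Soil temperature diagnostic
#'
#' Soil temperature is smoothed air temperature minus an insulation offset
#' proportional to the moss/organic-layer depth; losing moss therefore warms
#' the soil. The smoothing (exponential, weight `t_smooth`) stands in for the
#' thermal inertia of the ground. Pure function of the state's smoothed
#' temperature memory, the month's air temperature, and the moss depth; the
#' monthly step updates the memory itself.
#'
#' @param state a [cohort_state()].
#' @param clim one forcing row (needs `tair`).
#' @param params an [ecosys_params()].
#' @return Soil temperature, deg C.
#' @export
soil_temperature <- function(state, clim, params) {
  t_sm <- (1 - params$t_smooth) * state$t_sm + params$t_smooth * clim$tair
  t_sm - params$insulation * state$moss
}

#' Soil moisture diagnostic (single-bucket balance)
#'
#' One bucket of plant-available water: precipitation in,
#' evapotranspiration and baseflow drainage out, overflow lost as runoff.
#' ET scales with above-freezing air temperature and increases with foliage
#' fraction (transpiration) above a bare-soil evaporation floor, so a burned
#' (low-foliage) stand transpires less and sits slightly wetter — the small
#' post-fire moisture signal the carbon kernel feels. Returned as percent of
#' capacity ("% of total porosity"), clamped to `[0, 100]`.
#'
#' @inheritParams soil_temperature
#' @param clim one forcing row (needs `tair`, `prec`).
#' @return Moisture as % of capacity.
#' @export
soil_moisture <- function(state, clim, params) {
  et <- params$et_coef * max(clim$tair, 0) *
    (params$et_base + (1 - params$et_base) * state$fol)
  drain <- params$k_drain * state$water
  s_new <- min(max(state$water + clim$prec - et - drain, 0),
               params$bucket_mm)
  100 * s_new / params$bucket_mm
}

#' Advance one cohort by one month
#'
#' The kernel of the simulator. In order: update the physical diagnostics
#' (soil temperature, soil moisture), then compute
#' \itemize{
#' \item NPP = `npp_max` x foliage x g_T(air T) x g_W(moisture) x
#'   g_N(available N) x g_CO2(CO2), with a Gaussian temperature response,
#'   Michaelis-Menten moisture and N scalars, and a log CO2 fertilization
#'   term;
#' \item heterotrophic respiration R_H = `k_decomp` x soil C x
#'   Q10^((Tsoil - Tref)/10) x h_W(moisture);
#' \item litterfall = `k_litter` x vegetation C;
#' \item net N mineralization = (1 - `imm_frac`) x R_H x (soil N:C), i.e.
#'   decomposition releases N at the soil's actual N:C ratio and microbes
#'   immobilize a fixed share.
#' }
#' Pools are then updated by one explicit Euler step. Carbon mass balance
#' (d(veg+soil) = NPP - R_H) holds to machine precision; a negative pool
#' aborts loudly rather than clipping, since it signals a rate-parameter bug.
#'
#' @inheritParams soil_temperature
#' @param clim one forcing row (`tair`, `prec`, `co2`).
#' @return A list with `state` (updated [cohort_state()]) and `flux`, a
#'   one-row tibble: `npp`, `rh`, `nep`, `litterfall` (g C m-2 month-1) and
#'   `nmin` (g N m-2 month-1).
#' @export
step_month <- function(state, clim, params) {
  if (!all(is.finite(c(clim$tair, clim$prec, clim$co2)))) {
    abort("non-finite climate forcing")
  }
  tsoil <- soil_temperature(state, clim, params)
  moisture <- soil_moisture(state, clim, params)

  g_t <- exp(-((clim$tair - params$t_opt) / params$t_width)^2)
  g_w <- moisture / (moisture + params$k_w)
  g_n <- state$navail / (state$navail + params$k_n)
  g_c <- 1 + params$co2_slope * log(clim$co2 / 280)

  h_w <- moisture / (moisture + params$k_wh)
  rh <- params$k_decomp * state$csoil *
    params$q10^((tsoil - params$t_ref) / 10) * h_w

  litter <- params$k_litter * state$cveg
  nc_soil <- if (state$csoil > 0) state$norg / state$csoil else 0
  gross_min <- rh * nc_soil
  nmin <- (1 - params$imm_frac) * gross_min

  # NPP is the smaller of the climate-limited potential and what this
  # month's N supply can build (Liebig); uptake then always matches NPP,
  # which pins the equilibrium available-N pool at n_dep / k_leach
  npp_pot <- params$npp_max * state$fol * g_t * g_w * g_n * g_c
  n_supply <- max(0, state$navail * (1 - params$k_leach) +
                    nmin + params$n_dep)
  npp <- min(npp_pot, params$cn_veg * n_supply)
  uptake <- npp / params$cn_veg

  st <- state
  st$t_sm <- (1 - params$t_smooth) * state$t_sm + params$t_smooth * clim$tair
  st$tsoil <- tsoil
  st$moisture <- moisture
  st$water <- moisture / 100 * params$bucket_mm
  st$cveg <- state$cveg + npp - litter
  st$csoil <- state$csoil + litter - rh
  st$norg <- state$norg + litter / params$cn_veg - nmin -
    params$k_oleach * state$norg
  st$navail <- state$navail + nmin + params$n_dep - uptake -
    params$k_leach * state$navail
  validate_state(st)

  list(
    state = st,
    flux = tibble::new_tibble(
      list(npp = npp, rh = rh, nep = npp - rh,
           litterfall = litter, nmin = nmin),
      nrow = 1L
    )
  )
}
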