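#' Default parameters of the reduced-form ecosystem kernel
#'
#' Returns the parameter set of the monthly carbon-nitrogen simulator. The
#' kernel is deliberately compact: multiplicative-limitation NPP, first-order
#' decomposition with a Q10 temperature response and a Michaelis-Menten
#' moisture scalar, linear litterfall, and C:N-coupled net mineralization.
#' Defaults were tuned once so that spin-up under the default boreal
#' climatology settles near observed black-spruce stand stocks (~2.2 kg C m-2
#' vegetation, ~10.1 kg C m-2 soil) and post-fire responses have realistic
#' sign and magnitude; they ship as code, not as a dial to twist per run.
#'
#' @param ... name-value overrides of individual parameters.
#' @return A list of class `"ecosys_params"`:
#' \describe{
#'   \item{npp_max}{maximum NPP, g C m-2 month-1, at zero limitation.}
#'   \item{t_opt, t_width}{Gaussian air-temperature response (deg C).}
#'   \item{k_w}{moisture half-saturation of NPP (% of porosity).}
#'   \item{k_n}{available-N half-saturation of NPP (g N m-2).}
#'   \item{co2_slope}{fertilization slope per ln(CO2/280 ppm).}
#'   \item{k_litter}{litterfall rate, month-1.}
#'   \item{k_decomp}{base decomposition rate, month-1, at `t_ref`.}
#'   \item{q10, t_ref}{decomposition temperature sensitivity and reference
#'     soil temperature (deg C).}
#'   \item{k_wh}{moisture half-saturation of decomposition (% porosity).}
#'   \item{cn_veg, cn_soil0}{vegetation C:N and initial soil organic C:N.}
#'   \item{imm_frac}{fraction of gross mineralization immobilized by
#'     microbes.}
#'   \item{n_dep, k_leach}{N deposition plus fixation input (g N m-2
#'     month-1) and leaching rate on available N (month-1).}
#'   \item{k_oleach}{slow dissolved-organic-N loss rate on soil organic N
#'     (month-1); together with `n_dep` this anchors the ecosystem N stock
#'     at an absolute level instead of leaving it adrift.}
#'   \item{n_volat}{fraction of N in combusted biomass volatilized by fire;
#'     the remainder returns as available N.}
#'   \item{t_smooth}{monthly smoothing weight of air temperature entering the
#'     soil (thermal inertia).}
#'   \item{insulation}{soil cooling per cm of moss/organic layer (deg C
#'     cm-1).}
#'   \item{moss_max, moss_tau}{moss-layer asymptotic depth (cm) and recovery
#'     e-folding time (yr).}
#'   \item{fol_linear_years, fol_frac5, fol_k, fol_tm}{foliage recovery:
#'     linear phase length (yr), fraction of the canopy gap closed at its
#'     end, and logistic steepness (yr-1) and midpoint (yr) of the later
#'     sigmoid phase.}
#'   \item{et_coef}{evapotranspiration per degree of above-zero air
#'     temperature at full canopy (mm month-1 degC-1).}
#'   \item{et_base}{foliage-independent share of ET (bare-soil evaporation
#'     floor); ET scales with `et_base + (1 - et_base) * foliage`, so losing
#'     canopy wets the soil slightly, as observed, rather than massively.}
#'   \item{bucket_mm}{plant-available water capacity of the soil bucket
#'     (mm).}
#'   \item{k_drain}{baseflow drainage rate of the bucket (month-1), keeping
#'     the bucket off saturation so the moisture scalars stay responsive.}
#' }
#' @export
ecosys_params <- function(...) {
  p <- list(
    npp_max = 140,
    t_opt = 15, t_width = 13,
    k_w = 15,
    k_n = 0.15,
    co2_slope = 0.4,
    k_litter = 0.017,
    k_decomp = 0.0118,
    q10 = 2.0, t_ref = 5,
    k_wh = 60,
    cn_veg = 60, cn_soil0 = 39.1,
    imm_frac = 0.4,
    n_dep = 0.09, k_leach = 0.03, k_oleach = 0.0002,
    n_volat = 0.5,
    t_smooth = 0.5,
    insulation = 0.065,
    moss_max = 20, moss_tau = 20,
    fol_linear_years = 5, fol_frac5 = 0.3, fol_k = 0.35, fol_tm = 12,
    et_coef = 3,
    et_base = 0.95,
    bucket_mm = 250,
    k_drain = 0.2
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) abort(paste0("unknown parameters: ", paste(bad, collapse = ", ")))
  p <- modifyList(p, over)
  if (p$q10 <= 1) abort("q10 must exceed 1")
  rates <- c(p$k_litter, p$k_decomp, p$k_leach, p$k_oleach, p$npp_max,
             p$et_coef)
  if (any(rates < 0)) abort("rates must be >= 0")
  fracs <- c(p$imm_frac, p$n_volat, p$fol_frac5, p$et_base, p$k_drain)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  structure(p, class = "ecosys_params")
}

#' Initial cohort state
#'
#' One land cohort's pools and diagnostics. The defaults are a mature,
#' never-burned black-spruce stand at the kernel's equilibrium under the
#' default boreal climatology (close to the observed ~2.2 kg C m-2
#' vegetation and ~10.1 kg C m-2 soil stocks), so spin-up from the default
#' state drifts negligibly.
#'
#' @param cveg vegetation C (g C m-2).
#' @param csoil soil organic C (g C m-2).
#' @param norg soil organic N (g N m-2); default `csoil / cn_soil0`.
#' @param navail available inorganic N (g N m-2).
#' @param fol foliage fraction of the mature canopy, in `[0, 1]`.
#' @param moss moss/organic-layer depth (cm).
#' @param water soil bucket water storage (mm).
#' @param tsf years since fire (`Inf` = never burned).
#' @param params an [ecosys_params()] (used for derived defaults).
#' @return A list of class `"cohort_state"`.
#' @export
cohort_state <- function(cveg = 2123, csoil = 9560,
                         norg = NULL, navail = 1.75,
                         fol = 1, moss = NULL, water = 134.5,
                         tsf = Inf, params = ecosys_params()) {
  moss <- moss %||% params$moss_max
  st <- list(
    cveg = cveg, csoil = csoil,
    norg = norg %||% (csoil / params$cn_soil0), navail = navail,
    fol = fol, fol_prefire = fol, fol_postfire = fol,
    moss = moss, moss_prefire = moss, moss_postfire = moss,
    water = water, tsf = tsf,
    # smoothed-air-temperature memory as of a December under the default
    # boreal seasonal cycle (runs conventionally start in January)
    t_sm = -11.6, tsoil = NA_real_, moisture = NA_real_
  )
  validate_state(st, params)
  structure(st, class = "cohort_state")
}

validate_state <- function(st, params = NULL) {
  pools <- c(st$cveg, st$csoil, st$norg, st$navail)
  if (any(!is.finite(pools)) || any(pools < -1e-9)) {
    abort("negative or non-finite pool in cohort state")
  }
  if (st$fol < 0 || st$fol > 1) abort("foliage fraction outside [0, 1]")
  if (!is.null(params) && st$moss > params$moss_max + 1e-9) {
    abort("moss depth exceeds its asymptote")
  }
  invisible(st)
}
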