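#' Composite Burn Index from dNBR
#'
#' Linear field calibration between satellite dNBR and the ground-assessed
#' Composite Burn Index for boreal black-spruce forests:
#' CBI = 0.0023 x dNBR + 0.5561, clamped to the CBI's 0-3 scale.
#'
#' @param dnbr numeric vector of (background-corrected) dNBR.
#' @return CBI values in `[0, 3]`.
#' @examples
#' dnbr_to_cbi(0)       # 0.5561
#' dnbr_to_cbi(1300)    # clamped to 3
#' @export
dnbr_to_cbi <- function(dnbr) {
  stopifnot(all(is.finite(dnbr)))
  pmin(3, pmax(0, 0.0023 * dnbr + 0.5561))
}

#' Combustion fractions of the soil and canopy carbon pools from CBI
#'
#' Field regressions on black-spruce sites relate CBI to the share of each
#' carbon pool consumed by fire:
#' soil organic C combustion (%) = 51.42 x CBI - 63.49 and
#' canopy C combustion (%) = 14.15 x CBI + 48.63. Percentages are clamped to
#' `[0, 100]` (the fitted lines leave that range outside the calibration
#' domain) and returned as fractions. The soil line crosses zero at
#' CBI ~ 1.2347 (dNBR ~ 295.06): below that severity the organic soil barely
#' combusts.
#'
#' @param cbi numeric vector of CBI values in `[0, 3]`.
#' @return A tibble with columns `soil_frac` and `canopy_frac` in `[0, 1]`.
#' @examples
#' cbi_to_fractions(dnbr_to_cbi(633.28))$soil_frac  # 0.40
#' @export
cbi_to_fractions <- function(cbi) {
  stopifnot(all(cbi >= 0 & cbi <= 3))
  tibble(
    soil_frac = pmin(100, pmax(0, 51.42 * cbi - 63.49)) / 100,
    canopy_frac = pmin(100, pmax(0, 14.15 * cbi + 48.63)) / 100
  )
}

#' Invert a soil combustion fraction to the dNBR that implies it
#'
#' Runs the severity chain backwards: soil fraction -> CBI (inverse of the
#' soil-combustion regression) -> dNBR (inverse of the dNBR-CBI calibration).
#' Used to assign a burn severity to fires whose soil organic-layer loss is
#' known from field observation but which predate the satellite record.
#' Undefined at and below the zero crossing (soil fraction must be positive).
#'
#' @param soil_fraction numeric vector in `(0, 1]`.
#' @return dNBR values.
#' @examples
#' soil_fraction_to_dnbr(0.40)  # 633.28
#' soil_fraction_to_dnbr(0.65)  # 844.67
#' @export
soil_fraction_to_dnbr <- function(soil_fraction) {
  if (any(soil_fraction <= 0) || any(soil_fraction > 1)) {
    abort("soil fraction must lie in (0, 1]: the inverse is undefined below the zero crossing")
  }
  cbi <- (100 * soil_fraction + 63.49) / 51.42
  (cbi - 0.5561) / 0.0023
}

#' Complete severity records from corrected dNBR
#'
#' Adds CBI and the two combustion fractions to a table of fires with
#' (gap-filled) corrected dNBR. Negative corrected dNBR means no detected
#' burn and is floored at 0 before the CBI mapping.
#'
#' @param fires tibble with at least a `dnbr` column (no missing values;
#'   run [gap_fill()] first).
#' @return The input with added `cbi`, `soil_frac`, `canopy_frac` columns.
#' @export
severity_from_dnbr <- function(fires) {
  if (anyNA(fires$dnbr)) abort("missing dNBR; run gap_fill() first")
  cbi <- dnbr_to_cbi(pmax(fires$dnbr, 0))
  fires %>%
    mutate(cbi = cbi) %>%
    dplyr::bind_cols(cbi_to_fractions(cbi))
}
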