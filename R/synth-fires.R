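#' Generate a synthetic fire history
#'
#' Draws a multi-decade fire record over the configured grid: yearly fire
#' counts are Poisson with rate `config$fire_rate`, burned areas are
#' log-normal, per-fire mean dNBR is truncated-normal (inverse-CDF sampling,
#' so no rejection loop), and a configurable fraction of fires carries no
#' dNBR, emulating events with no usable satellite imagery. Perimeters are
#' axis-aligned rectangles in km, clipped to the domain; the recorded area is
#' the clipped rectangle area so cohort bookkeeping stays exact.
#'
#' @param config a [synth_config()].
#' @return A tibble of fire events: `fire_id`, `year`, `area_km2`,
#'   `x0`, `x1`, `y0`, `y1` (perimeter, km), `dnbr` (NA where no imagery).
#' @examples
#' fires <- gen_fire_history(synth_config(seed = 3))
#' @export
gen_fire_history <- function(config) {
  validate_synth_config(config)
  xmax <- config$nx * config$cell_km
  ymax <- config$ny * config$cell_km
  withr::with_seed(derive_seed(config$seed, "fires"), {
    counts <- rpois(length(config$years), config$fire_rate)
    n <- sum(counts)
    if (n == 0L) {
      return(tibble(
        fire_id = integer(), year = integer(), area_km2 = numeric(),
        x0 = numeric(), x1 = numeric(), y0 = numeric(), y1 = numeric(),
        dnbr = numeric()
      ))
    }
    year <- rep(config$years, counts)
    area <- rlnorm(n, config$area_meanlog, config$area_sdlog)
    aspect <- exp(runif(n, log(0.5), log(2)))
    w <- pmin(sqrt(area * aspect), xmax)
    h <- pmin(area / w, ymax)
    x0 <- runif(n, 0, xmax - w)
    y0 <- runif(n, 0, ymax - h)
    dnbr <- rtruncnorm(n, config$dnbr_mean, config$dnbr_sd,
                       config$dnbr_min, config$dnbr_max)
    dnbr[runif(n) < config$missing_frac] <- NA_real_
    tibble(
      fire_id = seq_len(n), year = year, area_km2 = w * h,
      x0 = x0, x1 = x0 + w, y0 = y0, y1 = y0 + h,
      dnbr = dnbr
    )
  })
}

# truncated normal via inverse CDF (exact, vectorized)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(runif(n, pl, pu), mean, sd)
}
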