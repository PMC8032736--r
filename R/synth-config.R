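#' Configuration for the synthetic landscape generator
#'
#' Bundles every knob of the synthetic inputs: the regional grid, the study
#' years, the seasonal climate statistics, the fire regime, and the burn
#' severity (dNBR) distribution. Defaults emulate a North American boreal
#' study domain: a fire-size distribution spanning small to very large events,
#' per-fire mean dNBR concentrated in 200-400 with an area-weighted mean near
#' 272.5, and a small fraction of fires lacking satellite imagery.
#'
#' @param nx,ny number of grid cells in x and y. Cells are square,
#'   `cell_km` on a side, an idealized equal-area stand-in for a 0.5-degree
#'   grid.
#' @param cell_km cell edge length in km (default 50).
#' @param years integer vector of contiguous simulation years
#'   (default 1986:2016).
#' @param climate named list of seasonal climate statistics per variable:
#'   `tair` (deg C), `prec` (mm/month), `vapr` (hPa), `cloud` (percent), each
#'   with `mean`, `amp` (seasonal amplitude, peak in July) and `sd`
#'   (interannual Gaussian noise).
#' @param co2_start,co2_trend annual atmospheric CO2 in the first year (ppm)
#'   and its linear trend (ppm/yr).
#' @param fire_rate expected number of fires per year (Poisson).
#' @param area_meanlog,area_sdlog log-normal fire area parameters (km^2).
#' @param dnbr_mean,dnbr_sd,dnbr_min,dnbr_max truncated-normal per-fire mean
#'   dNBR parameters. Defaults (272.5, 120, bounds 60-1300) put the histogram
#'   mode in the 200-400 band.
#' @param missing_frac fraction of fires carrying no dNBR (no usable imagery),
#'   exercising the gap-fill path.
#' @param seed master random seed; every generator derives its own stream
#'   from it via [derive_seed()].
#' @return A list of class `"synth_config"`.
#' @examples
#' cfg <- synth_config(nx = 2, ny = 2, seed = 42)
#' @export
synth_config <- function(nx = 4, ny = 4, cell_km = 50,
                         years = 1986:2016,
                         climate = list(
                           tair  = list(mean = -3,  amp = 18,  sd = 1.0),
                           prec  = list(mean = 40,  amp = 25,  sd = 8.0),
                           vapr  = list(mean = 6,   amp = 4,   sd = 0.5),
                           cloud = list(mean = 60,  amp = 10,  sd = 5.0)
                         ),
                         co2_start = 347, co2_trend = 1.8,
                         fire_rate = 8,
                         area_meanlog = 3.0, area_sdlog = 1.2,
                         dnbr_mean = 272.5, dnbr_sd = 120,
                         dnbr_min = 60, dnbr_max = 1300,
                         missing_frac = 0.0053,
                         seed = 1L) {
  cfg <- list(
    nx = as.integer(nx), ny = as.integer(ny), cell_km = cell_km,
    years = as.integer(years), climate = climate,
    co2_start = co2_start, co2_trend = co2_trend,
    fire_rate = fire_rate,
    area_meanlog = area_meanlog, area_sdlog = area_sdlog,
    dnbr_mean = dnbr_mean, dnbr_sd = dnbr_sd,
    dnbr_min = dnbr_min, dnbr_max = dnbr_max,
    missing_frac = missing_frac,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$nx < 1 || cfg$ny < 1 || cfg$cell_km <= 0) {
    abort("grid extent and resolution must be positive")
  }
  if (length(cfg$years) < 1) abort("non-positive year span")
  if (!all(diff(cfg$years) == 1L)) abort("`years` must be contiguous")
  sds <- c(vapply(cfg$climate, function(v) v$sd, numeric(1)))
  if (any(sds < 0)) abort("climate noise SDs must be >= 0")
  if (cfg$fire_rate < 0) abort("fire rate must be >= 0")
  if (cfg$dnbr_min < 0 || cfg$dnbr_max > 1300 || cfg$dnbr_min >= cfg$dnbr_max) {
    abort("dNBR truncation bounds must lie within [0, 1300]")
  }
  if (cfg$missing_frac < 0 || cfg$missing_frac > 1) {
    abort("missing_frac must be a probability")
  }
  invisible(cfg)
}

#' Read a synthetic-landscape configuration from YAML
#'
#' Scalar fields in the YAML file override the [synth_config()] defaults;
#' the nested `climate` block, when present, replaces per-variable entries.
#' `years` may be given either as an explicit sequence or as a mapping
#' `{from: 1986, to: 2016}`.
#'
#' @param path path to a YAML file.
#' @return A `"synth_config"` list.
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.list(raw$years) && all(c("from", "to") %in% names(raw$years))) {
    raw$years <- seq(raw$years$from, raw$years$to)
  }
  defaults <- formals(synth_config)
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  }
  do.call(synth_config, raw)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$nx, "x", x$ny, " cells of ", x$cell_km, " km, ",
      "years ", min(x$years), "-", max(x$years),
      ", fire rate ", x$fire_rate, "/yr, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
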