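#' Construct a two-band reflectance scene
#'
#' A scene is a long tibble of pixels with near-infrared (`b4`) and
#' shortwave-infrared (`b7`) reflectance, carrying its acquisition date and
#' pixel size as attributes. This is the in-memory stand-in for a two-band
#' raster tile.
#'
#' @param b4,b7 numeric matrices of equal dimension, non-negative reflectance.
#' @param date acquisition date (coerced with [as.Date()]).
#' @param pixel_size pixel edge length in metres.
#' @return A tibble (`x`, `y`, `b4`, `b7`) of class `"bb_scene"` with
#'   attributes `date` and `pixel_size`.
#' @export
scene <- function(b4, b7, date, pixel_size = 300) {
  if (!all(dim(b4) == dim(b7))) abort("band grids must share one shape")
  if (any(b4 < 0) || any(b7 < 0)) abort("reflectance must be non-negative")
  out <- tidyr::expand_grid(y = seq_len(nrow(b4)), x = seq_len(ncol(b4))) %>%
    mutate(b4 = as.vector(t(b4)), b7 = as.vector(t(b7))) %>%
    select("x", "y", "b4", "b7")
  structure(out, date = as.Date(date), pixel_size = pixel_size,
            class = c("bb_scene", class(out)))
}

#' Embed a prescribed dNBR into a synthetic pre/post scene pair
#'
#' Builds a pair of two-band scenes (pre-fire and post-fire summers) whose
#' in-perimeter mean dNBR, after buffer-based background correction, equals
#' `target_dnbr` to better than one dNBR unit. The construction adds a uniform
#' background drift between the two acquisitions plus pixel noise that is
#' re-centred region-by-region, so the severity chain must remove the drift
#' to recover the target; pixels outside the perimeter are statistically
#' unchanged. The event's footprint is drawn as a centred rectangle whose
#' pixel size scales with the recorded fire area.
#'
#' @param event a one-row fire event (needs `fire_id`, `year`, `area_km2`).
#' @param target_dnbr dNBR to embed, within `[0, 1300]`.
#' @param seed integer seed for the pixel noise.
#' @param noise_sd per-pixel NBR noise standard deviation.
#' @param background_drift uniform NBR shift applied to the whole post scene.
#' @return A list with elements `pre` and `post` ([scene()] objects), and
#'   `mask` — the perimeter as pixel bounds `c(x0, x1, y0, y1)`.
#' @examples
#' ev <- tibble::tibble(fire_id = 1L, year = 2000L, area_km2 = 25)
#' pair <- gen_scene_pair(ev, target_dnbr = 500, seed = 9)
#' @export
gen_scene_pair <- function(event, target_dnbr, seed = 1L,
                           noise_sd = 15, background_drift = 30,
                           pixel_size = 300) {
  if (target_dnbr < 0 || target_dnbr > 1300) {
    abort("target dNBR outside representable range [0, 1300]")
  }
  stopifnot(nrow(event) == 1L)
  # footprint scales with fire area, capped so the ring always fits
  side <- round(sqrt(event$area_km2) * 1000 / pixel_size)
  side <- max(4L, min(24L, as.integer(side)))
  ring_px <- ceiling(1800 / pixel_size) + 2L
  nx <- side + 2L * ring_px
  mask <- c(x0 = ring_px + 1L, x1 = ring_px + side,
            y0 = ring_px + 1L, y1 = ring_px + side)

  withr::with_seed(derive_seed(seed, "scene"), {
    nbr_pre <- matrix(600, nx, nx) + matrix(rnorm(nx * nx, 0, noise_sd), nx, nx)
    delta <- matrix(rnorm(nx * nx, 0, noise_sd), nx, nx)
  })
  inside <- matrix(FALSE, nx, nx)
  inside[mask["y0"]:mask["y1"], mask["x0"]:mask["x1"]] <- TRUE
  # re-centre the change noise within the perimeter, within the 1500-1800 m
  # buffer ring, and elsewhere, so the embedded severity survives background
  # correction exactly, not just in expectation
  xs <- matrix(rep(seq_len(nx), each = nx), nx, nx)
  ys <- matrix(rep(seq_len(nx), times = nx), nx, nx)
  dx <- pmax(mask["x0"] - xs, xs - mask["x1"], 0)
  dy <- pmax(mask["y0"] - ys, ys - mask["y1"], 0)
  dist_m <- sqrt(dx^2 + dy^2) * pixel_size
  ring <- !inside & dist_m >= 1500 & dist_m <= 1800
  other <- !inside & !ring
  delta[inside] <- delta[inside] - mean(delta[inside])
  delta[ring] <- delta[ring] - mean(delta[ring])
  delta[other] <- delta[other] - mean(delta[other])
  nbr_post <- nbr_pre - background_drift + delta
  nbr_post[inside] <- nbr_post[inside] - target_dnbr

  yr <- event$year[1]
  list(
    pre  = scene_from_nbr(nbr_pre, as.Date(sprintf("%d-08-01", yr - 1)),
                          pixel_size),
    post = scene_from_nbr(nbr_post, as.Date(sprintf("%d-08-01", yr + 1)),
                          pixel_size),
    mask = mask
  )
}

# invert NBR = (b4 - b7)/(b4 + b7) * 1000 with fixed band sum
scene_from_nbr <- function(nbr, date, pixel_size, band_sum = 0.5) {
  nbr[nbr > 1000] <- 1000
  nbr[nbr < -1000] <- -1000
  b4 <- band_sum * (1 + nbr / 1000) / 2
  b7 <- band_sum - b4
  scene(b4, b7, date, pixel_size)
}
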