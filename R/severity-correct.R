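#' Background-correct the in-perimeter mean dNBR of one fire
#'
#' The raw burn signal — the mean dNBR inside the fire perimeter — contains
#' scene-to-scene variation (phenology, illumination, atmospheric state) that
#' has nothing to do with the fire. It is removed by subtracting a background
#' dNBR estimated either from a buffer ring 1500-1800 m outside the perimeter
#' (`mode = "buffer"`) or, when no ring is available, from the same perimeter
#' one year earlier (`mode = "prior_year"`). If the requested buffer ring
#' contains no pixels (perimeter at the scene edge) the function falls back to
#' prior-year mode with a warning.
#'
#' @param fire one-row fire event tibble (needs `fire_id`, `year`,
#'   `area_km2`).
#' @param dnbr_grid dNBR tibble from [compute_dnbr()].
#' @param mask perimeter pixel bounds `c(x0, x1, y0, y1)` on the grid.
#' @param mode `"buffer"` or `"prior_year"`.
#' @param prior_dnbr prior-year dNBR grid (required for `"prior_year"`).
#' @param buffer_m inner/outer buffer distances in metres (default
#'   `c(1500, 1800)`).
#' @param pixel_size pixel size in metres; defaults to the grid attribute.
#' @return A one-row severity tibble: `fire_id`, `year`, `area_km2`,
#'   `dnbr_raw`, `dnbr_background`, `dnbr` (= raw - background),
#'   `gap_filled = FALSE`.
#' @export
background_correct <- function(fire, dnbr_grid, mask,
                               mode = c("buffer", "prior_year"),
                               prior_dnbr = NULL,
                               buffer_m = c(1500, 1800),
                               pixel_size = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(fire) == 1L, length(mask) == 4L)
  pixel_size <- pixel_size %||% attr(dnbr_grid, "pixel_size") %||% 300
  mask <- setNames(as.numeric(mask), c("x0", "x1", "y0", "y1"))

  inside <- dnbr_grid$x >= mask["x0"] & dnbr_grid$x <= mask["x1"] &
    dnbr_grid$y >= mask["y0"] & dnbr_grid$y <= mask["y1"]
  raw <- mean(dnbr_grid$dnbr[inside], na.rm = TRUE)

  if (mode == "buffer") {
    dx <- pmax(mask["x0"] - dnbr_grid$x, dnbr_grid$x - mask["x1"], 0)
    dy <- pmax(mask["y0"] - dnbr_grid$y, dnbr_grid$y - mask["y1"], 0)
    dist_m <- sqrt(dx^2 + dy^2) * pixel_size
    ring <- dist_m >= buffer_m[1] & dist_m <= buffer_m[2]
    if (!any(ring)) {
      warn("empty buffer ring; falling back to prior-year background")
      mode <- "prior_year"
    } else {
      background <- mean(dnbr_grid$dnbr[ring], na.rm = TRUE)
    }
  }
  if (mode == "prior_year") {
    if (is.null(prior_dnbr)) {
      abort("prior_year background requested but no prior-year dNBR supplied")
    }
    pin <- prior_dnbr$x >= mask["x0"] & prior_dnbr$x <= mask["x1"] &
      prior_dnbr$y >= mask["y0"] & prior_dnbr$y <= mask["y1"]
    background <- mean(prior_dnbr$dnbr[pin], na.rm = TRUE)
  }

  tibble(
    fire_id = fire$fire_id, year = fire$year, area_km2 = fire$area_km2,
    dnbr_raw = raw, dnbr_background = background,
    dnbr = raw - background, gap_filled = FALSE
  )
}

#' Fill missing per-fire dNBR from fires of similar size
#'
#' Fires with no usable imagery get the unweighted mean dNBR of the ten
#' known-dNBR fires closest in burned area (all of them when fewer than ten
#' are known; ties in area difference broken by fire id order). The
#' `gap_filled` flag marks estimated records.
#'
#' @param fires tibble with `fire_id`, `area_km2`, `dnbr` (NA = missing) and
#'   optionally `gap_filled`.
#' @param k number of size-neighbours to average (default 10).
#' @return The input tibble with `dnbr` filled and `gap_filled` set.
#' @export
gap_fill <- function(fires, k = 10L) {
  if (!"gap_filled" %in% names(fires)) fires$gap_filled <- FALSE
  missing <- which(is.na(fires$dnbr))
  if (length(missing) == 0L) return(fires)
  known <- fires[!is.na(fires$dnbr), ]
  if (nrow(known) == 0L) abort("no fires with known dNBR to gap-fill from")
  for (i in missing) {
    ord <- order(abs(known$area_km2 - fires$area_km2[i]), known$fire_id)
    nb <- head(ord, k)
    fires$dnbr[i] <- mean(known$dnbr[nb])
    fires$gap_filled[i] <- TRUE
  }
  fires
}
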