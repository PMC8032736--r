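#' Normalized Burn Ratio of a scene
#'
#' NBR = (B4 - B7) / (B4 + B7) x 1000, the classic Landsat TM/ETM burn index
#' built from near-infrared (band 4) and shortwave-infrared (band 7)
#' reflectance, on the conventional x1000 scale. Pixels where both bands are
#' zero are flagged missing (`NA`).
#'
#' @param scn a [scene()].
#' @return A tibble (`x`, `y`, `nbr`) with NBR in `[-1000, 1000]`, carrying
#'   the scene's `date` and `pixel_size` attributes.
#' @examples
#' s <- scene(matrix(0.3, 2, 2), matrix(0.1, 2, 2), "2000-08-01")
#' compute_nbr(s)  # 500 everywhere
#' @export
compute_nbr <- function(scn) {
  stopifnot(inherits(scn, "bb_scene"))
  tot <- scn$b4 + scn$b7
  nbr <- ifelse(tot > 0, (scn$b4 - scn$b7) / tot * 1000, NA_real_)
  out <- tibble(x = scn$x, y = scn$y, nbr = nbr)
  attr(out, "date") <- attr(scn, "date")
  attr(out, "pixel_size") <- attr(scn, "pixel_size")
  out
}

#' Composite summer NBR for one year
#'
#' Averages per-pixel NBR over all scenes acquired inside the summer window
#' (July 15 to September 15, inclusive, compared as day-of-year) of the given
#' year; scenes outside the window are excluded. Using only late-summer
#' acquisitions maximizes the visibility of fire effects on the forest floor.
#'
#' @param scenes a list of [scene()] objects.
#' @param year calendar year whose summer to composite.
#' @return A tibble (`x`, `y`, `nbr`) of the per-pixel mean, with the scene
#'   `pixel_size` attribute.
#' @section Errors:
#' Throws `"no imagery"` if no scene falls inside the window — callers use
#' this signal to route the fire into the gap-fill path.
#' @export
composite_summer <- function(scenes, year) {
  in_window <- vapply(scenes, function(s) {
    d <- attr(s, "date")
    doy <- day_of_year(d)
    as.integer(format(d, "%Y")) == year &&
      doy >= day_of_year(sprintf("%d-07-15", year)) &&
      doy <= day_of_year(sprintf("%d-09-15", year))
  }, logical(1))
  if (!any(in_window)) abort("no imagery", class = "bb_no_imagery")
  nbrs <- lapply(scenes[in_window], compute_nbr)
  out <- bind_rows(nbrs) %>%
    group_by(.data$x, .data$y) %>%
    summarise(nbr = mean(.data$nbr), .groups = "drop")
  attr(out, "pixel_size") <- attr(scenes[in_window][[1]], "pixel_size")
  out
}

#' Per-pixel dNBR from pre- and post-fire NBR grids
#'
#' dNBR = NBR(pre-fire) - NBR(post-fire), computed from the summer composites
#' of the year before and the year after the fire. Positive values indicate
#' burning; negative values (regrowth or brightening) are retained here and
#' handled downstream by background correction and flooring.
#'
#' @param pre_nbr,post_nbr NBR tibbles (`x`, `y`, `nbr`) on the same grid.
#' @return A tibble (`x`, `y`, `dnbr`).
#' @export
compute_dnbr <- function(pre_nbr, post_nbr) {
  if (nrow(pre_nbr) != nrow(post_nbr) ||
      !all(pre_nbr$x == post_nbr$x & pre_nbr$y == post_nbr$y)) {
    abort("pre and post NBR grids are misaligned")
  }
  out <- tibble(x = pre_nbr$x, y = pre_nbr$y,
                dnbr = pre_nbr$nbr - post_nbr$nbr)
  attr(out, "pixel_size") <- attr(pre_nbr, "pixel_size") %||%
    attr(post_nbr, "pixel_size")
  out
}
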