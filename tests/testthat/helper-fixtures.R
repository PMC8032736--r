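suppressMessages({
  library(dplyr)
  library(tibble)
})

# one shared single-cell world (climatology, forcing, spun-up stand and its
# paired fire / no-fire cohort runs), built lazily and cached for the whole
# test run
.shared_env <- new.env(parent = emptyenv())

shared_world <- function() {
  if (!is.null(.shared_env$world)) return(.shared_env$world)
  params <- ecosys_params()
  cfg <- synth_config(nx = 1, ny = 1, seed = 101)
  forcing <- gen_climate(cfg)
  clim <- climatology(forcing)
  st <- spinup(cohort_state(params = params), clim, params, years = 120)
  nofire <- run_cohort(st, forcing, params)
  fire_runs <- lapply(c(100, 200, 400, 600), function(d) {
    sev <- severity_from_dnbr(tibble(fire_id = 1L, year = 1990L, dnbr = d))
    run_cohort(st, forcing, params, fires = sev)
  })
  names(fire_runs) <- paste0("d", c(100, 200, 400, 600))
  .shared_env$world <- list(params = params, cfg = cfg, forcing = forcing,
                            clim = clim, state = st, nofire = nofire,
                            fire_runs = fire_runs)
  .shared_env$world
}

# independent gap-fill oracle: full sort by |area difference| then fire id
gap_fill_oracle <- function(fires, k = 10L) {
  known <- fires[!is.na(fires$dnbr), ]
  out <- fires$dnbr
  for (i in which(is.na(fires$dnbr))) {
    d <- abs(known$area_km2 - fires$area_km2[i])
    ord <- order(d, known$fire_id)
    out[i] <- mean(known$dnbr[ord][seq_len(min(k, nrow(known)))])
  }
  out
}

# independent cohort-fraction oracle: plain double loop over pixel centres
cohort_fraction_oracle <- function(config, fires, res_km = 1) {
  xs <- seq(res_km / 2, config$nx * config$cell_km, by = res_km)
  ys <- seq(res_km / 2, config$ny * config$cell_km, by = res_km)
  rows <- list()
  for (x in xs) for (y in ys) {
    cell <- (min(config$ny - 1, floor(y / config$cell_km)) * config$nx +
               min(config$nx - 1, floor(x / config$cell_km)) + 1)
    ids <- integer()
    if (nrow(fires)) {
      for (i in order(fires$year, fires$fire_id)) {
        if (x >= fires$x0[i] && x < fires$x1[i] &&
            y >= fires$y0[i] && y < fires$y1[i]) {
          ids <- c(ids, fires$fire_id[i])
        }
      }
    }
    rows[[length(rows) + 1L]] <- tibble(
      cell = as.integer(cell),
      history = paste(ids, collapse = " ")
    )
  }
  bind_rows(rows) %>%
    count(cell, history) %>%
    group_by(cell) %>%
    mutate(frac = n / sum(n)) %>%
    ungroup() %>%
    arrange(cell, history)
}
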