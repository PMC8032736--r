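test_that("cohort dissection handles no-fire, half-cell and overlap cases", {
  cfg <- synth_config(nx = 2, ny = 1, seed = 1)

  none <- build_cohorts(cfg, gen_fire_history(synth_config(fire_rate = 0)))
  expect_equal(nrow(none), 2)
  expect_equal(none$frac, c(1, 1))
  expect_equal(purrr::map_int(none$fires, nrow), c(0L, 0L))

  # one fire covering exactly the left half of cell 1
  half <- tibble(fire_id = 1L, year = 2000L, area_km2 = 25 * 50,
                 x0 = 0, x1 = 25, y0 = 0, y1 = 50, dnbr = 400)
  ch <- build_cohorts(cfg, half)
  c1 <- ch %>% filter(cell == 1)
  expect_equal(nrow(c1), 2)
  expect_equal(sort(c1$frac), c(0.5, 0.5))
  expect_equal(filter(ch, cell == 2)$frac, 1)

  # two partially overlapping fires in different years: 4 cohorts in cell 1
  two <- tibble(fire_id = 1:2, year = c(1995L, 2005L),
                area_km2 = c(400, 400),
                x0 = c(5, 15), x1 = c(25, 35), y0 = c(5, 15),
                y1 = c(25, 35), dnbr = c(300, 500))
  ch2 <- build_cohorts(cfg, two)
  expect_equal(nrow(filter(ch2, cell == 1)), 4)
  reburn <- ch2$fires[purrr::map_int(ch2$fires, nrow) == 2][[1]]
  expect_equal(reburn$year, c(1995L, 2005L))  # history ordered by year

  out <- tibble(fire_id = 1L, year = 2000L, area_km2 = 1,
                x0 = 90, x1 = 120, y0 = 0, y1 = 10, dnbr = 300)
  expect_error(build_cohorts(cfg, out), "outside the grid")
})

test_that("cohort fractions match a pixel-counting oracle on random overlaps", {
  cfg <- synth_config(nx = 2, ny = 2, seed = 1)
  set.seed(31)
  for (i in 1:8) {
    fires <- tibble(
      fire_id = 1:2, year = c(1990L, 2000L), area_km2 = 1,
      x0 = runif(2, 0, 60), y0 = runif(2, 0, 60),
      dnbr = c(250, 450)
    ) %>% mutate(x1 = x0 + runif(2, 10, 40), y1 = y0 + runif(2, 10, 40),
                 x1 = pmin(x1, 100), y1 = pmin(y1, 100),
                 area_km2 = (x1 - x0) * (y1 - y0))
    got <- build_cohorts(cfg, fires, res_km = 1) %>%
      mutate(history = purrr::map_chr(
        fires, ~ paste(.x$fire_id, collapse = " "))) %>%
      select(cell, history, frac) %>%
      arrange(cell, history)
    want <- cohort_fraction_oracle(cfg, fires, res_km = 1) %>%
      select(cell, history, frac)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("regional aggregation weights by area and converts units exactly", {
  cfg <- synth_config(nx = 1, ny = 1, seed = 1)
  mk_series <- function(vals, fracs) {
    purrr::map_dfr(seq_along(vals), function(i) {
      tibble(cell = 1L, cohort_id = i, frac = fracs[i], year = 2000L,
             npp = vals[i], rh = 0, nep = vals[i], emis_total = 0,
             cveg = 0, csoil = 0)
    })
  }
  # equal fractions, values 10 and 20 -> cell mean 15;
  # one 2500 km2 cell: 15 g C m-2 x 2500 km2 x 1e-6 = 0.0375 Tg C
  led <- aggregate_region(mk_series(c(10, 20), c(0.5, 0.5)), cfg)
  expect_equal(led$npp, 15 * 2500 * 1e-6)
  # a 1 g C m-2 flux over one fully forested 50-km cell is 0.0025 Tg C
  led1 <- aggregate_region(mk_series(1, 1), cfg)
  expect_equal(led1$npp, 0.0025)
  # fractions must close
  expect_error(aggregate_region(mk_series(c(1, 2), c(0.6, 0.6)), cfg),
               "sum to 1")
})

test_that("regional totals equal a direct summation oracle on a toy region", {
  w <- shared_world()
  cfg <- synth_config(nx = 3, ny = 1, seed = 3, fire_rate = 0)
  forcing <- gen_climate(cfg)
  cohorts <- tibble(
    cell = c(1L, 1L, 2L, 3L), cohort_id = 1:4,
    frac = c(0.25, 0.75, 1, 1),
    fires = list(
      severity_from_dnbr(tibble(fire_id = 1L, year = 1995L, dnbr = 450)),
      tibble(fire_id = integer(), year = integer(), dnbr = numeric()),
      severity_from_dnbr(tibble(fire_id = 2L, year = 2005L, dnbr = 250)),
      tibble(fire_id = integer(), year = integer(), dnbr = numeric())
    )
  )
  runs <- run_scenario(cohorts, forcing, w$params, with_fire = TRUE,
                       spinup_years = 30)
  forest <- tibble(cell = 1:3, forest_frac = c(1, 0.5, 0))
  ledger <- aggregate_region(runs, cfg, forest)
  # brute force: sum cohort values x cohort area over every cohort
  areas <- cohorts %>%
    left_join(forest, by = "cell") %>%
    mutate(area = frac * forest_frac * cfg$cell_km^2)
  direct <- runs %>%
    left_join(select(areas, cohort_id, area), by = "cohort_id") %>%
    group_by(year) %>%
    summarise(nep = sum(nep * area) * 1e-6,
              emis = sum(emis_total * area) * 1e-6)
  expect_equal(ledger$nep, direct$nep)
  expect_equal(ledger$emis, direct$emis)
  # ledger identity holds every year
  expect_equal(ledger$cbf, ledger$cb - ledger$cum_emis)
})

test_that("scenario runs are order-independent and no-fire ignores events", {
  w <- shared_world()
  cfg <- synth_config(nx = 1, ny = 1, seed = 5, fire_rate = 0)
  forcing <- gen_climate(cfg)
  empty_fires <- tibble(fire_id = integer(), year = integer(),
                        dnbr = numeric())
  sev <- severity_from_dnbr(tibble(fire_id = 1L, year = 2000L, dnbr = 500))
  cohorts <- tibble(cell = 1L, cohort_id = 1:2, frac = c(0.4, 0.6),
                    fires = list(empty_fires, sev))

  with_fire <- run_scenario(cohorts, forcing, w$params, TRUE,
                            spinup_years = 30)
  no_fire <- run_scenario(cohorts, forcing, w$params, FALSE,
                          spinup_years = 30)
  # emissions only in the fire year, only for the burned cohort
  emitting <- with_fire %>% filter(emis_total > 0)
  expect_equal(unique(emitting$year), 2000L)
  expect_equal(unique(emitting$cohort_id), 2L)
  # empty fire list behaves exactly like the no-fire scenario
  expect_identical(filter(with_fire, cohort_id == 1),
                   filter(no_fire, cohort_id == 1))

  # reversing cohort order leaves per-cohort results identical
  rev_runs <- run_scenario(cohorts[2:1, ], forcing, w$params, TRUE,
                           spinup_years = 30)
  expect_equal(
    as.data.frame(arrange(rev_runs, cohort_id, year)),
    as.data.frame(arrange(with_fire, cohort_id, year))
  )
})

test_that("splitting a cohort into identical halves leaves regional totals unchanged", {
  w <- shared_world()
  cfg <- synth_config(nx = 1, ny = 1, seed = 5, fire_rate = 0)
  forcing <- gen_climate(cfg)
  sev <- severity_from_dnbr(tibble(fire_id = 1L, year = 2000L, dnbr = 350))
  one <- tibble(cell = 1L, cohort_id = 1L, frac = 1, fires = list(sev))
  split <- tibble(cell = 1L, cohort_id = 1:2, frac = c(0.5, 0.5),
                  fires = list(sev, sev))
  l1 <- aggregate_region(
    run_scenario(one, forcing, w$params, TRUE, spinup_years = 30), cfg)
  l2 <- aggregate_region(
    run_scenario(split, forcing, w$params, TRUE, spinup_years = 30), cfg)
  expect_equal(as.data.frame(l1), as.data.frame(l2))
})

test_that("carbon-balance bookkeeping closes its identities", {
  bal <- carbon_balance(fire = list(cb = 59.0, emissions = 1769.8),
                        nofire = list(cb = 1030.0, emissions = 0))
  expect_equal(bal$nep_gap, 1030.0 - 59.0)
  expect_equal(bal$reduction, (1030.0 - 59.0) + 1769.8)
  expect_equal(bal$cbf_fire, 59.0 - 1769.8)
  # zero emissions: CBF equals CB
  bal0 <- carbon_balance(fire = list(cb = 12.5, emissions = 0),
                         nofire = list(cb = 12.5, emissions = 0))
  expect_equal(bal0$cbf_fire, bal0$cb_fire)

  expect_equal(annualize(1769.8, 31), 57.1)
  expect_equal(annualize(59.0, 31), 1.9)
  expect_equal(annualize(0, 7), 0)
  expect_error(annualize(10, 0), "positive")
})
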