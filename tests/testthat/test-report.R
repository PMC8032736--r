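test_that("fire-regime summary aggregates and recovers an injected trend", {
  fires <- tibble(fire_id = 1:4, year = c(1990L, 1990L, 1991L, 1991L),
                  area_km2 = c(5, 5, 2, 2), dnbr = c(100, 300, 400, 600))
  reg <- fire_regime_summary(fires)
  # equal areas: area-weighted mean equals the simple mean
  expect_equal(reg$annual$mean_dnbr, c(200, 500))
  expect_equal(reg$annual$n_fires, c(2L, 2L))
  expect_equal(reg$annual$area_km2, c(10, 4))

  flat <- tibble(fire_id = 1:6, year = rep(2000:2002, each = 2),
                 area_km2 = 1, dnbr = rep(c(200, 400), 3))
  expect_equal(glance(fire_regime_summary(flat))$dnbr_trend, 0)

  # +3 dNBR/yr drift injected into a synthetic record
  set.seed(77)
  years <- rep(1986:2016, each = 20)
  drift <- tibble(fire_id = seq_along(years), year = years, area_km2 = 1,
                  dnbr = 250 + 3 * (years - 1986) + rnorm(length(years), 0, 40))
  td <- tidy(fire_regime_summary(drift))
  slope <- td$estimate[td$term == "year"]
  se <- td$std.error[td$term == "year"]
  expect_lt(abs(slope - 3), 3 * se)
  expect_error(fire_regime_summary(tibble()), "empty")
})

test_that("chronosequence reproduces a single cohort's differences exactly", {
  w <- shared_world()
  sev <- severity_from_dnbr(tibble(fire_id = 1L, year = 1990L, dnbr = 400))
  cohorts <- tibble(cell = 1L, cohort_id = 1L, frac = 1, fires = list(sev))
  fire_run <- w$fire_runs$d400 %>%
    mutate(cell = 1L, cohort_id = 1L, frac = 1, .before = 1)
  nofire_run <- w$nofire %>%
    mutate(cell = 1L, cohort_id = 1L, frac = 1, .before = 1)
  chron <- chronosequence(fire_run, nofire_run, cohorts)
  expect_true(all(chron$class == "400-500"))
  expect_equal(sort(unique(chron$years_since_fire)), 0:25)
  npp0 <- chron %>%
    filter(variable == "npp", years_since_fire == 0) %>% pull(diff)
  direct <- (w$nofire$npp - w$fire_runs$d400$npp)[w$nofire$year == 1990]
  expect_equal(npp0, direct)
  # physical diagnostics are reported fire-minus-no-fire (positive = warmer)
  ts1 <- chron %>%
    filter(variable == "tsoil", years_since_fire == 1) %>% pull(diff)
  expect_gt(ts1, 0)
})

test_that("the all-cohort mean is the cohort-count-weighted mixture of class curves", {
  w <- shared_world()
  mk <- function(id, dnbr) {
    severity_from_dnbr(tibble(fire_id = id, year = 1990L, dnbr = dnbr))
  }
  cohorts <- tibble(cell = 1L, cohort_id = 1:3, frac = c(0.5, 0.3, 0.2),
                    fires = list(mk(1L, 150), mk(2L, 150), mk(3L, 450)))
  runs <- function(d) {
    w$fire_runs[[paste0("d", d)]]
  }
  fire_runs <- purrr::map2_dfr(1:3, c(100, 100, 400), function(id, d) {
    mutate(runs(d), cell = 1L, cohort_id = id,
           frac = cohorts$frac[id], .before = 1)
  })
  nofire_runs <- purrr::map_dfr(1:3, function(id) {
    mutate(w$nofire, cell = 1L, cohort_id = id,
           frac = cohorts$frac[id], .before = 1)
  })
  chron <- chronosequence(fire_runs, nofire_runs, cohorts)
  pooled <- chron %>%
    group_by(years_since_fire, variable) %>%
    summarise(mix = sum(diff * n_cohorts) / sum(n_cohorts),
              .groups = "drop")
  all_cohort <- fire_runs %>%
    inner_join(nofire_runs, by = c("cell", "cohort_id", "year"),
               suffix = c("_f", "_nf")) %>%
    mutate(years_since_fire = year - 1990L) %>%
    filter(years_since_fire %in% 0:25) %>%
    group_by(years_since_fire) %>%
    summarise(npp = mean(npp_nf - npp_f), .groups = "drop")
  got <- pooled %>% filter(variable == "npp") %>% arrange(years_since_fire)
  expect_equal(got$mix, all_cohort$npp)
})

test_that("a zero-severity fire has an identically zero chronosequence", {
  w <- shared_world()
  ghost <- tibble(fire_id = 1L, year = 1995L, dnbr = 0,
                  soil_frac = 0, canopy_frac = 0)
  cohorts <- tibble(cell = 1L, cohort_id = 1L, frac = 1,
                    fires = list(ghost))
  fire_run <- run_cohort(w$state, w$forcing, w$params, fires = ghost) %>%
    mutate(cell = 1L, cohort_id = 1L, frac = 1, .before = 1)
  nofire_run <- w$nofire %>%
    mutate(cell = 1L, cohort_id = 1L, frac = 1, .before = 1)
  chron <- chronosequence(fire_run, nofire_run, cohorts)
  expect_true(all(abs(chron$diff) < 1e-9))
})

test_that("emission partition separates soil and vegetation origins by class", {
  w <- shared_world()
  mk <- function(id, dnbr) {
    severity_from_dnbr(tibble(fire_id = id, year = 1990L, dnbr = dnbr))
  }
  dnbrs <- c(100, 200, 400, 600)
  cohorts <- tibble(cell = 1L, cohort_id = 1:4, frac = 0.25,
                    fires = purrr::map2(1:4, dnbrs, mk))
  fire_runs <- purrr::imap_dfr(w$fire_runs, function(run, nm) {
    id <- match(nm, paste0("d", dnbrs))
    mutate(run, cell = 1L, cohort_id = id, frac = 0.25, .before = 1)
  })
  part <- emission_partition(fire_runs, cohorts)
  shares <- part %>%
    filter(measure == "soil_share", years_since_fire == 0) %>%
    arrange(class)
  # soils barely combust below the zero crossing
  expect_equal(shares$value[shares$class %in% c("100-200", "200-300")],
               c(0, 0))
  expect_true(all(shares$value[shares$class %in% c("400-500", ">=600")] > 0))
  # all shares are proportions
  expect_true(all(part$value >= 0 & part$value <= 1, na.rm = TRUE))
  # the direct share declines as post-fire respiration accumulates
  ds <- part %>%
    filter(measure == "direct_share", class == ">=600") %>%
    arrange(years_since_fire)
  expect_true(ds$value[1] > ds$value[26])
})

test_that("partition shares are undefined (not zero) without any emission", {
  runs <- tibble(cell = 1L, cohort_id = 1L, frac = 1,
                 year = 1990:1992, npp = 0, rh = c(0, 5, 5), nep = 0,
                 nmin = 0, emis_veg = 0, emis_soil = 0, emis_total = 0,
                 cveg = 0, csoil = 0, moisture = 0, tsoil = 0, tsf = 0:2)
  cohorts <- tibble(cell = 1L, cohort_id = 1L, frac = 1,
                    fires = list(tibble(fire_id = 1L, year = 1990L,
                                        dnbr = 50)))
  part <- emission_partition(runs, cohorts)
  y0 <- part %>% filter(years_since_fire == 0)
  expect_true(is.na(y0$value[y0$measure == "soil_share"]))
  # with zero accumulated R_H and a soil pulse, the direct soil share is 1
  runs2 <- runs %>% mutate(rh = 0, emis_soil = c(10, 0, 0),
                           emis_total = c(10, 0, 0))
  p2 <- emission_partition(runs2, cohorts)
  expect_equal(
    p2$value[p2$measure == "soil_direct_share" & p2$years_since_fire == 0], 1)
})

test_that("indirect ratio is one when respiration is unaffected and ranks severities", {
  # hand-built paired runs with identical R_H: ratio is exactly 1 always
  base <- tibble(cell = 1L, cohort_id = 1L, frac = 1, year = 1990:1995,
                 npp = 100, rh = 50, nep = 50, nmin = 1,
                 emis_veg = c(200, 0, 0, 0, 0, 0),
                 emis_soil = c(100, 0, 0, 0, 0, 0),
                 emis_total = c(300, 0, 0, 0, 0, 0),
                 cveg = 0, csoil = 0, moisture = 0, tsoil = 0, tsf = 0:5)
  nofire <- base %>% mutate(emis_veg = 0, emis_soil = 0, emis_total = 0)
  cohorts <- tibble(cell = 1L, cohort_id = 1L, frac = 1,
                    fires = list(tibble(fire_id = 1L, year = 1990L,
                                        dnbr = 350)))
  ir <- indirect_ratio(base, nofire, cohorts)
  expect_equal(ir$ratio, rep(1, 6))
  # suppressed post-fire R_H pulls the ratio below 1
  sup <- base %>% mutate(rh = c(50, 30, 30, 30, 30, 30))
  ir2 <- indirect_ratio(sup, nofire, cohorts)
  expect_true(all(ir2$ratio[-1] < 1))

  # simulated cohorts: lower severity keeps higher early ratios
  w <- shared_world()
  mk <- function(id, dnbr) {
    severity_from_dnbr(tibble(fire_id = id, year = 1990L, dnbr = dnbr))
  }
  cohorts2 <- tibble(cell = 1L, cohort_id = 1:2, frac = 0.5,
                     fires = list(mk(1L, 200), mk(2L, 600)))
  fire_runs <- purrr::map2_dfr(1:2, c("d200", "d600"), function(id, nm) {
    mutate(w$fire_runs[[nm]], cell = 1L, cohort_id = id, frac = 0.5,
           .before = 1)
  })
  nofire_runs <- purrr::map_dfr(1:2, function(id) {
    mutate(w$nofire, cell = 1L, cohort_id = id, frac = 0.5, .before = 1)
  })
  ir3 <- indirect_ratio(fire_runs, nofire_runs, cohorts2)
  early <- ir3 %>% filter(years_since_fire %in% 0:3)
  low <- early$ratio[early$class == "200-300"]
  high <- early$ratio[early$class == ">=600"]
  expect_true(all(low > high))
})

test_that("report plots build without error", {
  w <- shared_world()
  fires <- gen_fire_history(synth_config(fire_rate = 5, seed = 2))
  reg <- fire_regime_summary(gap_fill(fires))
  expect_s3_class(autoplot(reg), "ggplot")
  sev <- severity_from_dnbr(tibble(fire_id = 1L, year = 1990L, dnbr = 400))
  cohorts <- tibble(cell = 1L, cohort_id = 1L, frac = 1, fires = list(sev))
  fire_run <- mutate(w$fire_runs$d400, cell = 1L, cohort_id = 1L, frac = 1,
                     .before = 1)
  nofire_run <- mutate(w$nofire, cell = 1L, cohort_id = 1L, frac = 1,
                       .before = 1)
  chron <- chronosequence(fire_run, nofire_run, cohorts)
  expect_s3_class(plot_chronosequence(chron), "ggplot")
})
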