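test_that("deposition generator follows the exponential and is seeded", {
  scn0 <- deposition_scenario(d1900 = 0.5, growth_rate = 0.02, noise_cv = 0,
                              qc_dropout_prob = 0, precip_cv = 0,
                              obs_years = c(1900, 1980))
  g <- gen_deposition_series(scn0, seed = 1)
  dep <- deposition_series(g$records)$deposition
  expect_equal(dep[1], 0.5)                      # reference year
  expect_equal(dep[2], 0.5 * exp(1.6))           # closed form at 1980
  # factorisation identity: 0.1 * conc * precip reproduces deposition
  expect_equal(0.1 * g$records$conc_mg_n_per_l * g$records$precip_cm, dep)

  scn <- deposition_scenario()
  a <- gen_deposition_series(scn, seed = 42)
  b <- gen_deposition_series(scn, seed = 42)
  c <- gen_deposition_series(scn, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$records, c$records))
  expect_error(gen_deposition_series(deposition_scenario(obs_years = integer(0))),
               "empty year range")
})

test_that("sediment-core generator is a CRS forward model", {
  # noise 0: CRS inversion recovers true ages closely over the datable range
  scn <- core_scenario(noise_cv = 0, core_length_cm = 70)
  core <- gen_sediment_core(scn, 2009, seed = 1)
  am <- crs_ages(core$profile, 2009,
                 background_depth = max(core$profile$slice_top_cm))
  truth <- core$truth[seq_len(nrow(am)), ]
  datable <- truth$age_top <= 100
  expect_lt(max(abs(am$date[datable] - truth$date_top[datable])), 0.5)

  # zero radium support: excess equals total
  scn0 <- core_scenario(ra226_level = 0, noise_cv = 0)
  core0 <- gen_sediment_core(scn0, 2009, seed = 1)
  ex <- excess_pb210(core0$profile)
  expect_equal(ex$excess, ex$pb210_total)

  # the slice containing 1963 holds the cs137 maximum
  core1 <- gen_sediment_core(core_scenario(noise_cv = 0), 2009, seed = 1)
  imax <- which.max(core1$profile$cs137)
  date_bot <- 2 * core1$truth$date_mid[imax] - core1$truth$date_top[imax]
  expect_true(date_bot <= 1963 && 1963 <= core1$truth$date_top[imax])

  expect_error(gen_sediment_core(core_scenario(shift_year = 2050), 2009),
               "coring_year")
})

test_that("diatom generator plants a detectable logistic indicator rise", {
  scn <- core_scenario(indicator_background = 0.01, indicator_plateau = 0.4,
                       noise_cv = 0)
  core <- gen_sediment_core(scn, 2009, seed = 2)
  dia <- gen_diatom_core(scn, core$truth, seed = 2)
  expect_true(all(rowSums(dia$counts) >= 500))

  # the deepest slice whose expected proportion crosses max(2*bg, 0.05)
  # brackets the true onset year
  curve <- indicator_curve(core$truth$date_mid, scn)
  k <- max(which(curve >= max(2 * 0.01, 0.05)))
  expect_true(core$truth$date_mid[k + 1] <= scn$shift_year + scn$rise_years)
  expect_true(core$truth$date_mid[k] >= scn$shift_year)

  # null scenario: no shift detected
  null_scn <- core_scenario(indicator_plateau = 0.010001,
                            indicator_background = 0.01)
  dia0 <- gen_diatom_core(null_scn, core$truth, seed = 3)
  am <- crs_ages(core$profile, 2009,
                 background_depth = max(core$profile$slice_top_cm))
  expect_null(detect_shift(dia0$counts, am,
                           taxa = indicator_taxa(extended = TRUE)))
  expect_error(core_scenario(indicator_plateau = 1.2), "plateau")
})

test_that("IER generator inverts the flux formula", {
  rates <- c(nh4_n = 0.8, no3_n = 0.6, so4_s = 1.5, po4_p = 0.01)
  cols <- gen_ier_columns(rates, n_columns = 5, days = 80,
                          funnel_area_cm2 = 120, noise_cv = 0, seed = 1)
  fx <- ier_fluxes(cols)
  summ <- site_summary(fx)
  expect_equal(summ$nh4_n_rate, unname(rates["nh4_n"]))
  expect_equal(summ$no3_n_rate, unname(rates["no3_n"]))
  expect_equal(summ$so4_s_rate, unname(rates["so4_s"]))
  expect_equal(summ$nh4_n_sd, 0)

  # control column mass does not depend on the true rate
  cols2 <- gen_ier_columns(rates * 10, n_columns = 5, days = 80,
                           funnel_area_cm2 = 120, noise_cv = 0, seed = 1)
  expect_equal(cols$nh4_n_mg[cols$role == "control"],
               cols2$nh4_n_mg[cols2$role == "control"])

  # Monte-Carlo: sd of recovered fluxes ~ cv * rate
  sds <- vapply(1:200, function(s) {
    f <- ier_fluxes(gen_ier_columns(rates, n_columns = 5, days = 80,
                                    funnel_area_cm2 = 120, noise_cv = 0.1,
                                    seed = s))
    sd(f$nh4_n)
  }, numeric(1))
  expect_equal(mean(sds), 0.1 * rates[["nh4_n"]], tolerance = 0.1)
  expect_error(gen_ier_columns(rates, days = 0), "days")
})

test_that("water-chemistry generator censors at the detection limit", {
  truth <- data.frame(site = "x", analyte = c("NH4-N", "NO3-N", "TP"),
                      true_value = c(0.003, 0.02, 0.005),
                      detection_limit = c(0.01, 0.01, 0))
  wc <- gen_water_chem(truth)
  expect_equal(wc$qualifier, c("<", "", ""))   # DL 0 never censors
  expect_equal(wc$value, c(NA, 0.02, 0.005))
  expect_error(gen_water_chem(data.frame(site = "x", analyte = "TP",
                                         true_value = -1,
                                         detection_limit = 0)),
               "negative")
})
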