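test_that("excess lead-210 subtracts radium support with quadrature sd", {
  p <- tiny_profile()
  ex <- excess_pb210(p)
  expect_equal(ex$excess, c(500, 250, 100))
  expect_equal(ex$excess_sd, sqrt(p$pb210_sd^2 + p$ra226_sd^2))
  clip <- p
  clip$pb210_total[3] <- 18
  expect_equal(excess_pb210(clip)$excess[3], 0)
  expect_equal(excess_pb210(data.frame(slice_top_cm = 1:3,
                                       pb210_total = c(10, 10, 10),
                                       pb210_sd = 5, ra226 = c(5, 5, 5),
                                       ra226_sd = 3))$excess_sd,
               rep(sqrt(34), 3))
  miss <- p; miss$ra226[2] <- NA
  expect_error(excess_pb210(miss), "slice top 1")
})

test_that("background detection needs all deeper slices at background", {
  mk <- function(excess) {
    n <- length(excess)
    data.frame(site = "x", slice_top_cm = seq_len(n) - 1,
               slice_bottom_cm = seq_len(n), bulk_density_g_cm3 = 0.3,
               pb210_total = 20 + excess, pb210_sd = 1, ra226 = 20,
               ra226_sd = 1, cs137 = 0, cs137_sd = 0)
  }
  # excess reaches zero at slice 8 of 12 and stays there
  p <- mk(c(400, 300, 200, 120, 80, 40, 20, 0, 0, 0, 0, 0))
  expect_equal(detect_background(p), 7)  # slice 8's top depth
  # all slices significantly positive: never converges
  expect_error(detect_background(mk(rep(100, 6))), "deeper core")
  # a single noisy zero above significant excess is not background
  p2 <- mk(c(400, 300, 200, 0, 80, 40, 0, 0, 0))
  expect_equal(detect_background(p2), 6)
  expect_error(detect_background(mk(c(1, 1))), ">= 3")
})

test_that("CRS ages equal the hand-computed log-inventory ratios", {
  p <- tiny_profile()
  am <- crs_ages(p, 2009, background_depth = 3)
  lam <- log(2) / 22.3
  inv <- c(500 * 0.2, 250 * 0.25, 100 * 0.4) / 1000
  a <- rev(cumsum(rev(inv)))
  expect_equal(am$age_yr, log(a[1] / a) / lam)
  expect_equal(am$date[1], 2009)  # surface boundary dates at coring year
  expect_equal(attr(am, "supply_rate_bq_cm2_yr"), lam * a[1])
  # inventory conservation: sum of slice inventories equals A(0)
  expect_equal(sum(inv), attr(am, "total_inventory_bq_cm2"))
  # mass accumulation at the surface boundary: lambda * A0 / C_surface
  expect_equal(am$mass_accum_rate[1], lam * a[1] / (500 / 1000))
})

test_that("the half-inventory depth dates one half-life before coring", {
  p <- data.frame(site = "x", slice_top_cm = c(0, 1, 2),
                  slice_bottom_cm = c(1, 2, 3), bulk_density_g_cm3 = 0.5,
                  pb210_total = c(120, 120, 20), pb210_sd = 0,
                  ra226 = 20, ra226_sd = 0, cs137 = 0, cs137_sd = 0)
  am <- crs_ages(p, 2000, background_depth = 2)
  expect_equal(am$age_yr[2], 22.3)
  expect_equal(am$date[2], 2000 - 22.3)
})

test_that("ages increase strictly with depth wherever excess is positive", {
  core <- gen_sediment_core(core_scenario(), 2009, seed = 7)
  am <- crs_ages(core$profile, 2009)
  pos <- am$excess > 0
  expect_true(all(diff(am$age_yr)[pos[-1]] > 0))
  # dated slices all lie above the detected background
  expect_true(all(am$slice_top_cm < attr(am, "background_depth_cm")))
})

test_that("noisy synthetic cores are dated within a few years at 1970", {
  errs <- vapply(1:20, function(s) {
    core <- gen_sediment_core(core_scenario(), 2009, seed = 100 + s)
    am <- tryCatch(crs_ages(core$profile, 2009), error = function(e) NULL)
    if (is.null(am)) return(NA_real_)
    i <- which.min(abs(core$truth$date_top - 1970))
    row <- match(core$truth$slice_top_cm[i], am$slice_top_cm)
    am$date[row] - core$truth$date_top[i]
  }, numeric(1))
  expect_lt(median(abs(errs), na.rm = TRUE), 3)
})

test_that("Monte-Carlo date uncertainty is zero for exact data and grows with noise", {
  p <- tiny_profile()
  p$pb210_sd <- 0; p$ra226_sd <- 0
  am <- age_uncertainty(p, 2009, n_reps = 50, seed = 1, background_depth = 3)
  expect_equal(am$date_sd, rep(0, 3))
  expect_error(age_uncertainty(p, 2009, n_reps = 1), "n_reps")

  core <- gen_sediment_core(core_scenario(), 2009, seed = 1)
  bg <- detect_background(excess_pb210(core$profile))
  am1 <- age_uncertainty(core$profile, 2009, n_reps = 200, seed = 9,
                         background_depth = bg)
  dbl <- core$profile
  dbl$pb210_sd <- 2 * dbl$pb210_sd
  dbl$ra226_sd <- 2 * dbl$ra226_sd
  am2 <- age_uncertainty(dbl, 2009, n_reps = 200, seed = 9,
                         background_depth = bg)
  # surface boundary is pinned at the coring date in every replicate
  expect_equal(am1$date_sd[1], 0)
  expect_true(all(am2$date_sd[-1] > am1$date_sd[-1]))
  # uncertainty grows with depth on a decaying-excess profile
  expect_equal(cor(seq_along(am1$date_sd), am1$date_sd, method = "spearman"),
               1)
})

test_that("cesium-137 validation finds the 1963 peak within 2 years", {
  core <- gen_sediment_core(core_scenario(noise_cv = 0), 2009, seed = 3)
  am <- crs_ages(core$profile, 2009,
                 background_depth = max(core$profile$slice_top_cm))
  v <- cs137_validate(core$profile, am)
  expect_lt(abs(v$offset_yr), 2)

  mono <- tiny_profile()
  mono$cs137 <- c(30, 20, 10)
  am3 <- crs_ages(mono, 2009, background_depth = 3)
  expect_warning(out <- cs137_validate(mono, am3), "monotone|flat")
  expect_null(out)

  tie <- tiny_profile()
  tie$cs137 <- c(10, 40, 40)
  expect_message(v2 <- cs137_validate(tie, am3), "shallower")
  expect_equal(v2$peak_depth_cm, 1)
})
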