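# Seeded synthetic-data generators.
#
# Every generator is the measurable inverse of a pipeline stage: it simulates
# an input table from known parameters so the stage has a parameter-recovery
# test with ground truth. Noise models: multiplicative lognormal
# (cv-parameterised) for deposition and radionuclide activities (positivity),
# multinomial for valve counts (counting statistics). Default constants are
# chosen to resemble the study regime the package targets: deposition
# growing from ~0.5 to ~2 kg N ha^-1 yr^-1 over 1900-2009, a diatom shift
# near 1970, and a ~120-taxon assemblage in which most taxa are rare.

#' Deposition scenario
#'
#' @param d1900 deposition at the 1900 reference year, kg N ha^-1 yr^-1.
#' @param growth_rate exponential growth rate, yr^-1 (default ln(4)/109,
#'   i.e. a quadrupling over 1900-2009).
#' @param obs_years observed years (default 1980:2009, the monitoring era).
#' @param noise_cv lognormal coefficient of variation of annual deposition.
#' @param qc_dropout_prob probability a year fails QC (default 8/30,
#'   mirroring a typical completeness screen over a 30-yr record).
#' @param precip_cm mean annual precipitation at the lake, cm.
#' @param precip_cv interannual cv of precipitation.
#' @return scenario list.
#' @export
deposition_scenario <- function(d1900 = 0.5, growth_rate = log(4) / 109,
                                obs_years = 1980:2009, noise_cv = 0.2,
                                qc_dropout_prob = 8 / 30, precip_cm = 350,
                                precip_cv = 0.1) {
  if (d1900 <= 0) stop_nlakes("d1900 must be > 0")
  if (noise_cv < 0) stop_nlakes("noise_cv must be >= 0")
  if (qc_dropout_prob < 0 || qc_dropout_prob >= 1)
    stop_nlakes("qc_dropout_prob must be in [0, 1)")
  list(d1900 = d1900, growth_rate = growth_rate, obs_years = obs_years,
       noise_cv = noise_cv, qc_dropout_prob = qc_dropout_prob,
       precip_cm = precip_cm, precip_cv = precip_cv)
}

#' Generate an annual deposition series with known truth
#'
#' Deposition follows \code{d1900 * exp(growth_rate * (year - 1900))} times
#' lognormal noise; precipitation and concentration columns are factorised so
#' that \code{0.1 * conc * precip} reproduces the deposition value exactly.
#'
#' @param scenario a \code{\link{deposition_scenario}}.
#' @param seed RNG seed.
#' @return list with \code{records} (a \code{deposition_series} data frame)
#'   and \code{truth} (\code{d1900}, \code{growth_rate}, per-year true and
#'   realised deposition).
#' @export
gen_deposition_series <- function(scenario = deposition_scenario(),
                                  seed = NULL) {
  years <- scenario$obs_years
  if (length(years) == 0) stop_nlakes("gen_deposition_series: empty year range")
  with_seed(seed, {
    n <- length(years)
    true_dep <- scenario$d1900 * exp(scenario$growth_rate * (years - 1900))
    dep <- true_dep * rlnorm_cv(n, scenario$noise_cv)
    precip <- scenario$precip_cm * rlnorm_cv(n, scenario$precip_cv)
    conc <- dep / (0.1 * precip)
    qc <- stats::rbinom(n, 1, 1 - scenario$qc_dropout_prob)
    list(
      records = data.frame(year = years, precip_cm = precip,
                           conc_mg_n_per_l = conc, qc_pass = qc),
      truth = list(d1900 = scenario$d1900,
                   growth_rate = scenario$growth_rate,
                   deposition_true = stats::setNames(true_dep, years),
                   deposition_realised = stats::setNames(dep, years))
    )
  })
}

#' Sediment-core scenario
#'
#' Constant supply of excess lead-210, constant mass accumulation, constant
#' radium support, a Gaussian cesium-137 fallout pulse centred on 1963 (3-yr
#' sd in deposition-year space; only its argmax is used downstream), and a
#' logistic diatom indicator rise starting at \code{shift_year}.
#'
#' @param supply_flux excess 210Pb supply, Bq cm^-2 yr^-1.
#' @param mass_accumulation g cm^-2 yr^-1.
#' @param bulk_density dry bulk density, g cm^-3.
#' @param ra226_level supported activity, Bq kg^-1.
#' @param noise_cv lognormal cv of measured activities.
#' @param cs137_peak_year fallout maximum year.
#' @param cs137_peak_bq_kg pulse amplitude, Bq kg^-1.
#' @param shift_year onset year of the diatom indicator increase.
#' @param indicator_background combined indicator proportion before the
#'   shift.
#' @param indicator_plateau combined indicator proportion reached after the
#'   rise (< 1).
#' @param rise_years duration of the rise from onset to plateau.
#' @param n_taxa assemblage richness (most taxa rare).
#' @param valves_per_sample valves identified per slice (>= 500).
#' @param core_length_cm simulated core length.
#' @param slice_fine_cm slice thickness above \code{fine_to_cm}.
#' @param fine_to_cm depth where sectioning coarsens to 1 cm.
#' @return scenario list.
#' @export
core_scenario <- function(supply_flux = 0.015, mass_accumulation = 0.065,
                          bulk_density = 0.25, ra226_level = 30,
                          noise_cv = 0.05, cs137_peak_year = 1963,
                          cs137_peak_bq_kg = 60, shift_year = 1970,
                          indicator_background = 0.01,
                          indicator_plateau = 0.5, rise_years = 10,
                          n_taxa = 120, valves_per_sample = 500,
                          core_length_cm = 45, slice_fine_cm = 0.5,
                          fine_to_cm = 10) {
  if (supply_flux <= 0) stop_nlakes("supply_flux must be > 0")
  if (mass_accumulation <= 0) stop_nlakes("mass_accumulation must be > 0")
  if (valves_per_sample < 500)
    stop_nlakes("valves_per_sample must be >= 500 for analysis-grade samples")
  if (indicator_plateau >= 1) stop_nlakes("plateau proportion must be < 1")
  list(supply_flux = supply_flux, mass_accumulation = mass_accumulation,
       bulk_density = bulk_density, ra226_level = ra226_level,
       noise_cv = noise_cv, cs137_peak_year = cs137_peak_year,
       cs137_peak_bq_kg = cs137_peak_bq_kg, shift_year = shift_year,
       indicator_background = indicator_background,
       indicator_plateau = indicator_plateau, rise_years = rise_years,
       n_taxa = n_taxa, valves_per_sample = valves_per_sample,
       core_length_cm = core_length_cm, slice_fine_cm = slice_fine_cm,
       fine_to_cm = fine_to_cm)
}

.slice_boundaries <- function(scenario) {
  fine <- seq(0, scenario$fine_to_cm, by = scenario$slice_fine_cm)
  coarse <- seq(scenario$fine_to_cm + 1, scenario$core_length_cm, by = 1)
  unique(c(fine, coarse))
}

#' Generate a sediment core under constant supply
#'
#' Forward-simulates the CRS model: the excess activity of the slice spanning
#' ages [t1, t2] is the decayed inventory deposited in that interval divided
#' by the slice mass; total 210Pb adds the radium-supported level; measured
#' activities get multiplicative lognormal noise with reported 1-sd columns.
#'
#' @param scenario a \code{\link{core_scenario}}.
#' @param coring_year calendar year of coring.
#' @param seed RNG seed.
#' @return list with \code{profile} (a \code{sediment} data frame) and
#'   \code{truth} (per-slice true boundary ages/dates and the scenario
#'   parameters).
#' @export
gen_sediment_core <- function(scenario = core_scenario(), coring_year = 2009,
                              seed = NULL) {
  if (coring_year < scenario$cs137_peak_year ||
      coring_year < scenario$shift_year)
    stop_nlakes("gen_sediment_core: coring_year precedes a simulated event year")
  bounds <- .slice_boundaries(scenario)
  top <- utils::head(bounds, -1)
  bot <- bounds[-1]
  rho <- scenario$bulk_density
  r <- scenario$mass_accumulation
  lam <- pb210_lambda()
  t_top <- rho * top / r              # true age at each slice top, yr
  t_bot <- rho * bot / r
  # inventory deposited in [t1, t2] and already decayed: (P/lam)(e^-l t1 - e^-l t2)
  inv <- (scenario$supply_flux / lam) * (exp(-lam * t_top) - exp(-lam * t_bot))
  mass <- rho * (bot - top)                         # g cm^-2
  excess_true <- inv / mass * 1000                  # Bq kg^-1
  year_mid <- coring_year - (t_top + t_bot) / 2
  cs_true <- scenario$cs137_peak_bq_kg *
    exp(-(year_mid - scenario$cs137_peak_year)^2 / (2 * 3^2))
  with_seed(seed, {
    n <- length(top)
    cv <- scenario$noise_cv
    total_true <- excess_true + scenario$ra226_level
    profile <- data.frame(
      site = "synthetic",
      slice_top_cm = top, slice_bottom_cm = bot,
      bulk_density_g_cm3 = rho,
      pb210_total = total_true * rlnorm_cv(n, cv),
      pb210_sd = cv * total_true,
      ra226 = scenario$ra226_level * rlnorm_cv(n, cv),
      ra226_sd = cv * scenario$ra226_level,
      cs137 = cs_true * rlnorm_cv(n, cv),
      cs137_sd = cv * cs_true
    )
    truth <- data.frame(slice_top_cm = top, slice_bottom_cm = bot,
                        age_top = t_top,
                        date_top = coring_year - t_top,
                        date_mid = year_mid,
                        excess_true = excess_true)
    list(profile = profile, truth = truth,
         params = scenario, coring_year = coring_year)
  })
}

# smoothstep: 0 at x<=0, 1 at x>=1, C1-continuous in between
.smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^2 * (3 - 2 * x)
}

#' Expected indicator proportion through time
#'
#' Background before \code{shift_year}, then a smooth logistic-like rise to
#' the plateau over \code{rise_years}.
#'
#' @param year calendar years.
#' @param scenario a \code{\link{core_scenario}}.
#' @return expected combined indicator proportion.
#' @export
indicator_curve <- function(year, scenario) {
  bg <- scenario$indicator_background
  bg + (scenario$indicator_plateau - bg) *
    .smoothstep((year - scenario$shift_year) / scenario$rise_years)
}

#' Generate a diatom count matrix with a known shift
#'
#' Baseline composition is a geometric-series rank abundance over
#' \code{n_taxa} taxa (most rare); the indicator taxa share the expected
#' indicator proportion from \code{\link{indicator_curve}} and the remaining
#' taxa are rescaled to fill the rest. Counts are multinomial with
#' \code{valves_per_sample} valves per slice.
#'
#' @param scenario a \code{\link{core_scenario}}.
#' @param age_table data frame with \code{slice_top_cm} and a date column
#'   (\code{date_mid} preferred, else \code{date}) giving each slice's age;
#'   typically the \code{truth} of \code{\link{gen_sediment_core}} or a CRS
#'   age model.
#' @param seed RNG seed.
#' @param indicators indicator taxon names to plant (default the extended
#'   set).
#' @return list with \code{counts} (slice-by-taxon matrix, rows named by
#'   depth) and \code{truth} (\code{shift_year}, per-slice expected indicator
#'   proportion).
#' @export
gen_diatom_core <- function(scenario = core_scenario(), age_table,
                            seed = NULL,
                            indicators = indicator_taxa(extended = TRUE)[
                              c(1, 3)]) {
  if (scenario$indicator_plateau >= 1)
    stop_nlakes("plateau proportion must be < 1")
  dates <- age_table$date_mid %||% age_table$date
  if (is.null(dates)) stop_nlakes("gen_diatom_core: age_table needs dates")
  depths <- age_table$slice_top_cm
  n_bg <- scenario$n_taxa
  # geometric-series rank abundance for the background flora (k chosen so
  # the few dominant taxa hold tens of percent and the tail is rare)
  k <- 0.12
  base_p <- k * (1 - k)^(seq_len(n_bg) - 1)
  base_p <- base_p / sum(base_p)
  bg_names <- sprintf("taxon_%03d", seq_len(n_bg))
  with_seed(seed, {
    p_ind <- indicator_curve(dates, scenario)
    rows <- lapply(seq_along(dates), function(i) {
      ind_share <- rep(p_ind[i] / length(indicators), length(indicators))
      probs <- c(ind_share, base_p * (1 - p_ind[i]))
      stats::rmultinom(1, scenario$valves_per_sample, probs)[, 1]
    })
    counts <- do.call(rbind, rows)
    dimnames(counts) <- list(format(depths, trim = TRUE),
                             c(indicators, bg_names))
    list(counts = counts,
         truth = list(shift_year = scenario$shift_year,
                      expected_indicator = stats::setNames(p_ind,
                                                           format(depths))))
  })
}

#' Generate IER collector columns with known deposition rates
#'
#' Extract masses are back-computed from the true flux via the flux formula,
#' then blank and control contributions are added so the correction pipeline
#' recovers the truth: with \code{noise_cv = 0} the site mean flux equals
#' \code{true_rate} exactly.
#'
#' @param true_rate named vector of true fluxes (kg ha^-1 yr^-1) for
#'   \code{nh4_n}, \code{no3_n}, \code{so4_s}, \code{po4_p}.
#' @param n_columns number of active columns (>= 1; five is the field
#'   protocol).
#' @param days days deployed.
#' @param funnel_area_cm2 funnel area, cm^2.
#' @param noise_cv lognormal cv of extract masses.
#' @param seed RNG seed.
#' @param site site label.
#' @param blank_mass background mass on blank columns, mg.
#' @param control_release NH4 release from the capped control column, mg.
#' @return an \code{ier_columns} data frame (active columns + one control +
#'   one field and one lab blank).
#' @export
gen_ier_columns <- function(true_rate = c(nh4_n = 0.5, no3_n = 0.5,
                                          so4_s = 1.5, po4_p = 0.01),
                            n_columns = 5, days = 75, funnel_area_cm2 = 100,
                            noise_cv = 0.1, seed = NULL, site = "synthetic",
                            blank_mass = 0.01, control_release = 0.02) {
  if (n_columns < 1) stop_nlakes("n_columns must be >= 1")
  if (days <= 0) stop_nlakes("days must be > 0")
  with_seed(seed, {
    # invert rate = (mass/area) * 100 * (365.25/days)
    mass_true <- true_rate * funnel_area_cm2 * days / (100 * 365.25)
    mk_row <- function(id, role, masses) {
      data.frame(site = site, column_id = id, role = role,
                 days_deployed = days, funnel_area_cm2 = funnel_area_cm2,
                 nh4_n_mg = masses[["nh4_n"]], no3_n_mg = masses[["no3_n"]],
                 so4_s_mg = masses[["so4_s"]], po4_p_mg = masses[["po4_p"]])
    }
    active <- do.call(rbind, lapply(seq_len(n_columns), function(i) {
      noisy <- mass_true * rlnorm_cv(length(mass_true), noise_cv)
      noisy["nh4_n"] <- noisy[["nh4_n"]] + control_release + blank_mass
      noisy[c("no3_n", "so4_s", "po4_p")] <-
        noisy[c("no3_n", "so4_s", "po4_p")] + blank_mass
      mk_row(sprintf("%s_A%d", site, i), "active", as.list(noisy))
    }))
    ctrl <- mk_row(paste0(site, "_C"), "control",
                   list(nh4_n = control_release, no3_n = 0, so4_s = 0,
                        po4_p = 0))
    blank <- list(nh4_n = blank_mass, no3_n = blank_mass, so4_s = blank_mass,
                  po4_p = blank_mass)
    rbind(active, ctrl,
          mk_row(paste0(site, "_FB"), "field_blank", blank),
          mk_row(paste0(site, "_LB"), "lab_blank", blank))
  })
}

#' Generate censored water-chemistry records
#'
#' Values below their detection limit are emitted censored (qualifier
#' \code{"<"}, value missing); others plain. A detection limit of zero never
#' censors.
#'
#' @param truth data frame with \code{site}, \code{analyte},
#'   \code{true_value}, \code{detection_limit}.
#' @param date sample date string.
#' @return a \code{water_chem} data frame.
#' @export
gen_water_chem <- function(truth, date = "2009-09-01") {
  if (any(truth$true_value < 0))
    stop_nlakes("gen_water_chem: negative concentration")
  cen <- truth$detection_limit > 0 & truth$true_value < truth$detection_limit
  data.frame(site = truth$site, date = date, analyte = truth$analyte,
             value = ifelse(cen, NA_real_, truth$true_value),
             qualifier = ifelse(cen, "<", ""),
             detection_limit = truth$detection_limit)
}
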