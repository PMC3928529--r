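# Constant-rate-of-supply (CRS) lead-210 geochronology.
#
# Total 210Pb in a sediment slice has two pools: a parent-supported pool in
# secular equilibrium with 226Ra, and the unsupported ("excess") pool
# delivered from the atmosphere, which decays with a ~22.3-yr half-life after
# burial. The CRS model assumes a constant areal supply of excess 210Pb, so
# the age at depth z follows from cumulative inventories:
#   t(z) = (1/lambda) * ln(A(0) / A(z)),
# where A(z) is the excess inventory (Bq cm^-2) below z and A(0) the total.
# Dates are assigned at slice top boundaries (inventory-below-depth is a
# boundary quantity); mid-slice dates are also reported for point markers
# such as the 1963 137Cs peak.

#' Decay constant for lead-210
#'
#' @param half_life half-life in years (default 22.3; the literature uses
#'   22.26--22.3).
#' @return decay constant, yr^-1.
#' @export
pb210_lambda <- function(half_life = 22.3) log(2) / half_life

#' Excess (unsupported) lead-210
#'
#' \code{excess = pb210_total - ra226}, clipped at zero; standard deviations
#' propagate in quadrature.
#'
#' @param profile a \code{sediment} data frame (one site, slices ordered by
#'   depth; see \code{\link{read_table}}).
#' @return \code{profile} with columns \code{excess} and \code{excess_sd}
#'   added (Bq kg^-1).
#' @export
excess_pb210 <- function(profile) {
  need <- c("pb210_total", "ra226")
  for (col in need) {
    bad <- which(is.na(profile[[col]]))
    if (length(bad) > 0)
      stop_nlakes(sprintf("excess_pb210: missing %s at slice top %s cm",
                          col, profile$slice_top_cm[bad[1]]))
  }
  profile$excess <- pmax(profile$pb210_total - profile$ra226, 0)
  sd_pb <- if (is.null(profile$pb210_sd)) 0 else profile$pb210_sd
  sd_ra <- if (is.null(profile$ra226_sd)) 0 else profile$ra226_sd
  profile$excess_sd <- sqrt(sd_pb^2 + sd_ra^2)
  profile
}

#' Detect the excess-lead background depth
#'
#' Background is reached where the total 210Pb and 226Ra profiles converge.
#' The rule: the shallowest slice below which (inclusive) every slice's
#' excess is indistinguishable from zero, by default below its counting
#' detection limit of \code{sd_mult = 3} times its propagated 1-sd
#' uncertainty (the usual counting-statistics convention; a 1-sd threshold
#' would reject a truly background slice a third of the time and the
#' every-deeper-slice requirement would then almost never hold on a long
#' background tail).
#'
#' @param profile sediment profile with \code{excess}/\code{excess_sd}
#'   columns (see \code{\link{excess_pb210}}; computed if absent).
#' @param tolerance optional absolute tolerance (Bq kg^-1) overriding the
#'   sd-based rule.
#' @param sd_mult multiple of the per-slice excess sd used as the
#'   indistinguishability threshold.
#' @return background depth, cm (the qualifying slice's top).
#' @export
detect_background <- function(profile, tolerance = NULL, sd_mult = 3) {
  if (!"excess" %in% names(profile)) profile <- excess_pb210(profile)
  n <- nrow(profile)
  if (n < 3) stop_nlakes("detect_background: need >= 3 slices")
  tol <- if (is.null(tolerance)) sd_mult * profile$excess_sd
         else rep_len(tolerance, n)
  at_bg <- profile$excess < pmax(tol, .Machine$double.eps)
  # all slices from i downward must be at background
  ok <- rev(cumprod(rev(at_bg))) == 1
  if (!any(ok))
    stop_nlakes("detect_background: excess 210Pb never reaches background; a deeper core is needed")
  profile$slice_top_cm[which(ok)[1]]
}

#' Constant-rate-of-supply ages
#'
#' Computes per-slice areal mass (bulk density x thickness), cumulative
#' excess inventories below each slice boundary, CRS ages and dates, the
#' supply rate \code{lambda * A(0)}, and mass accumulation rates
#' \code{lambda * A(z) / C(z)}.
#'
#' @param profile a \code{sediment} data frame for one site, slices
#'   contiguous and ordered by increasing depth.
#' @param coring_year calendar year of core collection (date at depth 0).
#' @param half_life lead-210 half-life, years.
#' @param background_depth cm; detected with \code{\link{detect_background}}
#'   when NULL.
#' @return an age model data frame (class \code{nlakes_age_model}) with one
#'   row per dated slice: \code{slice_top_cm}, \code{slice_bottom_cm},
#'   \code{age_yr} and \code{date} at the slice top, \code{date_mid}
#'   (mid-slice), \code{mass_accum_rate} (g cm^-2 yr^-1), \code{excess}
#'   (Bq kg^-1). Attributes: \code{background_depth_cm},
#'   \code{supply_rate_bq_cm2_yr}, \code{total_inventory_bq_cm2},
#'   \code{coring_year}, \code{half_life}.
#' @export
crs_ages <- function(profile, coring_year, half_life = 22.3,
                     background_depth = NULL) {
  if (!"excess" %in% names(profile)) profile <- excess_pb210(profile)
  profile <- profile[order(profile$slice_top_cm), , drop = FALSE]
  if (any(profile$bulk_density_g_cm3 <= 0))
    stop_nlakes("crs_ages: bulk densities must be > 0")
  if (is.null(background_depth))
    background_depth <- detect_background(profile)
  lam <- pb210_lambda(half_life)
  dated <- profile$slice_top_cm < background_depth
  if (!any(dated)) stop_nlakes("crs_ages: no slices above background")
  d <- profile[dated, , drop = FALSE]
  thick <- d$slice_bottom_cm - d$slice_top_cm
  mass <- d$bulk_density_g_cm3 * thick                  # g cm^-2
  slice_inv <- d$excess * mass / 1000                   # Bq cm^-2 (kg -> g)
  a_top <- rev(cumsum(rev(slice_inv)))                  # inventory below top
  # a_top is non-increasing with depth, so zero-inventory slices form a
  # trailing run: they carry no excess and belong to the background zone
  keep <- a_top > 0
  if (!any(keep))
    stop_nlakes("crs_ages: zero inventory above background; age undefined")
  if (!all(keep)) {
    background_depth <- d$slice_top_cm[which(!keep)[1]]
    d <- d[keep, , drop = FALSE]
    a_top <- a_top[keep]
    message(sprintf(
      "crs_ages: %d zero-inventory slice(s) folded into background (now %s cm)",
      sum(!keep), format(background_depth)))
  }
  a_bot <- c(a_top[-1], 0)                              # below bottom
  a0 <- a_top[1]
  age_top <- log(a0 / a_top) / lam
  # bottom boundary of the deepest dated slice sits at background: undefined
  age_bot <- ifelse(a_bot > 0, log(a0 / a_bot) / lam, NA_real_)
  out <- data.frame(
    slice_top_cm = d$slice_top_cm,
    slice_bottom_cm = d$slice_bottom_cm,
    age_yr = age_top,
    date = coring_year - age_top,
    date_mid = coring_year - (age_top + age_bot) / 2,
    mass_accum_rate = ifelse(d$excess > 0, lam * a_top / (d$excess / 1000),
                             NA_real_),
    excess = d$excess
  )
  structure(out,
            class = c("nlakes_age_model", "data.frame"),
            background_depth_cm = background_depth,
            supply_rate_bq_cm2_yr = lam * a0,
            total_inventory_bq_cm2 = a0,
            coring_year = coring_year,
            half_life = half_life)
}

#' Monte-Carlo date uncertainty for a CRS age model
#'
#' Resamples slice activities from Gaussians truncated at zero (sd from the
#' profile's counting-uncertainty columns), reruns the CRS computation with
#' the background depth held fixed, and reports the per-slice standard
#' deviation of the dates. On decaying-excess profiles the sd grows with
#' depth because deep inventories are small relative to their noise.
#'
#' @param profile sediment profile (one site).
#' @param coring_year calendar year of coring.
#' @param n_reps number of Monte-Carlo replicates (>= 2; default 1000).
#' @param seed RNG seed.
#' @param half_life lead-210 half-life, years.
#' @param background_depth cm; detected from the unperturbed profile when
#'   NULL.
#' @return the age model of the unperturbed profile with a \code{date_sd}
#'   column added (years).
#' @export
age_uncertainty <- function(profile, coring_year, n_reps = 1000, seed = NULL,
                            half_life = 22.3, background_depth = NULL) {
  if (n_reps < 2) stop_nlakes("age_uncertainty: n_reps must be >= 2")
  profile <- excess_pb210(profile)
  if (is.null(background_depth))
    background_depth <- detect_background(profile)
  base <- crs_ages(profile, coring_year, half_life, background_depth)
  with_seed(seed, {
    n <- nrow(profile)
    dates <- matrix(NA_real_, nrow = n_reps, ncol = nrow(base))
    for (r in seq_len(n_reps)) {
      pert <- profile
      pert$pb210_total <- pmax(stats::rnorm(n, profile$pb210_total,
                                            profile$pb210_sd), 0)
      pert$ra226 <- pmax(stats::rnorm(n, profile$ra226, profile$ra226_sd), 0)
      pert$excess <- NULL
      am <- tryCatch(
        crs_ages(pert, coring_year, half_life, background_depth),
        error = function(e) NULL)
      if (!is.null(am) && nrow(am) == nrow(base))
        dates[r, ] <- am$date
    }
    base$date_sd <- apply(dates, 2, stats::sd, na.rm = TRUE)
  })
  base
}

#' Validate a CRS chronology against the 1963 cesium-137 peak
#'
#' The sediment 137Cs maximum marks 1963, the height of atmospheric nuclear
#' testing. The offset between the CRS date at the peak and 1963 measures the
#' chronology's accuracy.
#'
#' @param profile sediment profile with a \code{cs137} column.
#' @param age_model output of \code{\link{crs_ages}} or
#'   \code{\link{age_uncertainty}}.
#' @param peak_year reference year of the fallout maximum (default 1963).
#' @return list with \code{peak_depth_cm}, \code{crs_date_at_peak} (mid-slice
#'   date), \code{offset_yr}; or NULL (with a warning) when the 137Cs profile
#'   has no peak.
#' @export
cs137_validate <- function(profile, age_model, peak_year = 1963) {
  cs <- profile$cs137
  if (all(is.na(cs)) || length(unique(cs[!is.na(cs)])) == 1) {
    warning("cs137_validate: flat 137Cs profile; no peak to validate against")
    return(NULL)
  }
  # monotone profiles have their max at an end slice: not a depositional peak
  imax <- which(cs == max(cs, na.rm = TRUE))
  if (length(imax) > 1) {
    message("cs137_validate: tie in 137Cs maximum; using the shallower slice")
    imax <- imax[1]
  }
  if (imax == 1 || imax == length(cs)) {
    interior <- cs[-c(1, length(cs))]
    if (all(cs[imax] >= interior, na.rm = TRUE) &&
        (all(diff(cs) <= 0, na.rm = TRUE) || all(diff(cs) >= 0, na.rm = TRUE))) {
      warning("cs137_validate: monotone 137Cs profile; no peak to validate against")
      return(NULL)
    }
  }
  depth <- profile$slice_top_cm[imax]
  row <- which(age_model$slice_top_cm == depth)
  if (length(row) == 0)
    stop_nlakes("cs137_validate: 137Cs peak lies below the dated interval")
  at_peak <- age_model$date_mid[row]
  if (is.na(at_peak)) at_peak <- age_model$date[row]
  list(peak_depth_cm = depth, crs_date_at_peak = at_peak,
       offset_yr = at_peak - peak_year)
}
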