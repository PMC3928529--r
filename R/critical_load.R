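# Elevation-corrected deposition reconstruction, exponential trend fitting
# with an optional preindustrial anchor, and hindcasting to the diatom shift
# window.
#
# Wet deposition monitoring stations sit at low elevation; the lake-level
# deposition series is reconstructed by multiplying an elevation-specific
# annual precipitation (e.g. a PRISM extraction at the lake) by the annual
# precipitation-weighted inorganic-N concentration from the nearest station:
# deposition [kg N ha^-1 yr^-1] = 0.1 * conc [mg/L] * precip [cm], since
# 1 cm of water over 1 ha is 1e5 L and mg -> kg is 1e-6.

#' Elevation-corrected wet deposition
#'
#' @param precip_cm annual precipitation at the lake, cm.
#' @param conc_mg_l annual precipitation-weighted inorganic N concentration,
#'   mg N/L.
#' @return deposition, kg N ha^-1 yr^-1.
#' @export
#' @examples
#' elevation_corrected_deposition(350, 0.2)  # 7 kg N ha^-1 yr^-1
elevation_corrected_deposition <- function(precip_cm, conc_mg_l) {
  check_nonneg(precip_cm, "precip_cm")
  check_nonneg(conc_mg_l, "conc_mg_l")
  0.1 * conc_mg_l * precip_cm
}

#' Prepare an annual deposition series
#'
#' Adds the computed deposition column and drops QC-failing years.
#'
#' @param records a \code{deposition_series} data frame (see
#'   \code{\link{read_table}}).
#' @param qc_only drop rows with \code{qc_pass == 0} (default TRUE).
#' @return the records with a \code{deposition} column.
#' @export
deposition_series <- function(records, qc_only = TRUE) {
  records$deposition <- elevation_corrected_deposition(records$precip_cm,
                                                       records$conc_mg_n_per_l)
  if (qc_only) records <- records[records$qc_pass == 1, , drop = FALSE]
  records
}

#' Fit an exponential trend to annual deposition
#'
#' Ordinary least squares of \code{ln(deposition)} on \code{year - 1900}.
#' The preindustrial anchor, when supplied, enters as one ordinary
#' observation (by default 0.5 kg N ha^-1 yr^-1 at 1900, the value used for
#' Western-US hindcasts). A nonlinear natural-scale fit is available via
#' \code{scale = "natural"}.
#'
#' @param records data frame with \code{year} and \code{deposition} columns
#'   (QC-passing rows only; see \code{\link{deposition_series}}).
#' @param anchor optional \code{list(year =, value =)} anchor point.
#' @param ref_year reference year for the parameterisation (default 1900).
#' @param scale \code{"log"} (default, deterministic OLS) or
#'   \code{"natural"} (nonlinear least squares started from the log fit).
#' @return list of class \code{exponential_fit}: \code{d_ref} (deposition at
#'   \code{ref_year}), \code{growth_rate} (yr^-1), \code{anchored},
#'   \code{anchor}, \code{n_obs}, \code{ref_year}, \code{residual_sd} (log
#'   scale), \code{scale}.
#' @export
fit_exponential <- function(records, anchor = NULL, ref_year = 1900,
                            scale = c("log", "natural")) {
  scale <- match.arg(scale)
  year <- records$year
  dep <- records$deposition
  keep <- !is.na(dep) & !is.na(year)
  year <- year[keep]; dep <- dep[keep]
  if (length(dep) < 3) stop_nlakes("fit_exponential: need >= 3 observations")
  if (!is.null(anchor)) {
    year <- c(year, anchor$year)
    dep <- c(dep, anchor$value)
  }
  if (any(dep <= 0))
    stop_nlakes("fit_exponential: zero or negative deposition; log fit undefined")
  x <- year - ref_year
  fit <- stats::lm(log(dep) ~ x)
  co <- stats::coef(fit)
  d_ref <- exp(unname(co[1]))
  rate <- unname(co[2])
  if (scale == "natural") {
    # scaleOffset keeps convergence well-defined on (near-)exact data
    nls_fit <- stats::nls(dep ~ a * exp(b * x),
                          start = list(a = d_ref, b = rate),
                          control = stats::nls.control(maxiter = 200,
                                                       scaleOffset = 1))
    co <- stats::coef(nls_fit)
    d_ref <- unname(co["a"]); rate <- unname(co["b"])
  }
  structure(list(d_ref = d_ref, growth_rate = rate,
                 anchored = !is.null(anchor), anchor = anchor,
                 n_obs = length(dep), ref_year = ref_year,
                 residual_sd = stats::sd(stats::residuals(fit)),
                 scale = scale),
            class = "exponential_fit")
}

#' Evaluate an exponential fit at given years
#'
#' @param fit an \code{exponential_fit}.
#' @param years calendar years.
#' @return fitted deposition, kg N ha^-1 yr^-1.
#' @export
predict_deposition <- function(fit, years) {
  fit$d_ref * exp(fit$growth_rate * (years - fit$ref_year))
}

#' Hindcast a critical load over a shift window
#'
#' Evaluates the fitted deposition curve at each integer year of the diatom
#' shift window and reports the mean and standard deviation of those values
#' as the critical-load estimate.
#'
#' @param fit an \code{exponential_fit}.
#' @param window numeric length-2 year range (e.g. \code{c(1969, 1975)}), or
#'   a vector of years.
#' @return list of class \code{critical_load}: \code{window}, \code{mean},
#'   \code{sd}, \code{anchored}, \code{values} (per-year).
#' @export
estimate_critical_load <- function(fit, window) {
  if (length(window) == 0 || anyNA(window))
    stop_nlakes("estimate_critical_load: empty window")
  years <- if (length(window) == 2) seq(floor(window[1]), floor(window[2]))
           else sort(unique(floor(window)))
  if (length(years) == 0)
    stop_nlakes("estimate_critical_load: empty window")
  if (min(years) < fit$ref_year)
    stop_nlakes(sprintf("estimate_critical_load: window precedes reference year %d",
                        fit$ref_year))
  vals <- predict_deposition(fit, years)
  structure(list(window = range(years), mean = mean(vals),
                 sd = if (length(vals) > 1) stats::sd(vals) else 0,
                 anchored = fit$anchored,
                 values = stats::setNames(vals, years)),
            class = "critical_load")
}

#' 95 percent lower confidence limit of mean deposition
#'
#' \code{mean - t * s / sqrt(n)} with the Student-t quantile; by default the
#' lower bound of the two-sided 95\% interval (\code{t_{0.975, n-1}}), with a
#' one-sided bound (\code{t_{0.95, n-1}}) available. Used as a consistency
#' check: when a shift predates the monitoring record, every annual value
#' should already exceed the critical load, so this limit bounds it from
#' above.
#'
#' @param depositions QC-passing annual deposition values (n >= 2).
#' @param one_sided use the one-sided 95\% bound.
#' @return kg N ha^-1 yr^-1.
#' @export
lcl95 <- function(depositions, one_sided = FALSE) {
  n <- length(depositions)
  if (n < 2) stop_nlakes("lcl95: need >= 2 values")
  p <- if (one_sided) 0.95 else 0.975
  mean(depositions) -
    stats::qt(p, n - 1) * stats::sd(depositions) / sqrt(n)
}

#' Decadal mean deposition
#'
#' Arithmetic mean of elevation-corrected deposition over the QC-passing
#' years of a decade; a lower bound on the critical load for lakes whose
#' diatoms have not yet responded.
#'
#' @param records data frame with \code{year}, \code{deposition} and
#'   \code{qc_pass} columns.
#' @param decade length-2 year range, e.g. \code{c(2000, 2009)}.
#' @return kg N ha^-1 yr^-1.
#' @export
decadal_mean <- function(records, decade) {
  sel <- records$year >= decade[1] & records$year <= decade[2] &
    records$qc_pass == 1
  if (!any(sel)) stop_nlakes("decadal_mean: no QC-passing years in range")
  mean(records$deposition[sel])
}
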