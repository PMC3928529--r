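# Bulk deposition from ion-exchange-resin (IER) collector columns.
#
# Each collector is a funnel over a resin column deployed around a lake basin
# for a summer season; the laboratory extract gives a sorbed mass (mg) per
# analyte per column. Fluxes are normalised to kg ha^-1 yr^-1 using the
# funnel area and deployment length, so they are summer rates scaled to a
# common period, not annual totals.

.analytes <- c("nh4_n_mg", "no3_n_mg", "so4_s_mg", "po4_p_mg")
.analyte_labels <- c(nh4_n_mg = "NH4-N", no3_n_mg = "NO3-N",
                     so4_s_mg = "SO4-S", po4_p_mg = "PO4-P")

#' Blank/control correction of an extract mass
#'
#' Subtracts the pooled blank mean and (for ammonium only, by convention of
#' the caller) the capped control column's release, flooring at zero.
#'
#' @param raw_mass extract mass, mg.
#' @param blank_mean pooled field/lab blank mean, mg.
#' @param control_release control-column release, mg (pass 0 for analytes
#'   other than NH4-N).
#' @return corrected mass, mg.
#' @export
correct_column <- function(raw_mass, blank_mean = 0, control_release = 0) {
  check_nonneg(raw_mass, "raw_mass")
  check_nonneg(blank_mean, "blank_mean")
  check_nonneg(control_release, "control_release")
  pmax(raw_mass - blank_mean - control_release, 0)
}

#' Convert an extract mass to a deposition flux
#'
#' \code{rate = (mass / area) * 100 * (365.25 / days)}: 1 mg cm^-2 equals
#' 100 kg ha^-1, and the deployment is scaled to a 365.25-day year.
#'
#' @param mass corrected extract mass, mg.
#' @param funnel_area_cm2 funnel area, cm^2.
#' @param days_deployed deployment length, days.
#' @return flux in kg ha^-1 yr^-1.
#' @export
#' @examples
#' column_flux(1, 100, 365.25)  # 1 kg ha^-1 yr^-1
column_flux <- function(mass, funnel_area_cm2, days_deployed) {
  check_nonneg(mass, "mass")
  if (any(funnel_area_cm2 <= 0)) stop_nlakes("funnel_area_cm2 must be > 0")
  if (any(days_deployed <= 0)) stop_nlakes("days_deployed must be > 0")
  (mass / funnel_area_cm2) * 100 * (365.25 / days_deployed)
}

#' Per-column deposition rates from an IER table
#'
#' Applies blank correction (pooled field and lab blank mean per analyte,
#' across the whole table) and the per-site control-column NH4 release, then
#' converts each active column's masses to fluxes. Inorganic N is the sum of
#' NH4-N and NO3-N per column, formed before any averaging.
#'
#' @param columns an \code{ier_columns} data frame (see
#'   \code{\link{read_table}}).
#' @return data frame with one row per active column: \code{site},
#'   \code{column_id}, and rates \code{nh4_n}, \code{no3_n}, \code{so4_s},
#'   \code{po4_p}, \code{inorganic_n} (kg ha^-1 yr^-1).
#' @export
ier_fluxes <- function(columns) {
  act <- columns[columns$role == "active", , drop = FALSE]
  if (nrow(act) == 0) stop_nlakes("no active columns")
  blanks <- columns[columns$role %in% c("field_blank", "lab_blank"), ,
                    drop = FALSE]
  blank_mean <- vapply(.analytes, function(a) {
    if (nrow(blanks) == 0) 0 else mean(blanks[[a]])
  }, numeric(1))
  controls <- columns[columns$role == "control", , drop = FALSE]
  out <- act[c("site", "column_id")]
  for (a in .analytes) {
    ctrl <- if (a == "nh4_n_mg" && nrow(controls) > 0) {
      cr <- tapply(controls[[a]], controls$site, mean)
      ifelse(act$site %in% names(cr), cr[act$site], 0)
    } else 0
    corrected <- correct_column(act[[a]], blank_mean[[a]], ctrl)
    out[[sub("_mg$", "", a)]] <-
      column_flux(corrected, act$funnel_area_cm2, act$days_deployed)
  }
  out$inorganic_n <- out$nh4_n + out$no3_n
  out
}

.summarise_rates <- function(rates, group) {
  vars <- c("nh4_n", "no3_n", "inorganic_n", "so4_s")
  groups <- split(rates, rates[[group]])
  do.call(rbind, lapply(names(groups), function(g) {
    df <- groups[[g]]
    row <- data.frame(group = g, n_columns = nrow(df))
    for (v in vars) {
      row[[paste0(v, "_rate")]] <- mean(df[[v]])
      row[[paste0(v, "_sd")]] <-
        if (nrow(df) > 1) stats::sd(df[[v]]) else NA_real_
    }
    row
  }))
}

#' Site-level deposition summary
#'
#' Mean and standard deviation of per-column rates by site. When only one
#' column was retrieved the sd is reported as NA rather than 0.
#'
#' @param fluxes output of \code{\link{ier_fluxes}}.
#' @return data frame with columns \code{site}, \code{n_columns}, and
#'   \code{<analyte>_rate}/\code{<analyte>_sd} for NH4-N, NO3-N, inorganic N
#'   and SO4-S.
#' @export
site_summary <- function(fluxes) {
  if (nrow(fluxes) == 0) stop_nlakes("no active columns")
  out <- .summarise_rates(fluxes, "site")
  names(out)[names(out) == "group"] <- "site"
  out
}

#' Park-level deposition summary
#'
#' Statistics are computed across all individual columns in the park, not
#' across site means, so a site with fewer retrieved columns weighs less.
#' This is the convention that reproduces published park averages when one
#' site contributed a single column.
#'
#' @param fluxes output of \code{\link{ier_fluxes}} with a \code{park} column
#'   (join against a sites table).
#' @return data frame as \code{\link{site_summary}} but keyed by \code{park}.
#' @export
park_summary <- function(fluxes) {
  if (!"park" %in% names(fluxes))
    stop_nlakes("park_summary: fluxes need a 'park' column")
  if (nrow(fluxes) < 2) stop_nlakes("park_summary: need >= 2 columns")
  out <- .summarise_rates(fluxes, "park")
  names(out)[names(out) == "group"] <- "park"
  out
}

#' One-way ANOVA with Tukey HSD pairwise comparison
#'
#' Tests for differences in deposition between groups (lakes within a park,
#' or parks), then identifies which pairs differ at the given level.
#'
#' @param values numeric deposition rates.
#' @param group group label per value.
#' @param alpha significance level (default 0.05, i.e. a 95\% confidence
#'   limit).
#' @return list with \code{p_value} (ANOVA F-test), \code{pairs} (data frame:
#'   \code{pair}, \code{diff}, \code{p_adj}, \code{significant}), \code{alpha}.
#' @export
compare_groups <- function(values, group, alpha = 0.05) {
  group <- as.character(group)
  sizes <- table(group)
  if (length(sizes) < 2) stop_nlakes("compare_groups: need >= 2 groups")
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0)
    stop_nlakes(sprintf("compare_groups: group(s) with < 2 observations: %s",
                        paste(small, collapse = ", ")))
  df <- data.frame(y = values, g = factor(group))
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  p <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  # degenerate case: zero within- and between-group variance
  if (!is.finite(p)) {
    p <- 1
    pairs$p_adj[!is.finite(pairs$p_adj)] <- 1
    pairs$significant <- pairs$p_adj < alpha
  }
  list(p_value = p, pairs = pairs, alpha = alpha)
}

#' Screen phosphate masses for contamination
#'
#' Orthophosphate is not a deposition analyte here; an anomalously high PO4-P
#' mass flags probable contamination (e.g. bird droppings in the funnel).
#' A column is flagged when its mass exceeds the site mean + 3 sd.
#'
#' @param po4_masses numeric PO4-P masses (mg) for one site's columns.
#' @param column_id optional labels.
#' @return character vector of flagged column ids (possibly empty).
#' @export
contamination_screen <- function(po4_masses, column_id = seq_along(po4_masses)) {
  if (length(po4_masses) < 3) {
    warning("contamination_screen: fewer than 3 columns; screen skipped")
    return(character(0))
  }
  flagged <- logical(length(po4_masses))
  for (i in seq_along(po4_masses)) {
    others <- po4_masses[-i]
    thr <- mean(others) + 3 * stats::sd(others)
    flagged[i] <- is.finite(thr) && po4_masses[i] > thr
  }
  as.character(column_id)[flagged]
}

#' Round a deposition summary to report precision
#'
#' @param summary output of \code{\link{site_summary}} or
#'   \code{\link{park_summary}}.
#' @param digits decimal places (default 2, matching report tables).
#' @return the summary with rate/sd columns rounded half away from zero.
#' @export
format_deposition_summary <- function(summary, digits = 2) {
  num <- grepl("_rate$|_sd$", names(summary))
  summary[num] <- lapply(summary[num], round_half_up, digits = digits)
  summary
}
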