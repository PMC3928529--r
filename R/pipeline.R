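# Stage runners chaining the modules over on-disk CSVs. These back the
# command-line entry point (inst/cli/nlakes.R) and make a full run
# reproducible from a config file: every stage logs its input counts,
# parameters and seed, and all randomness flows from the config seed.

#' Simulate a complete input set
#'
#' Writes all five input tables for one synthetic lake plus
#' \code{ground_truth.json} holding the generating parameters, so a full
#' pipeline run can be checked against truth.
#'
#' @param config run configuration (see \code{\link{default_run_config}}).
#' @param out_dir output directory (created if needed).
#' @param dep_scenario a \code{\link{deposition_scenario}}.
#' @param core_scn a \code{\link{core_scenario}}.
#' @return \code{out_dir}, invisibly.
#' @export
simulate_inputs <- function(config = default_run_config(), out_dir,
                            dep_scenario = deposition_scenario(),
                            core_scn = core_scenario()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  dep <- gen_deposition_series(dep_scenario, seed = seed)
  core <- gen_sediment_core(core_scn, coring_year = config$coring_year,
                            seed = seed + 1L)
  dia <- gen_diatom_core(core_scn, core$truth, seed = seed + 2L)
  ier <- gen_ier_columns(seed = seed + 3L)
  wc <- gen_water_chem(data.frame(
    site = "synthetic",
    analyte = c("NH4-N", "NO3-N", "TP"),
    true_value = c(0.004, 0.003, 0.005),
    detection_limit = c(0.01, 0.001, 0.001)))
  utils::write.csv(dep$records, file.path(out_dir, "deposition_series.csv"),
                   row.names = FALSE)
  utils::write.csv(core$profile, file.path(out_dir, "sediment.csv"),
                   row.names = FALSE)
  counts_long <- data.frame(
    site = "synthetic",
    slice_top_cm = rep(as.numeric(rownames(dia$counts)),
                       times = ncol(dia$counts)),
    taxon = rep(colnames(dia$counts), each = nrow(dia$counts)),
    count = as.vector(dia$counts))
  counts_long <- counts_long[counts_long$count > 0, ]
  utils::write.csv(counts_long, file.path(out_dir, "diatom_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(ier, file.path(out_dir, "ier_columns.csv"),
                   row.names = FALSE)
  utils::write.csv(wc, file.path(out_dir, "water_chem.csv"),
                   row.names = FALSE)
  write_results(list(
    seed = seed,
    deposition = dep$truth[c("d1900", "growth_rate")],
    core = core$params[c("supply_flux", "mass_accumulation", "ra226_level",
                         "shift_year", "indicator_background",
                         "indicator_plateau")],
    coring_year = config$coring_year
  ), file.path(out_dir, "ground_truth.json"))
  log_stage("simulate", length(dep_scenario$obs_years), seed = seed)
  invisible(out_dir)
}

#' Run the deposition stage over a directory
#'
#' Reads \code{ier_columns.csv}, converts to per-column fluxes, and writes
#' \code{deposition_summary.csv} (site rows, then park rows when a
#' \code{sites.csv} supplies the site-to-park mapping).
#'
#' @param in_dir directory holding \code{ier_columns.csv} (and optionally
#'   \code{sites.csv}).
#' @param out_dir output directory.
#' @return the summary data frame, invisibly.
#' @export
stage_deposition <- function(in_dir, out_dir = in_dir) {
  cols <- read_table(file.path(in_dir, "ier_columns.csv"), "ier_columns")
  fx <- ier_fluxes(cols)
  summ <- site_summary(fx)
  out <- cbind(level = "site", summ)
  sites_path <- file.path(in_dir, "sites.csv")
  if (file.exists(sites_path)) {
    sites <- read_table(sites_path, "sites")
    fx$park <- sites$park[match(fx$site, sites$name)]
    if (!anyNA(fx$park)) {
      pk <- park_summary(fx)
      names(pk)[names(pk) == "park"] <- "site"
      out <- rbind(out, cbind(level = "park", pk))
    }
  }
  out <- format_deposition_summary(out)
  utils::write.csv(out, file.path(out_dir, "deposition_summary.csv"),
                   row.names = FALSE)
  log_stage("deposition", nrow(cols))
  invisible(out)
}

#' Run the water-chemistry stage over a directory
#'
#' @param in_dir directory holding \code{water_chem.csv}.
#' @param out_dir output directory for \code{limitation.csv}.
#' @param config run configuration (censor rule).
#' @return the limitation table, invisibly.
#' @export
stage_waterchem <- function(in_dir, out_dir = in_dir,
                            config = default_run_config()) {
  wc <- read_table(file.path(in_dir, "water_chem.csv"), "water_chem")
  lim <- limitation_table(wc, rule = config$censor_rule)
  utils::write.csv(lim, file.path(out_dir, "limitation.csv"),
                   row.names = FALSE)
  log_stage("waterchem", nrow(wc), rule = config$censor_rule)
  invisible(lim)
}

#' Run the geochronology stage over a directory
#'
#' @param in_dir directory holding \code{sediment.csv} (one site).
#' @param out_dir output directory for \code{age_model.csv} and
#'   \code{cs137_validation.json}.
#' @param config run configuration (coring year, half-life, Monte-Carlo
#'   reps, seed).
#' @return the age model, invisibly.
#' @export
stage_agemodel <- function(in_dir, out_dir = in_dir,
                           config = default_run_config()) {
  prof <- read_table(file.path(in_dir, "sediment.csv"), "sediment")
  am <- age_uncertainty(prof, coring_year = config$coring_year,
                        n_reps = config$crs_n_reps,
                        seed = config$seed,
                        half_life = config$pb210_half_life)
  utils::write.csv(as.data.frame(am), file.path(out_dir, "age_model.csv"),
                   row.names = FALSE)
  val <- cs137_validate(prof, am)
  if (!is.null(val))
    write_results(val, file.path(out_dir, "cs137_validation.json"))
  log_stage("agemodel", nrow(prof), seed = config$seed,
            reps = config$crs_n_reps)
  invisible(am)
}

#' Run the diatom stage over a directory
#'
#' Writes the relative-abundance table, a group-average dendrogram of the
#' square-root-standardised Bray--Curtis resemblance, and the detected
#' indicator shift (\code{shifts.json}; an empty object when no shift
#' fires).
#'
#' @param in_dir directory holding \code{diatom_counts.csv} and
#'   \code{age_model.csv}.
#' @param out_dir output directory.
#' @param config run configuration.
#' @param taxa indicator taxon set.
#' @return the \code{indicator_shift} (or NULL), invisibly.
#' @export
stage_diatoms <- function(in_dir, out_dir = in_dir,
                          config = default_run_config(),
                          taxa = indicator_taxa(extended = TRUE)) {
  counts <- read_table(file.path(in_dir, "diatom_counts.csv"),
                       "diatom_counts")
  m <- counts_to_matrix(counts)
  props <- relative_abundance(m)
  utils::write.csv(data.frame(slice_top_cm = rownames(props), props,
                              check.names = FALSE),
                   file.path(out_dir, "proportions.csv"), row.names = FALSE)
  if (nrow(m) >= 2) {
    hc <- cluster_group_average(bray_curtis(transform_standardize(m)),
                                labels = rownames(m))
    write_results(hc, file.path(out_dir, "dendrogram.nwk"))
  }
  am_path <- file.path(in_dir, "age_model.csv")
  shift <- NULL
  if (file.exists(am_path)) {
    am <- utils::read.csv(am_path)
    shift <- detect_shift(m, am, taxa = taxa,
                          background_fraction = config$background_fraction)
  }
  write_results(if (is.null(shift)) list(shift = NULL)
                else unclass(shift),
                file.path(out_dir, "shifts.json"))
  log_stage("diatoms", nrow(m))
  invisible(shift)
}

#' Run the critical-load stage over a directory
#'
#' Fits the exponential deposition trend with and without the configured
#' anchor, hindcasts over the shift window from \code{shifts.json}, and
#' writes \code{critical_load.json}.
#'
#' @param in_dir directory holding \code{deposition_series.csv} and
#'   \code{shifts.json}.
#' @param out_dir output directory.
#' @param config run configuration (anchor point).
#' @return list with anchored and unanchored \code{critical_load} estimates,
#'   invisibly.
#' @export
stage_criticalload <- function(in_dir, out_dir = in_dir,
                               config = default_run_config()) {
  recs <- read_table(file.path(in_dir, "deposition_series.csv"),
                     "deposition_series")
  recs <- deposition_series(recs)
  shifts <- jsonlite::read_json(file.path(in_dir, "shifts.json"),
                                simplifyVector = TRUE)
  if (is.null(shifts$window))
    stop_nlakes("stage_criticalload: no detected shift window in shifts.json")
  window <- as.numeric(shifts$window)
  fit_anch <- fit_exponential(recs, anchor = config$anchor)
  fit_free <- fit_exponential(recs, anchor = NULL)
  cl_anch <- estimate_critical_load(fit_anch, window)
  cl_free <- estimate_critical_load(fit_free, window)
  out <- list(
    window = cl_anch$window,
    anchored = list(mean = cl_anch$mean, sd = cl_anch$sd,
                    d_ref = fit_anch$d_ref,
                    growth_rate = fit_anch$growth_rate),
    unanchored = list(mean = cl_free$mean, sd = cl_free$sd,
                      d_ref = fit_free$d_ref,
                      growth_rate = fit_free$growth_rate),
    anchor = config$anchor,
    n_obs = sum(recs$qc_pass == 1),
    lcl95 = lcl95(recs$deposition)
  )
  write_results(out, file.path(out_dir, "critical_load.json"))
  log_stage("criticalload", nrow(recs))
  invisible(list(anchored = cl_anch, unanchored = cl_free, json = out))
}
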