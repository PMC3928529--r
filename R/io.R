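# CSV schema registry, validated readers, result writers and run
# configuration.
#
# All tables are comma-separated UTF-8 with "." decimals and one header row.
# Censoring qualifiers live in their own column; a value cell written as
# "<0.01" is accepted on input and split into qualifier "<" plus detection
# limit 0.01. Depths are cm below the sediment surface and a slice is the
# half-open interval [top, bottom). Dates are calendar years (decimal years
# allowed in outputs).

.schemas <- list(
  sites = list(
    cols = c("name", "park", "usgs_id", "latitude_deg", "longitude_deg",
             "elevation_m", "area_ha", "max_depth_m"),
    num  = c("latitude_deg", "longitude_deg", "elevation_m", "area_ha",
             "max_depth_m")
  ),
  ier_columns = list(
    cols = c("site", "column_id", "role", "days_deployed", "funnel_area_cm2",
             "nh4_n_mg", "no3_n_mg", "so4_s_mg", "po4_p_mg"),
    num  = c("days_deployed", "funnel_area_cm2", "nh4_n_mg", "no3_n_mg",
             "so4_s_mg", "po4_p_mg")
  ),
  water_chem = list(
    cols = c("site", "date", "analyte", "value", "qualifier",
             "detection_limit"),
    num  = c("detection_limit")
  ),
  sediment = list(
    cols = c("site", "slice_top_cm", "slice_bottom_cm", "bulk_density_g_cm3",
             "pb210_total", "pb210_sd", "ra226", "ra226_sd", "cs137",
             "cs137_sd"),
    num  = c("slice_top_cm", "slice_bottom_cm", "bulk_density_g_cm3",
             "pb210_total", "pb210_sd", "ra226", "ra226_sd", "cs137",
             "cs137_sd")
  ),
  diatom_counts = list(
    cols = c("site", "slice_top_cm", "taxon", "count"),
    num  = c("slice_top_cm", "count")
  ),
  deposition_series = list(
    cols = c("year", "precip_cm", "conc_mg_n_per_l", "qc_pass"),
    num  = c("year", "precip_cm", "conc_mg_n_per_l", "qc_pass")
  )
)

#' Read and validate an input table
#'
#' Reads one of the pipeline's CSV schemas, type-checks every row, and parses
#' censoring qualifiers. Valid schemas: \code{sites}, \code{ier_columns},
#' \code{water_chem}, \code{sediment}, \code{diatom_counts},
#' \code{deposition_series}.
#'
#' For \code{water_chem}, a value cell of the form \code{"<0.01"} is split
#' into \code{qualifier = "<"} and \code{detection_limit = 0.01} with a
#' missing numeric value; a plain cell keeps qualifier \code{""}. Qualifier
#' \code{"E"} marks an estimated value (detected below the reporting limit)
#' which passes through as a number.
#'
#' @param path path to a CSV file.
#' @param schema schema name (see above).
#' @return a \code{data.frame} with typed columns; row count equals the file's
#'   data rows.
#' @export
read_table <- function(path, schema) {
  if (!schema %in% names(.schemas))
    stop_nlakes(sprintf("unknown schema '%s'", schema))
  if (!file.exists(path))
    stop_nlakes(sprintf("file not found: %s", path))
  sch <- .schemas[[schema]]
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(sch$cols, names(raw))
  if (length(missing) > 0)
    stop_nlakes(sprintf("schema '%s': missing column(s): %s", schema,
                        paste(missing, collapse = ", ")))
  df <- raw[sch$cols]
  if (schema == "water_chem") df <- .parse_waterchem_values(df)
  for (col in sch$num) {
    v <- trimws(df[[col]])
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & v != "NA" & is.na(out))
    if (length(bad) > 0)
      stop_nlakes(sprintf("schema '%s': column '%s', row %d: cannot parse '%s'",
                          schema, col, bad[1], v[bad[1]]))
    df[[col]] <- out
  }
  .validate_schema(df, schema)
  df
}

.parse_waterchem_values <- function(df) {
  v <- trimws(df$value)
  q <- trimws(df$qualifier)
  inline <- grepl("^<", v)
  if (any(inline)) {
    lim <- suppressWarnings(as.numeric(sub("^<", "", v[inline])))
    bad <- which(is.na(lim))
    if (length(bad) > 0)
      stop_nlakes(sprintf("water_chem: row %d: cannot parse censored value '%s'",
                          which(inline)[bad[1]], v[inline][bad[1]]))
    q[inline] <- "<"
    df$detection_limit[inline] <- as.character(lim)
    v[inline] <- NA_character_
  }
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & v != "" & v != "NA" & is.na(out))
  if (length(bad) > 0)
    stop_nlakes(sprintf("water_chem: column 'value', row %d: cannot parse '%s'",
                        bad[1], v[bad[1]]))
  df$value <- out
  df$qualifier <- q
  df
}

.validate_schema <- function(df, schema) {
  n <- nrow(df)
  if (n == 0) return(invisible(df))
  switch(schema,
    sites = {
      if (any(df$elevation_m <= 0, na.rm = TRUE))
        stop_nlakes("sites: elevation_m must be > 0")
      if (any(df$area_ha <= 0, na.rm = TRUE))
        stop_nlakes("sites: area_ha must be > 0")
      if (any(df$max_depth_m <= 0, na.rm = TRUE))
        stop_nlakes("sites: max_depth_m must be > 0")
    },
    ier_columns = {
      ok_roles <- c("active", "control", "field_blank", "lab_blank")
      bad <- which(!df$role %in% ok_roles)
      if (length(bad) > 0)
        stop_nlakes(sprintf("ier_columns: row %d: unknown role '%s'",
                            bad[1], df$role[bad[1]]))
      act <- df$role == "active"
      if (any(act & (is.na(df$days_deployed) | df$days_deployed <= 0)))
        stop_nlakes("ier_columns: active columns need days_deployed > 0")
    },
    water_chem = {
      cen <- df$qualifier == "<"
      if (any(cen & (is.na(df$detection_limit) | df$detection_limit <= 0)))
        stop_nlakes("water_chem: censored record without detection_limit > 0")
    },
    sediment = {
      ord <- order(df$site, df$slice_top_cm)
      for (s in unique(df$site)) {
        sl <- df[df$site == s, ][order(df$slice_top_cm[df$site == s]), ]
        if (any(diff(sl$slice_top_cm) <= 0))
          stop_nlakes(sprintf("sediment: site '%s': slice tops must strictly increase", s))
        if (any(sl$slice_bottom_cm <= sl$slice_top_cm))
          stop_nlakes(sprintf("sediment: site '%s': slice bottom must exceed top", s))
        if (any(sl$bulk_density_g_cm3 <= 0))
          stop_nlakes(sprintf("sediment: site '%s': bulk densities must be > 0", s))
      }
    },
    diatom_counts = {
      if (any(df$count < 0 | df$count != floor(df$count)))
        stop_nlakes("diatom_counts: counts must be non-negative integers")
    },
    deposition_series = {
      if (!all(df$qc_pass %in% c(0, 1)))
        stop_nlakes("deposition_series: qc_pass must be 0 or 1")
    }
  )
  invisible(df)
}

#' Write a stage result to disk
#'
#' Dispatches on the result type: data frames are written as CSV,
#' \code{hclust}/\code{phylo} dendrograms as newick, and lists as JSON.
#' Read-back round-trips reproduce the structure within printed precision.
#'
#' @param results a stage output (data.frame, hclust, phylo, or list).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_nlakes(sprintf("cannot write to '%s': directory does not exist", path))
  if (inherits(results, "hclust")) results <- ape::as.phylo(results)
  if (inherits(results, "phylo")) {
    ape::write.tree(results, file = path)
  } else if (is.data.frame(results)) {
    utils::write.csv(results, path, row.names = FALSE)
  } else if (is.list(results)) {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    stop_nlakes("write_results: unsupported result type")
  }
  invisible(path)
}

#' Convert a count table in long form to a slice-by-taxon matrix
#'
#' @param counts a \code{diatom_counts} data frame (one site).
#' @return integer matrix; rows named by slice top depth (cm, increasing),
#'   columns by taxon.
#' @export
counts_to_matrix <- function(counts) {
  if (length(unique(counts$site)) > 1)
    stop_nlakes("counts_to_matrix: expected a single site")
  depths <- sort(unique(counts$slice_top_cm))
  taxa <- unique(counts$taxon)
  m <- matrix(0L, nrow = length(depths), ncol = length(taxa),
              dimnames = list(format(depths, trim = TRUE), taxa))
  m[cbind(match(counts$slice_top_cm, depths),
          match(counts$taxon, taxa))] <- as.integer(counts$count)
  m
}

#' Default run configuration
#'
#' All pipeline randomness flows from \code{seed}; two runs with equal
#' configuration and inputs produce identical outputs.
#'
#' @param seed integer RNG seed.
#' @return a named list with components \code{seed}, \code{coring_year},
#'   \code{censor_rule} (\code{"half_dl"}, \code{"zero"} or \code{"dl"}),
#'   \code{anchor} (\code{list(year, value)} or NULL), \code{pb210_half_life}
#'   (yr), \code{crs_n_reps}, \code{background_fraction} (deepest fraction of
#'   slices used as the indicator background zone), \code{cluster_linkage},
#'   and \code{alpha}.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    coring_year = 2009,
    censor_rule = "half_dl",
    anchor = list(year = 1900, value = 0.5),
    pb210_half_life = 22.3,
    crs_n_reps = 1000L,
    background_fraction = 1 / 3,
    cluster_linkage = "average",
    alpha = 0.05
  )
}

#' Read a YAML run configuration
#'
#' Unspecified fields fall back to \code{\link{default_run_config}}.
#'
#' @param path YAML file.
#' @return a run-config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_nlakes(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  out <- utils::modifyList(base, cfg)
  if (!out$censor_rule %in% c("half_dl", "zero", "dl"))
    stop_nlakes(sprintf("unknown censor_rule '%s'", out$censor_rule))
  out$seed <- as.integer(out$seed)
  out
}
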