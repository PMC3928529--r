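# Diatom stratigraphy: relative abundances, community resemblance, and the
# dated indicator-shift detection that anchors the critical-load window.
#
# Count matrices are slices (rows, named by top depth in cm, increasing
# downward) by taxa (columns); analysis-grade samples have >= 500 identified
# valves. The nitrogen-enrichment indicator set defaults to Asterionella
# formosa + Fragilaria crotonensis, with an extended set adding F. tenera and
# F. sepes for coastal-park assemblages.

#' Default nitrogen-enrichment indicator taxa
#'
#' @param extended add \emph{Fragilaria tenera} and \emph{Fragilaria sepes}.
#' @return character vector of taxon names.
#' @export
indicator_taxa <- function(extended = FALSE) {
  base <- c("Asterionella formosa", "Fragilaria crotonensis")
  if (extended) c(base, "Fragilaria tenera", "Fragilaria sepes") else base
}

.check_counts <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (any(m < 0)) stop_nlakes("counts must be non-negative")
  rs <- rowSums(m)
  bad <- which(rs == 0)
  if (length(bad) > 0)
    stop_nlakes(sprintf("zero-count slice at row '%s'",
                        rownames(m)[bad[1]] %||% bad[1]))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative abundance matrix
#'
#' @param m slice-by-taxon count matrix (see \code{\link{counts_to_matrix}}).
#' @return matrix of proportions; each row sums to 1.
#' @export
relative_abundance <- function(m) {
  m <- .check_counts(m)
  sweep(m, 1, rowSums(m), "/")
}

#' Square-root standardisation
#'
#' Standardises by total sample count then square-root transforms:
#' \code{sqrt(count / row total)}. This is the conventional pre-treatment
#' before Bray--Curtis resemblance; it is deliberately not idempotent, so do
#' not apply it twice.
#'
#' @param m slice-by-taxon count matrix.
#' @return transformed matrix.
#' @export
transform_standardize <- function(m) sqrt(relative_abundance(m))

#' Bray--Curtis dissimilarity
#'
#' \code{d(u, v) = 1 - 2 * sum(min(u, v)) / (sum(u) + sum(v))}; symmetric,
#' zero diagonal, range [0, 1] for non-negative rows.
#'
#' @param m sample-by-variable matrix (typically the output of
#'   \code{\link{transform_standardize}}).
#' @return a \code{dist} object.
#' @export
bray_curtis <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (nrow(m) < 2) stop_nlakes("bray_curtis: need >= 2 rows")
  if (any(m < 0)) stop_nlakes("bray_curtis: negative entries")
  vegan::vegdist(m, method = "bray")
}

#' Group-average (UPGMA) clustering
#'
#' Agglomerates with unweighted pair-group average linkage; merge heights are
#' non-decreasing and leaf order follows input order with ties broken by the
#' smallest original index, so newick output is byte-stable.
#'
#' @param d a \code{dist} object or square symmetric dissimilarity matrix.
#' @param labels optional leaf labels.
#' @return an \code{hclust} object; write as newick with
#'   \code{\link{write_results}}.
#' @export
cluster_group_average <- function(d, labels = NULL) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d))
      stop_nlakes("cluster_group_average: matrix must be square")
    d <- stats::as.dist(d)
  }
  if (!inherits(d, "dist"))
    stop_nlakes("cluster_group_average: need a dist or square matrix")
  hc <- stats::hclust(d, method = "average")
  if (!is.null(labels)) hc$labels <- labels
  hc
}

#' Top/bottom indicator screen
#'
#' Screens a core by comparing its surface and bottom slices: the site is
#' flagged when any indicator taxon reaches at least 5\% of the surface
#' assemblage and has at least doubled relative to the bottom slice
#' (presence in a previously indicator-free core always counts as doubling).
#'
#' @param m slice-by-taxon count matrix (>= 2 slices).
#' @param taxa indicator taxon names (see \code{\link{indicator_taxa}}).
#' @return list with \code{top}, \code{bottom} (named proportion vectors over
#'   \code{taxa}) and \code{flag}.
#' @export
top_bottom_screen <- function(m, taxa = indicator_taxa()) {
  m <- .check_counts(m)
  if (nrow(m) < 2) stop_nlakes("top_bottom_screen: need >= 2 slices")
  present <- intersect(taxa, colnames(m))
  if (length(present) < length(taxa))
    warning(sprintf("indicator taxa absent from counts: %s",
                    paste(setdiff(taxa, present), collapse = ", ")))
  p <- relative_abundance(m)
  top <- stats::setNames(rep(0, length(taxa)), taxa)
  bot <- top
  top[present] <- p[1, present]
  bot[present] <- p[nrow(p), present]
  flag <- any(top >= 0.05 & top >= 2 * bot)
  list(top = top, bottom = bot, flag = flag)
}

#' Detect a dated indicator shift in a stratigraphy
#'
#' Implements the doubling-plus-5\% rule: with the background level taken as
#' the mean indicator proportion over a background zone (by default the
#' deepest third of slices), the shift slice is the deepest slice above the
#' background zone whose proportion is at least \code{max(2 * background,
#' 0.05)}. The rule is applied to each indicator taxon separately and to the
#' summed indicator set; the earliest (deepest-dated) trigger is reported.
#' When the background is zero the doubling clause is vacuous and the 5\%
#' absolute clause alone triggers.
#'
#' @param m slice-by-taxon count matrix (>= 4 slices), depths increasing.
#' @param age_model CRS age model covering the candidate slices (see
#'   \code{\link{crs_ages}}).
#' @param taxa indicator taxon set.
#' @param background_fraction deepest fraction of slices forming the
#'   background zone.
#' @param background_n explicit number of deepest slices (overrides the
#'   fraction).
#' @return an \code{indicator_shift} list (\code{shift_depth_cm},
#'   \code{shift_date}, \code{shift_date_sd}, \code{window},
#'   \code{background_level}, \code{triggered_by}, \code{threshold}), or
#'   \code{NULL} when no shift fires. The window brackets the onset of the
#'   change: because a slice's count averages over the slice's whole
#'   deposition span, the slice just below the trigger can already contain
#'   the onset without its average crossing the threshold, so the window runs
#'   from that slice's bottom-boundary date to the trigger slice's top date,
#'   each widened by its 1-sd dating uncertainty when available.
#' @export
detect_shift <- function(m, age_model, taxa = indicator_taxa(),
                         background_fraction = 1 / 3, background_n = NULL) {
  m <- .check_counts(m)
  n <- nrow(m)
  if (n < 4) stop_nlakes("detect_shift: need >= 4 slices")
  if (is.null(background_n))
    background_n <- max(1L, floor(n * background_fraction))
  if (background_n >= n)
    stop_nlakes("detect_shift: background zone covers the whole core")
  p <- relative_abundance(m)
  present <- intersect(taxa, colnames(m))
  if (length(present) == 0) return(NULL)
  series <- cbind(p[, present, drop = FALSE],
                  combined = rowSums(p[, present, drop = FALSE]))
  bg_rows <- seq(n - background_n + 1L, n)          # deepest slices
  cand_rows <- seq_len(n - background_n)            # above the zone
  depths <- as.numeric(rownames(m))
  hits <- lapply(colnames(series), function(s) {
    v <- series[, s]
    bg <- mean(v[bg_rows])
    thr <- max(2 * bg, 0.05)
    ok <- cand_rows[v[cand_rows] >= thr]
    if (length(ok) == 0) return(NULL)
    list(name = s, row = max(ok), background = bg, threshold = thr)
  })
  hits <- Filter(Negate(is.null), hits)
  if (length(hits) == 0) return(NULL)
  deepest <- which.max(vapply(hits, `[[`, numeric(1), "row"))
  hit <- hits[[deepest]]
  depth <- depths[hit$row]
  row <- which(age_model$slice_top_cm == depth)
  if (length(row) == 0)
    stop_nlakes(sprintf("detect_shift: age model missing at shift depth %s cm",
                        depth))
  sdcol <- age_model$date_sd %||% rep(NA_real_, nrow(age_model))
  date <- age_model$date[row]
  # onset bracket: bottom boundary of the slice below the trigger (= the top
  # of the slice two below, for contiguous slices) up to the trigger slice's
  # top, each end widened by its 1-sd dating uncertainty when available
  lo_row <- min(row + 2L, nrow(age_model))
  lo <- age_model$date[lo_row] - ifelse(is.na(sdcol[lo_row]), 0, sdcol[lo_row])
  hi <- date + ifelse(is.na(sdcol[row]), 0, sdcol[row])
  structure(list(
    taxa = present,
    background_level = hit$background,
    threshold = hit$threshold,
    shift_depth_cm = depth,
    shift_date = date,
    shift_date_sd = sdcol[row],
    window = c(lo, hi),
    triggered_by = hit$name
  ), class = "indicator_shift")
}
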