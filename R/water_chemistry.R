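# Censored surface-water chemistry and DIN/TP nutrient-limitation
# classification.
#
# Nutrient concentrations at ultra-oligotrophic lakes are routinely at or
# below laboratory detection limits; a censored record ("<DL") is substituted
# before ratios are formed. The DIN/TP mass ratio (dissolved inorganic
# nitrogen = NH4-N + NO3-N over total phosphorus) classifies lakes as
# N-limited (<= 1.5), possibly co-limited (1.5, 3.4], or strictly P-limited
# (> 3.4), after Bergstrom's survey thresholds.

#' Substitute a censored value
#'
#' @param value numeric value (NA for a censored record).
#' @param qualifier \code{""} (plain), \code{"<"} (censored at the detection
#'   limit) or \code{"E"} (estimated: detected but below the reporting limit;
#'   used as-is).
#' @param detection_limit detection limit, required for censored records.
#' @param rule \code{"half_dl"} (default: DL/2), \code{"zero"}, or
#'   \code{"dl"}.
#' @return numeric value after substitution.
#' @export
#' @examples
#' substitute_censored(NA, "<", 0.01)       # 0.005
#' substitute_censored(0.004, "", 0.001)    # 0.004
substitute_censored <- function(value, qualifier, detection_limit = NA,
                                rule = c("half_dl", "zero", "dl")) {
  rule <- match.arg(rule)
  stopifnot(length(value) == length(qualifier))
  detection_limit <- rep_len(detection_limit, length(value))
  cen <- qualifier == "<"
  if (any(cen & (is.na(detection_limit) | detection_limit <= 0)))
    stop_nlakes("censored record without a positive detection limit")
  sub <- switch(rule,
                half_dl = detection_limit / 2,
                zero = 0 * detection_limit,
                dl = detection_limit)
  ifelse(cen, sub, value)
}

#' DIN/TP mass ratio
#'
#' @param nh4 ammonium, mg N/L.
#' @param no3 nitrate (NO2+NO3), mg N/L.
#' @param tp total phosphorus, mg P/L.
#' @return (nh4 + no3) / tp at full precision; round to 1 decimal for report
#'   tables.
#' @export
din_tp_ratio <- function(nh4, no3, tp) {
  check_nonneg(nh4, "nh4")
  check_nonneg(no3, "no3")
  if (any(tp <= 0)) stop_nlakes("din_tp_ratio: tp must be > 0")
  (nh4 + no3) / tp
}

#' Classify nutrient limitation from the DIN/TP ratio
#'
#' Boundaries follow the thresholds in the lake-survey literature: a ratio of
#' 1.5 or less indicates N limitation, above 3.4 strict P limitation, and
#' values between indicate possible co-limitation. Both boundaries are
#' inclusive downward (1.5 is N-limited, 3.4 co-limited).
#'
#' @param ratio DIN/TP mass ratio (>= 0).
#' @return factor with levels \code{N_limited}, \code{co_limited},
#'   \code{P_limited}.
#' @export
classify_limitation <- function(ratio) {
  check_nonneg(ratio, "ratio")
  cut(ratio, breaks = c(-Inf, 1.5, 3.4, Inf),
      labels = c("N_limited", "co_limited", "P_limited"))
}

#' Site-level nutrient-limitation table
#'
#' Applies the censoring rule to NH4-N, NO3-N and TP records, forms DIN/TP
#' per site, and classifies limitation.
#'
#' @param water_chem a \code{water_chem} data frame (see
#'   \code{\link{read_table}}) with analytes \code{"NH4-N"}, \code{"NO3-N"}
#'   and \code{"TP"}.
#' @param rule censoring rule passed to \code{\link{substitute_censored}}.
#' @return data frame: \code{site}, \code{din}, \code{tp}, \code{ratio}
#'   (full precision), \code{ratio_1dp}, \code{class}.
#' @export
limitation_table <- function(water_chem, rule = "half_dl") {
  need <- c("NH4-N", "NO3-N", "TP")
  wc <- water_chem[water_chem$analyte %in% need, , drop = FALSE]
  wc$subst <- substitute_censored(wc$value, wc$qualifier, wc$detection_limit,
                                  rule = rule)
  sites <- unique(wc$site)
  rows <- lapply(sites, function(s) {
    sub <- wc[wc$site == s, ]
    get1 <- function(a) {
      v <- sub$subst[sub$analyte == a]
      if (length(v) == 0) NA_real_ else v[1]
    }
    nh4 <- get1("NH4-N"); no3 <- get1("NO3-N"); tp <- get1("TP")
    if (anyNA(c(nh4, no3, tp)))
      return(data.frame(site = s, din = NA_real_, tp = NA_real_,
                        ratio = NA_real_, ratio_1dp = NA_real_,
                        class = NA_character_))
    r <- din_tp_ratio(nh4, no3, tp)
    data.frame(site = s, din = nh4 + no3, tp = tp, ratio = r,
               ratio_1dp = round_half_up(r, 1),
               class = as.character(classify_limitation(r)))
  })
  do.call(rbind, rows)
}
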