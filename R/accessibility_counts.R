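# Cumulative-opportunity accessibility counts.
#
# A facility is accessible from a zone, for a mode and threshold, when its
# journey time is within the threshold (inclusive). Counts are tabulated per
# zone x mode x intensity x threshold, raw and population-adjusted
# (facilities per `per_capita_base` residents). Light-intensity facilities
# are classified upstream but excluded from counts by default.

#' Analysis configuration for accessibility counts
#'
#' @param thresholds journey-time thresholds in minutes, strictly increasing;
#'   default `c(20, 30)`.
#' @param intensities intensity categories counted; default moderate and
#'   vigorous (light facilities are excluded by default).
#' @param per_capita_base population base for adjusted counts; default 1000.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(thresholds = c(20, 30),
                            intensities = c("moderate", "vigorous"),
                            per_capita_base = 1000) {
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE)) {
    stop("'thresholds' must be positive and strictly increasing", call. = FALSE)
  }
  if (!all(intensities %in% c("light", "moderate", "vigorous"))) {
    stop("unknown intensity label", call. = FALSE)
  }
  stop_if_not_scalar_number(per_capita_base, "per_capita_base", positive = TRUE)
  structure(list(thresholds = thresholds, intensities = intensities,
                 per_capita_base = per_capita_base),
            class = "analysis_config")
}

#' Count accessible facilities per zone
#'
#' @param ttm a [travel_time_matrix()] (long form).
#' @param facilities a classified facility table with `facility_id` and
#'   `intensity`.
#' @param intensity category to count (`"moderate"`, `"vigorous"`, or
#'   `"light"` if explicitly requested).
#' @param threshold minutes; a facility counts when its journey time is
#'   `<= threshold`. Unreachable (NA) never counts.
#' @return data frame `zone_id`, `count`, one row per zone in `ttm`.
#' @export
count_accessible <- function(ttm, facilities, intensity, threshold) {
  if (!intensity %in% c("light", "moderate", "vigorous")) {
    stop(sprintf("unknown intensity label '%s'", intensity), call. = FALSE)
  }
  stop_if_not_scalar_number(threshold, "threshold", positive = TRUE)
  keep <- facilities$facility_id[facilities$intensity == intensity]
  zid <- unique(ttm$zone_id)
  sub <- ttm[ttm$facility_id %in% keep & !is.na(ttm$minutes) &
               ttm$minutes <= threshold, , drop = FALSE]
  n <- table(factor(sub$zone_id, levels = zid))
  data.frame(zone_id = zid, count = as.integer(n[zid]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Population-adjust a count
#'
#' @param count facility count (vectorised).
#' @param population zone population, positive.
#' @param per_capita_base base population, default 1000.
#' @return `count * per_capita_base / population`: facilities per
#'   `per_capita_base` residents.
#' @export
population_adjust <- function(count, population, per_capita_base = 1000) {
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  count * per_capita_base / population
}

#' Full accessibility table over modes, intensities and thresholds
#'
#' @param ttms list of [travel_time_matrix()] objects (one per mode).
#' @param facilities classified facility table.
#' @param zones data frame with `zone_id` and `population`.
#' @param config an [analysis_config()].
#' @return an `accessibility_table` data frame with columns `zone_id`, `mode`,
#'   `intensity`, `threshold`, `count`, `adjusted_count`.
#' @export
accessibility_table <- function(ttms, facilities, zones,
                                config = analysis_config()) {
  if (inherits(ttms, "travel_time_matrix")) ttms <- list(ttms)
  rows <- list()
  for (ttm in ttms) {
    mode <- ttm$mode[1]
    for (intensity in config$intensities) {
      for (thr in config$thresholds) {
        cnt <- count_accessible(ttm, facilities, intensity, thr)
        pop <- zones$population[match(cnt$zone_id, zones$zone_id)]
        rows[[length(rows) + 1L]] <- data.frame(
          zone_id = cnt$zone_id, mode = mode, intensity = intensity,
          threshold = thr, count = cnt$count,
          adjusted_count = population_adjust(cnt$count, pop,
                                             config$per_capita_base),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("accessibility_table", "data.frame")
  out
}

quintile_labels <- function() {
  c("Q1 (most affluent)", "Q2", "Q3 (middling)", "Q4", "Q5 (most deprived)")
}

#' Quintile summary of accessibility (table analogue)
#'
#' Median, minimum and maximum of the raw and population-adjusted counts per
#' deprivation quintile, for each mode x intensity x threshold combination:
#' the layout of the classic accessible-facilities-by-deprivation tables.
#' An empty quintile yields a row of explicit `NA` markers.
#'
#' @param table an [accessibility_table()].
#' @param zones data frame with `zone_id` and `quintile` (1--5).
#' @return data frame with columns `intensity`, `mode`, `threshold`,
#'   `quintile`, `label`, `n_zones`, and median/min/max of count and
#'   adjusted count.
#' @export
quintile_summary <- function(table, zones) {
  if (!all(zones$quintile %in% 1:5)) {
    stop("every zone must carry a quintile 1-5", call. = FALSE)
  }
  q <- zones$quintile[match(table$zone_id, zones$zone_id)]
  combos <- unique(table[, c("mode", "intensity", "threshold")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- table$mode == combos$mode[i] &
      table$intensity == combos$intensity[i] &
      table$threshold == combos$threshold[i]
    for (qq in 1:5) {
      cnt <- table$count[sel & q == qq]
      adj <- table$adjusted_count[sel & q == qq]
      rows[[length(rows) + 1L]] <- data.frame(
        intensity = combos$intensity[i], mode = combos$mode[i],
        threshold = combos$threshold[i], quintile = qq,
        label = quintile_labels()[qq], n_zones = length(cnt),
        count_median = if (length(cnt)) median(cnt) else NA_real_,
        count_min = if (length(cnt)) min(cnt) else NA_real_,
        count_max = if (length(cnt)) max(cnt) else NA_real_,
        adjusted_median = if (length(adj)) median(adj) else NA_real_,
        adjusted_min = if (length(adj)) min(adj) else NA_real_,
        adjusted_max = if (length(adj)) max(adj) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
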