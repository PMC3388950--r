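# Facility intensity classification.
#
# Each fixed physical-activity facility type is assigned a typical energy
# expenditure in METs (multiples of resting metabolic rate) from a curated
# lookup, then graded with the standard cut-points: light < 3 METs,
# moderate 3-6 METs, vigorous > 6 METs.

#' Intensity classification rule
#'
#' Cut-points used to grade a MET value. The defaults are the standard ones:
#' activity below `light_upper` METs is light, between `light_upper` and
#' `moderate_upper` (both inclusive of the upper bound) is moderate, and above
#' `moderate_upper` is vigorous.
#'
#' @param light_upper exclusive upper MET bound for light intensity (default 3).
#' @param moderate_upper inclusive upper MET bound for moderate intensity
#'   (default 6).
#' @return an object of class `intensity_rule`.
#' @export
intensity_rule <- function(light_upper = 3, moderate_upper = 6) {
  stop_if_not_scalar_number(light_upper, "light_upper", positive = TRUE)
  stop_if_not_scalar_number(moderate_upper, "moderate_upper", positive = TRUE)
  if (light_upper >= moderate_upper) {
    stop("'light_upper' must be strictly below 'moderate_upper'", call. = FALSE)
  }
  structure(list(light_upper = light_upper, moderate_upper = moderate_upper),
            class = "intensity_rule")
}

#' Grade MET values into intensity categories
#'
#' @param met numeric vector of MET values; all must be positive.
#' @param rule an [intensity_rule()].
#' @return character vector with values `"light"`, `"moderate"` or
#'   `"vigorous"`: light iff `met < light_upper`, moderate iff
#'   `light_upper <= met <= moderate_upper`, vigorous iff
#'   `met > moderate_upper`.
#' @examples
#' intensity_category(c(2.5, 3, 6, 6.5))
#' @export
intensity_category <- function(met, rule = intensity_rule()) {
  stopifnot(inherits(rule, "intensity_rule"))
  if (!is.numeric(met) || any(is.na(met)) || any(met <= 0)) {
    stop("MET values must be positive numbers", call. = FALSE)
  }
  ifelse(met < rule$light_upper, "light",
         ifelse(met <= rule$moderate_upper, "moderate", "vigorous"))
}

#' Load a facility-type to MET lookup table
#'
#' Reads a CSV with columns `facility_type`, `met` (and optionally
#' `source_note`). With no path, the lookup shipped with the package (a small
#' curated table of common facility types) is loaded.
#'
#' @param path optional path to a lookup CSV.
#' @return an object of class `met_lookup`: a data frame with columns
#'   `facility_type` and `met`.
#' @export
met_lookup <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "met_lookup.csv", package = "modaccess")
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("facility_type", "met") %in% names(tab))) {
    stop("lookup must have columns 'facility_type' and 'met'", call. = FALSE)
  }
  if (any(tab$met <= 0) || anyNA(tab$met)) {
    stop("all MET values in the lookup must be positive", call. = FALSE)
  }
  if (anyDuplicated(tab$facility_type)) {
    stop("duplicate facility types in lookup", call. = FALSE)
  }
  class(tab) <- c("met_lookup", "data.frame")
  tab
}

# A type absent from the lookup that reads as a generic hall or similar
# multi-purpose space falls back to moderate intensity: the typical activities
# held in such spaces (badminton, table tennis) are moderate. This mirrors the
# conservative convention for church and occasional sports halls.
.hall_like <- function(type) {
  grepl("hall|community|church|centre|center|pavilion", tolower(type))
}

#' Classify a raw facility table by MET intensity
#'
#' Deduplicates facilities (identical `(facility_type, x, y)` records collapse
#' to one), assigns a MET value to each facility type from the lookup, and
#' grades each facility light / moderate / vigorous under the rule. Unknown
#' hall-like types (e.g. "church hall") fall back to moderate intensity; other
#' unknown types are reported in the `rejects` attribute, not silently dropped.
#'
#' @param raw data frame with columns `facility_type`, `x`, `y` (planar
#'   metres) and optionally `facility_id`.
#' @param lookup a [met_lookup()].
#' @param rule an [intensity_rule()].
#' @return a `classified_facilities` data frame with columns `facility_id`,
#'   `facility_type`, `x`, `y`, `met`, `intensity`; attributes `counts` (per
#'   category), `n_duplicates_removed` and `rejects` (unmatched rows).
#' @export
classify_facilities <- function(raw, lookup = met_lookup(),
                                rule = intensity_rule()) {
  stopifnot(is.data.frame(raw))
  if (nrow(lookup) == 0L) stop("lookup is empty", call. = FALSE)
  need <- c("facility_type", "x", "y")
  if (!all(need %in% names(raw))) {
    stop("'raw' needs columns facility_type, x, y", call. = FALSE)
  }
  key <- paste(raw$facility_type, raw$x, raw$y, sep = "\r")
  dup <- duplicated(key)
  fac <- raw[!dup, , drop = FALSE]

  idx <- match(fac$facility_type, lookup$facility_type)
  met <- lookup$met[idx]
  unknown <- is.na(idx)
  hallish <- unknown & .hall_like(fac$facility_type)
  # hall-like fallback: representative moderate MET (badminton/table tennis)
  met[hallish] <- 4.5
  rejects <- fac[unknown & !hallish, c("facility_type", "x", "y"), drop = FALSE]
  keep <- !(unknown & !hallish)
  fac <- fac[keep, , drop = FALSE]
  met <- met[keep]

  out <- data.frame(
    facility_id = if ("facility_id" %in% names(fac)) fac$facility_id else
      sprintf("F%d", seq_len(nrow(fac))),
    facility_type = fac$facility_type,
    x = fac$x, y = fac$y,
    met = met,
    intensity = if (nrow(fac)) intensity_category(met, rule) else character(0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  counts <- table(factor(out$intensity,
                         levels = c("light", "moderate", "vigorous")))
  structure(out,
            counts = counts,
            n_duplicates_removed = sum(dup),
            rejects = rejects,
            class = c("classified_facilities", "data.frame"))
}

#' @export
print.classified_facilities <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf(
    "Classified facilities: %d (light %d, moderate %d, vigorous %d); %d duplicate(s) removed, %d unmatched\n",
    nrow(x), counts[["light"]], counts[["moderate"]], counts[["vigorous"]],
    attr(x, "n_duplicates_removed"), nrow(attr(x, "rejects"))))
  print.data.frame(head(x, 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
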