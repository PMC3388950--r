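# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a clock time to minutes since midnight
#'
#' Accepts `"HH:MM"` or `"HH:MM:SS"`. Used for GTFS-style timetable times and
#' service-window bounds.
#'
#' @param x character vector of clock times.
#' @return numeric vector of minutes since midnight.
#' @examples
#' parse_clock("10:00")      # 600
#' parse_clock("15:59:30")   # 959.5
#' @export
parse_clock <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) < 2L || length(p) > 3L || anyNA(p)) {
      stop("clock times must be 'HH:MM' or 'HH:MM:SS'", call. = FALSE)
    }
    p[1] * 60 + p[2] + if (length(p) == 3L) p[3] / 60 else 0
  }, numeric(1))
}

#' Format minutes since midnight as HH:MM:SS
#'
#' @param m numeric vector, minutes since midnight.
#' @return character vector `"HH:MM:SS"`, seconds rounded to the nearest whole
#'   second.
#' @export
format_clock <- function(m) {
  s <- round(m * 60)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

# Draw a reproducible sub-stream seed from a master seed. Keeps results
# independent across components while governed by one global seed.
substream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  (as.integer(seed) %% 1000000L) * 1009L + offs %% 100003L
}

# Evaluate `expr` under a locally-set RNG seed, restoring prior RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# md5 of an R object via its serialized JSON; used for manifest/stage hashes.
md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}
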