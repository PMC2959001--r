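#' Define the temporal structure of an operant session
#'
#' An operant session is a fixed-length recording window divided into
#' equal, contiguous segments. The default mirrors a 90-minute session
#' split into five 18-minute segments, the design used throughout the
#' package: dispersion is computed over the per-segment trait counts of
#' each session.
#'
#' Segments are half-open intervals
#' `[k * segment_duration_s, (k + 1) * segment_duration_s)`, so every
#' time in `[0, session_duration_s)` belongs to exactly one segment and
#' an event falling exactly on a boundary belongs to the later segment.
#'
#' @param session_duration_s Session length in seconds (default 5400,
#'   i.e. 90 minutes).
#' @param n_segments Number of equal segments (default 5).
#'
#' @return An object of class `session_structure`: a list with
#'   `session_duration_s`, `n_segments` and the derived
#'   `segment_duration_s`.
#' @examples
#' ss <- session_structure()
#' ss$segment_duration_s # 1080 s = 18 min
#' @export
session_structure <- function(session_duration_s = 5400, n_segments = 5) {
  if (!is.numeric(session_duration_s) || length(session_duration_s) != 1 ||
      !is.finite(session_duration_s) || session_duration_s <= 0) {
    abort("`session_duration_s` must be a single positive finite number.")
  }
  if (!is.numeric(n_segments) || length(n_segments) != 1 ||
      !is.finite(n_segments) || n_segments < 1 || n_segments != round(n_segments)) {
    abort("`n_segments` must be a single positive integer.")
  }
  structure(
    list(
      session_duration_s = as.numeric(session_duration_s),
      n_segments = as.integer(n_segments),
      segment_duration_s = as.numeric(session_duration_s) / as.integer(n_segments)
    ),
    class = "session_structure"
  )
}

#' @export
print.session_structure <- function(x, ...) {
  cat(sprintf(
    "<session_structure> %g s session, %d segments of %g s\n",
    x$session_duration_s, x$n_segments, x$segment_duration_s
  ))
  invisible(x)
}

#' Map event times to session segments
#'
#' Assigns each time to the half-open segment interval containing it:
#' `floor(time_s / segment_duration_s)`. Returned indices are 0-based;
#' user-facing tables produced by [extract_traits()] report 1-based
#' segment numbers.
#'
#' @param time_s Numeric vector of times in seconds from session start.
#'   All values must lie in `[0, session_duration_s)`.
#' @param structure A [session_structure()].
#'
#' @return Integer vector of 0-based segment indices.
#' @examples
#' assign_segment(c(0, 1080, 5399.99), session_structure())
#' @export
assign_segment <- function(time_s, structure = session_structure()) {
  stopifnot(inherits(structure, "session_structure"))
  if (!is.numeric(time_s)) abort("`time_s` must be numeric.")
  bad <- !is.finite(time_s) | time_s < 0 | time_s >= structure$session_duration_s
  if (any(bad)) {
    abort(sprintf(
      "%d time value(s) outside the session interval [0, %g); first offender: %s",
      sum(bad), structure$session_duration_s, format(time_s[which(bad)[1]])
    ))
  }
  as.integer(floor(time_s / structure$segment_duration_s))
}
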