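#' Read a behavioral event file
#'
#' Reads a delimited text file of time-stamped operant-chamber events
#' (one row per event) and validates every row against the event model:
#' times must lie in the half-open session interval
#' `[0, session_duration_s)` and event types must be one of
#' `correct_lever`, `incorrect_lever`, `correct_door`, `incorrect_door`,
#' `reinforcer`. The field delimiter is comma by default; tab-delimited
#' files are detected from the header line.
#'
#' Events are returned sorted by `(rat_id, session, time_s)`; rows with
#' tied times keep their file order (a stable sort), which makes
#' downstream inter-response-time computation deterministic.
#'
#' @param path Path to the event file. Must have the header
#'   `rat_id,strain,session,time_s,event_type`.
#' @param structure A [session_structure()]; its `session_duration_s`
#'   bounds valid event times.
#'
#' @return A tibble with columns `rat_id` (character), `strain`
#'   (character), `session` (integer, >= 1), `time_s` (double) and
#'   `event_type` (character).
#' @seealso [write_events()], [simulate_experiment()]
#' @export
read_events <- function(path, structure = session_structure()) {
  stopifnot(inherits(structure, "session_structure"))
  if (!file.exists(path)) abort(sprintf("Event file not found: %s", path))

  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  header_fields <- trimws(strsplit(header, delim, fixed = TRUE)[[1]])
  if (!identical(header_fields, EVENT_COLUMNS)) {
    abort(sprintf(
      "Event file header must be `%s`; got `%s`.",
      paste(EVENT_COLUMNS, collapse = ","), paste(header_fields, collapse = ",")
    ))
  }
  ev <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(
      rat_id = readr::col_character(),
      strain = readr::col_character(),
      session = readr::col_integer(),
      time_s = readr::col_double(),
      event_type = readr::col_character()
    ),
    progress = FALSE,
    show_col_types = FALSE
  )
  if (!identical(names(ev), EVENT_COLUMNS)) {
    abort(sprintf(
      "Event file header must be `%s`; got `%s`.",
      paste(EVENT_COLUMNS, collapse = ","), paste(names(ev), collapse = ",")
    ))
  }
  validate_events(ev, structure, line_offset = 1L)
}

#' Write behavioral events to a delimited text file
#'
#' Writes the standard comma-delimited event format read back by
#' [read_events()]. All fields round-trip exactly (times are written
#' with full precision).
#'
#' @param events Event tibble as produced by [read_events()] or
#'   [simulate_experiment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- events[EVENT_COLUMNS]
  readr::write_csv(events, path, progress = FALSE)
  invisible(path)
}

# Validate an in-memory event table against the event-model invariants.
# line_offset is added to the row index in error messages so that file
# line numbers (header = line 1) can be reported.
validate_events <- function(events, structure = session_structure(),
                            line_offset = 0L) {
  missing_cols <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing_cols) > 0) {
    abort(sprintf("Event table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  fail_row <- function(i, field, why) {
    abort(sprintf("Invalid event at line %d: field `%s` %s.",
                  i + line_offset, field, why))
  }
  bad <- which(is.na(events$rat_id) | events$rat_id == "")
  if (length(bad) > 0) fail_row(bad[1], "rat_id", "is missing")
  bad <- which(is.na(events$strain) | events$strain == "")
  if (length(bad) > 0) fail_row(bad[1], "strain", "is missing")
  bad <- which(is.na(events$session) | events$session < 1)
  if (length(bad) > 0) fail_row(bad[1], "session", "must be an integer >= 1")
  bad <- which(!is.finite(events$time_s) | events$time_s < 0 |
                 events$time_s >= structure$session_duration_s)
  if (length(bad) > 0) {
    fail_row(bad[1], "time_s", sprintf(
      "must lie in [0, %g) (got %s)",
      structure$session_duration_s, format(events$time_s[bad[1]])
    ))
  }
  bad <- which(!(events$event_type %in% EVENT_TYPES))
  if (length(bad) > 0) {
    fail_row(bad[1], "event_type", sprintf(
      "must be one of %s (got \"%s\")",
      paste(EVENT_TYPES, collapse = ", "), events$event_type[bad[1]]
    ))
  }
  ev <- tibble::as_tibble(events)
  ev$session <- as.integer(ev$session)
  dplyr::arrange(ev, .data$rat_id, .data$session, .data$time_s)
}
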