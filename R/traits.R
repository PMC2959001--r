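#' Inter-response times of correct lever presses
#'
#' Computes, for every correct lever press, the time elapsed since the
#' previous correct lever press of the same rat and session (the
#' inter-response time, IRT). IRTs are defined only between consecutive
#' *correct* presses: incorrect-lever presses neither carry an IRT nor
#' reset the clock, IRTs never span sessions, and segment boundaries
#' are not breaks (a pair straddling a boundary yields an IRT carried
#' by the later press). The first correct press of each session has no
#' previous press and gets `NA`.
#'
#' @param events Event tibble (see [read_events()]); must be
#'   time-sorted within rat and session, as every reader/generator in
#'   the package guarantees.
#' @return A tibble with one row per correct lever press: `rat_id`,
#'   `strain`, `session`, `time_s`, `irt_s` (`NA` for the first press
#'   of a session).
#' @examples
#' ev <- tibble::tibble(
#'   rat_id = "r1", strain = "SHR", session = 1L,
#'   time_s = c(10, 10.5, 12), event_type = "correct_lever"
#' )
#' compute_irts(ev)
#' @export
compute_irts <- function(events) {
  events |>
    dplyr::filter(.data$event_type == "correct_lever") |>
    dplyr::group_by(.data$rat_id, .data$strain, .data$session) |>
    dplyr::mutate(irt_s = .data$time_s - dplyr::lag(.data$time_s)) |>
    dplyr::ungroup() |>
    dplyr::select("rat_id", "strain", "session", "time_s", "irt_s")
}

#' Per-segment counts of the three operant traits
#'
#' Converts an event stream into the per-segment trait table the
#' dispersion analysis consumes, using the operational definitions:
#'
#' * **impulsiveness** — correct lever presses whose IRT is defined and
#'   shorter than `irt_threshold_s` (default 0.67 s);
#' * **hyperactivity** — total lever presses (correct + incorrect by
#'   default) *minus* the impulsive presses, so that short-IRT burst
#'   responding does not leak into the activity measure (set
#'   `short_irt_exclusion = FALSE` to keep all presses);
#' * **inattention** — incorrect openings of the reinforcer-cubicle
#'   door.
#'
#' Every `(rat, session)` pair observed in `events` gets exactly
#' `n_segments` rows; segments with no events are explicit zeros.
#' A short-IRT press counts in the segment containing the press itself,
#' so with the default settings `impulsiveness + hyperactivity` equals
#' the total lever presses of each segment.
#'
#' @param events Event tibble.
#' @param structure A [session_structure()].
#' @param irt_threshold_s Impulsiveness IRT threshold in seconds; must
#'   be > 0.
#' @param hyperactivity_levers Which presses count toward
#'   hyperactivity: `"both"` levers (default) or `"correct"` only.
#' @param short_irt_exclusion Apply the short-IRT exclusion to
#'   hyperactivity (default `TRUE`).
#' @return A tibble with columns `rat_id`, `strain`, `session`,
#'   `segment` (1-based), `hyperactivity`, `impulsiveness`,
#'   `inattention`.
#' @seealso [dispersion_table()]
#' @export
extract_traits <- function(events,
                           structure = session_structure(),
                           irt_threshold_s = 0.67,
                           hyperactivity_levers = c("both", "correct"),
                           short_irt_exclusion = TRUE) {
  hyperactivity_levers <- match.arg(hyperactivity_levers)
  if (!is.numeric(irt_threshold_s) || length(irt_threshold_s) != 1 ||
      !is.finite(irt_threshold_s) || irt_threshold_s <= 0) {
    abort("`irt_threshold_s` must be a single positive number.")
  }
  events <- validate_events(events, structure)

  grid <- events |>
    dplyr::distinct(.data$rat_id, .data$strain, .data$session) |>
    tidyr::crossing(segment = seq_len(structure$n_segments))

  lever <- events |>
    dplyr::filter(.data$event_type %in% c("correct_lever", "incorrect_lever")) |>
    dplyr::mutate(segment = assign_segment(.data$time_s, structure) + 1L)
  if (hyperactivity_levers == "correct") {
    lever <- dplyr::filter(lever, .data$event_type == "correct_lever")
  }
  lever_counts <- lever |>
    dplyr::count(.data$rat_id, .data$strain, .data$session, .data$segment,
                 name = "n_lever")

  impulsive <- compute_irts(events) |>
    dplyr::filter(!is.na(.data$irt_s), .data$irt_s < irt_threshold_s) |>
    dplyr::mutate(segment = assign_segment(.data$time_s, structure) + 1L) |>
    dplyr::count(.data$rat_id, .data$strain, .data$session, .data$segment,
                 name = "impulsiveness")

  door <- events |>
    dplyr::filter(.data$event_type == "incorrect_door") |>
    dplyr::mutate(segment = assign_segment(.data$time_s, structure) + 1L) |>
    dplyr::count(.data$rat_id, .data$strain, .data$session, .data$segment,
                 name = "inattention")

  grid |>
    dplyr::left_join(lever_counts,
                     by = c("rat_id", "strain", "session", "segment")) |>
    dplyr::left_join(impulsive,
                     by = c("rat_id", "strain", "session", "segment")) |>
    dplyr::left_join(door,
                     by = c("rat_id", "strain", "session", "segment")) |>
    dplyr::mutate(
      dplyr::across(c("n_lever", "impulsiveness", "inattention"),
                    ~ tidyr::replace_na(.x, 0L)),
      hyperactivity = .data$n_lever -
        if (short_irt_exclusion) .data$impulsiveness else 0L
    ) |>
    dplyr::select("rat_id", "strain", "session", "segment",
                  "hyperactivity", "impulsiveness", "inattention") |>
    dplyr::arrange(.data$rat_id, .data$session, .data$segment)
}
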