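#' Phenotypic dispersion of one session
#'
#' The core intra-individual variability statistic: the mean absolute
#' deviation of a session's per-segment trait values from that
#' session's mean,
#' \deqn{PD = \frac{1}{J}\sum_{j=1}^{J} |x_j - \bar{x}|,}
#' with the plain divisor `J` (no n-1 correction). `PD = 0` exactly
#' when all segment values are equal; the statistic is invariant to
#' permutation and translation of the segment values and scales as
#' `|c|` under multiplication by `c`.
#'
#' @param segment_values Numeric vector of per-segment values for one
#'   session; length >= 2, all finite.
#' @return A list with elements `pd` and `session_mean`.
#' @examples
#' pd_session(c(2, 4, 6, 8, 10)) # pd = 2.4, mean = 6
#' @export
pd_session <- function(segment_values) {
  if (!is.numeric(segment_values) || length(segment_values) < 2) {
    abort("`segment_values` must be a numeric vector of length >= 2.")
  }
  if (!all(is.finite(segment_values))) {
    abort("`segment_values` must be finite.")
  }
  m <- mean(segment_values)
  list(pd = mean(abs(segment_values - m)), session_mean = m)
}

# Long view of a trait table, with completeness check.
traits_long <- function(traits, n_segments) {
  long <- traits |>
    tidyr::pivot_longer(dplyr::all_of(TRAITS),
                        names_to = "trait", values_to = "value") |>
    dplyr::mutate(trait = factor(.data$trait, levels = TRAITS))
  check <- traits |>
    dplyr::count(.data$rat_id, .data$session, name = "n_seg") |>
    dplyr::filter(.data$n_seg != n_segments)
  if (nrow(check) > 0) {
    abort(sprintf(
      "Incomplete trait table: rat %s session %d has %d segment rows (expected %d).",
      check$rat_id[1], check$session[1], check$n_seg[1], n_segments
    ))
  }
  long
}

#' Per-session phenotypic dispersion table
#'
#' Applies [pd_session()] to every `(rat, session, trait)` cell of a
#' per-segment trait table, yielding one dispersion value per rat per
#' session per trait — the unit of all downstream strain comparisons.
#'
#' @param traits Trait table from [extract_traits()]; every rat-session
#'   must have all `n_segments` rows.
#' @param n_segments Expected segments per session (default 5).
#' @return A tibble with columns `rat_id`, `strain`, `session`,
#'   `trait`, `pd`, `session_mean`.
#' @export
dispersion_table <- function(traits, n_segments = 5) {
  traits_long(traits, n_segments) |>
    dplyr::summarise(
      pd = mean(abs(.data$value - mean(.data$value))),
      session_mean = mean(.data$value),
      .by = c("rat_id", "strain", "session", "trait")
    ) |>
    dplyr::arrange(.data$rat_id, .data$session, .data$trait)
}

#' Per-segment mean absolute deviation, averaged over sessions
#'
#' The segment-resolved companion of [dispersion_table()], used by the
#' within-session trend analysis: for each rat, trait and segment `k`,
#' the absolute deviation of the segment value from its own session's
#' mean, averaged over sessions. Averaging these values over segments
#' recovers the rat's mean per-session dispersion, so the two views are
#' consistent.
#'
#' @inheritParams dispersion_table
#' @return A tibble with columns `rat_id`, `strain`, `trait`, `segment`
#'   (1-based), `mean_abs_dev`.
#' @seealso [within_sessions_model()]
#' @export
segment_deviation_table <- function(traits, n_segments = 5) {
  traits_long(traits, n_segments) |>
    dplyr::mutate(dev = abs(.data$value - mean(.data$value)),
                  .by = c("rat_id", "session", "trait")) |>
    dplyr::summarise(
      mean_abs_dev = mean(.data$dev),
      .by = c("rat_id", "strain", "trait", "segment")
    ) |>
    dplyr::arrange(.data$rat_id, .data$trait, .data$segment)
}
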