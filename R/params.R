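#' Strain-level generative parameters for the synthetic event stream
#'
#' Bundles the knobs that govern one strain's simulated operant
#' behavior. Rates are per minute; the two inter-response-time (IRT)
#' mixture components must straddle the 0.67 s impulsiveness threshold
#' so that "burst" presses are the ones an IRT-based impulsiveness
#' count picks up.
#'
#' @param base_lever_rate Mean lever-press rate across rats
#'   (responses/min).
#' @param rat_rate_sd_log SD of the rat-level log-rate random effect
#'   (between-rat heterogeneity).
#' @param segment_dispersion_sd_log SD of the segment-level
#'   multiplicative log-normal rate noise — the intra-individual
#'   variability knob. Larger values produce larger phenotypic
#'   dispersion downstream.
#' @param dispersion_trend_per_segment Additive change in the
#'   segment-level log-noise SD per unit 0-based segment index (the
#'   within-session IIV trend knob); the effective SD is floored at 0.
#' @param burst_prob Probability that a press's IRT is drawn from the
#'   short "burst" component.
#' @param burst_irt_mean_s Mean of the short-IRT exponential component;
#'   must be < 0.67 s.
#' @param nonburst_irt_mean_s Nominal mean of the long-IRT exponential
#'   component; must be > 0.67 s.
#' @param incorrect_door_rate Incorrect door-opening rate (events/min),
#'   modulated by the same segment multiplier as lever pressing.
#' @param incorrect_lever_frac Fraction of lever presses landing on the
#'   wrong (extinction) lever.
#'
#' @return An object of class `strain_params` (a validated list).
#' @seealso [shr_like_params()], [wky_like_params()],
#'   [simulate_experiment()]
#' @export
strain_params <- function(base_lever_rate,
                          rat_rate_sd_log = 0,
                          segment_dispersion_sd_log = 0,
                          dispersion_trend_per_segment = 0,
                          burst_prob = 0,
                          burst_irt_mean_s = 0.3,
                          nonburst_irt_mean_s = 4,
                          incorrect_door_rate = 0,
                          incorrect_lever_frac = 0) {
  p <- list(
    base_lever_rate = base_lever_rate,
    rat_rate_sd_log = rat_rate_sd_log,
    segment_dispersion_sd_log = segment_dispersion_sd_log,
    dispersion_trend_per_segment = dispersion_trend_per_segment,
    burst_prob = burst_prob,
    burst_irt_mean_s = burst_irt_mean_s,
    nonburst_irt_mean_s = nonburst_irt_mean_s,
    incorrect_door_rate = incorrect_door_rate,
    incorrect_lever_frac = incorrect_lever_frac
  )
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                  logical(1)))) {
    abort("All strain parameters must be single finite numbers.")
  }
  nonneg <- c("base_lever_rate", "rat_rate_sd_log", "segment_dispersion_sd_log",
              "burst_irt_mean_s", "nonburst_irt_mean_s", "incorrect_door_rate")
  for (nm in nonneg) {
    if (p[[nm]] < 0) abort(sprintf("`%s` must be >= 0.", nm))
  }
  for (nm in c("burst_prob", "incorrect_lever_frac")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) abort(sprintf("`%s` must be in [0, 1].", nm))
  }
  if (!(p$burst_irt_mean_s < 0.67 && p$nonburst_irt_mean_s > 0.67)) {
    abort("Need burst_irt_mean_s < 0.67 < nonburst_irt_mean_s so the impulsiveness threshold separates the IRT mixture components.")
  }
  structure(p, class = "strain_params")
}

#' Shipped parameter presets for the two canonical strains
#'
#' Preset generative parameters emulating, directionally, an
#' ADHD-model strain (SHR-like: higher press rate, more burst
#' responding, more incorrect door openings, larger segment-to-segment
#' dispersion, dispersion increasing within session) versus a control
#' strain (WKY-like: calmer on every axis, mild downward
#' within-session dispersion trend). The values are design choices for
#' a realistic variable-interval operant preparation, not estimates
#' fitted to any particular dataset.
#'
#' @return A `strain_params` object.
#' @export
shr_like_params <- function() {
  strain_params(
    base_lever_rate = 18,
    rat_rate_sd_log = 0.25,
    segment_dispersion_sd_log = 0.35,
    dispersion_trend_per_segment = 0.04,
    burst_prob = 0.35,
    burst_irt_mean_s = 0.30,
    nonburst_irt_mean_s = 4,
    incorrect_door_rate = 3,
    incorrect_lever_frac = 0.25
  )
}

#' @rdname shr_like_params
#' @export
wky_like_params <- function() {
  strain_params(
    base_lever_rate = 10,
    rat_rate_sd_log = 0.20,
    segment_dispersion_sd_log = 0.15,
    dispersion_trend_per_segment = -0.02,
    burst_prob = 0.15,
    burst_irt_mean_s = 0.35,
    nonburst_irt_mean_s = 5,
    incorrect_door_rate = 0.8,
    incorrect_lever_frac = 0.15
  )
}

#' Design of a simulated operant experiment
#'
#' The experimental layout the generator reproduces: how many rats per
#' strain, how many daily sessions, the session/segment structure and
#' the mean of the variable-interval (VI) reinforcement schedule. The
#' defaults are the canonical two-strain design: 16 SHR and 15 WKY
#' rats, five 90-minute sessions, VI 180 s.
#'
#' @param n_rats Named integer vector: rats per strain. Names are the
#'   strain labels.
#' @param n_sessions Number of sessions (one per day), >= 1.
#' @param structure A [session_structure()].
#' @param vi_mean_s Mean of the exponential inter-availability wait of
#'   the VI schedule, seconds.
#'
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_rats = c(SHR = 16, WKY = 15),
                              n_sessions = 5,
                              structure = session_structure(),
                              vi_mean_s = 180) {
  if (is.null(names(n_rats)) || any(names(n_rats) == "")) {
    abort("`n_rats` must be a named vector (names are strain labels).")
  }
  if (any(n_rats < 1) || any(n_rats != round(n_rats))) {
    abort("Each strain needs at least one rat (integer counts).")
  }
  if (!is.numeric(n_sessions) || n_sessions < 1 || n_sessions != round(n_sessions)) {
    abort("`n_sessions` must be an integer >= 1.")
  }
  if (!is.numeric(vi_mean_s) || !is.finite(vi_mean_s) || vi_mean_s <= 0) {
    abort("`vi_mean_s` must be a positive finite number.")
  }
  stopifnot(inherits(structure, "session_structure"))
  structure(
    list(
      n_rats = setNames(as.integer(n_rats), names(n_rats)),
      n_sessions = as.integer(n_sessions),
      structure = structure,
      vi_mean_s = as.numeric(vi_mean_s)
    ),
    class = "simulation_design"
  )
}

#' Read a simulation configuration file
#'
#' Reads a YAML file describing a [simulation_design()] and one
#' [strain_params()] block per strain. Recognized design keys:
#' `n_rats` (map of strain label to count), `n_sessions`,
#' `session_duration_s`, `n_segments`, `vi_mean_s`. Each entry under
#' `strains:` holds `strain_params()` arguments.
#'
#' A complete example mirroring the shipped presets is installed at
#' `system.file("extdata", "default-sim-config.yml", package = "operantiiv")`.
#'
#' @param path Path to the YAML configuration file.
#' @return A list with elements `design` (a `simulation_design`) and
#'   `params` (named list of `strain_params`, one per strain).
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  d <- cfg$design %||% list()
  strains <- cfg$strains
  if (is.null(strains) || length(strains) == 0) {
    abort("Config must define at least one entry under `strains:`.")
  }
  n_rats <- unlist(d$n_rats %||% abort("Config `design:` must give `n_rats`."))
  design <- simulation_design(
    n_rats = n_rats,
    n_sessions = d$n_sessions %||% 5,
    structure = session_structure(
      session_duration_s = d$session_duration_s %||% 5400,
      n_segments = d$n_segments %||% 5
    ),
    vi_mean_s = d$vi_mean_s %||% 180
  )
  missing_strains <- setdiff(names(design$n_rats), names(strains))
  if (length(missing_strains) > 0) {
    abort(sprintf("Config lacks `strains:` entries for: %s",
                  paste(missing_strains, collapse = ", ")))
  }
  params <- lapply(strains, function(s) do.call(strain_params, s))
  list(design = design, params = params[names(design$n_rats)])
}
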