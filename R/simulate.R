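#' Sample inter-response times from the burst/non-burst mixture
#'
#' Lever pressing is modeled as a renewal process whose inter-response
#' times (IRTs) come from a two-component exponential mixture: with
#' probability `burst_prob` a short "burst" IRT (mean
#' `burst_irt_mean_s`), otherwise a long IRT whose mean is chosen so
#' the mixture mean equals `60 / target_rate` seconds. If the required
#' non-burst mean would fall below the 0.67 s impulsiveness threshold
#' (so the components would no longer straddle it), both component
#' means are instead rescaled proportionally from their nominal values,
#' preserving the target mixture mean. With `burst_prob = 1` every IRT
#' is a burst IRT and no rate matching is attempted.
#'
#' @param n Number of IRTs to draw.
#' @param params A [strain_params()] object.
#' @param target_rate Target press rate, responses/min; must be > 0.
#' @return Numeric vector of `n` positive IRTs in seconds.
#' @export
r_irt_mixture <- function(n, params, target_rate) {
  stopifnot(inherits(params, "strain_params"))
  if (!is.numeric(target_rate) || length(target_rate) != 1 ||
      !is.finite(target_rate) || target_rate <= 0) {
    abort("`target_rate` must be a single positive finite rate (responses/min).")
  }
  if (n == 0) return(numeric(0))
  mu <- irt_component_means(params, target_rate)
  p <- params$burst_prob
  if (p <= 0) return(rexp(n) * mu$nonburst)
  if (p >= 1) return(rexp(n) * mu$burst)
  is_burst <- runif(n) < p
  e <- rexp(n)
  ifelse(is_burst, e * mu$burst, e * mu$nonburst)
}

# Resolve the two component means for a target rate. The non-burst
# mean is rate-matched; if it would cross the 0.67 s threshold, both
# nominal component means are rescaled by a common factor instead.
irt_component_means <- function(params, target_rate, floor_s = 0.67) {
  m_t <- 60 / target_rate
  p <- params$burst_prob
  b <- params$burst_irt_mean_s
  if (p >= 1) return(list(burst = b, nonburst = params$nonburst_irt_mean_s))
  if (p <= 0) return(list(burst = b, nonburst = m_t))
  m2 <- (m_t - p * b) / (1 - p)
  if (m2 >= floor_s) return(list(burst = b, nonburst = m2))
  nominal_mean <- p * b + (1 - p) * params$nonburst_irt_mean_s
  c_scale <- m_t / nominal_mean
  list(burst = b * c_scale, nonburst = params$nonburst_irt_mean_s * c_scale)
}

#' Simulate a two-strain operant experiment
#'
#' Generates a full synthetic event stream with the statistical
#' structure the dispersion analysis assumes. For each rat a log-rate
#' random effect is drawn once; for each session segment a
#' multiplicative log-normal rate multiplier `exp(N(0, sigma_k^2))` is
#' drawn, where `sigma_k = segment_dispersion_sd_log +
#' dispersion_trend_per_segment * k` (0-based segment `k`, floored at
#' 0) — this is the intra-individual variability injection. Lever
#' presses follow the renewal process of [r_irt_mixture()] at the
#' segment's target rate; each press lands on the wrong lever with
#' probability `incorrect_lever_frac`. Incorrect door openings are a
#' homogeneous Poisson process at `incorrect_door_rate` times the same
#' segment multiplier. Reinforcement follows a variable-interval
#' schedule: after each reinforcer the next availability is an
#' exponential wait of mean `vi_mean_s` clipped to
#' `[1 s, 3 * vi_mean_s]`, and the first correct lever press at or
#' after availability triggers a `reinforcer` event followed by one
#' `correct_door` event after a log-normal latency (median 1.5 s,
#' log-SD 0.4).
#'
#' Each rat is simulated from its own deterministic RNG substream
#' derived from `seed`, so identical `(design, params, seed)` yield a
#' bit-identical event table and adding rats to a strain leaves the
#' existing rats' events unchanged. The caller's RNG state is
#' restored on exit.
#'
#' @param design A [simulation_design()].
#' @param params Named list of [strain_params()], one per strain label
#'   in `design$n_rats`.
#' @param seed Integer seed governing every random draw.
#' @return An event tibble (`rat_id`, `strain`, `session`, `time_s`,
#'   `event_type`) sorted by rat, session and time, satisfying every
#'   event-model invariant.
#' @examples
#' design <- simulation_design(n_rats = c(SHR = 2, WKY = 2), n_sessions = 1)
#' ev <- simulate_experiment(design, seed = 42)
#' dplyr::count(ev, strain, event_type)
#' @export
simulate_experiment <- function(design = simulation_design(),
                                params = list(SHR = shr_like_params(),
                                              WKY = wky_like_params()),
                                seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  strains <- names(design$n_rats)
  missing_p <- setdiff(strains, names(params))
  if (length(missing_p) > 0) {
    abort(sprintf("`params` lacks entries for strain(s): %s",
                  paste(missing_p, collapse = ", ")))
  }
  for (s in strains) {
    if (!inherits(params[[s]], "strain_params")) {
      abort(sprintf("`params$%s` must be a `strain_params` object.", s))
    }
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single integer.")
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }

  id_width <- max(2L, nchar(as.character(max(design$n_rats))))
  pieces <- vector("list", sum(design$n_rats))
  k <- 0L
  for (si in seq_along(strains)) {
    s <- strains[si]
    for (r in seq_len(design$n_rats[[s]])) {
      k <- k + 1L
      set.seed(derive_rat_seed(seed, si, r))
      pieces[[k]] <- simulate_rat(
        rat_id = sprintf("%s_%0*d", s, id_width, r),
        strain = s, params = params[[s]], design = design
      )
    }
  }
  ev <- dplyr::bind_rows(pieces)
  dplyr::arrange(ev, .data$rat_id, .data$session, .data$time_s)
}

# Deterministic per-rat substream seed: the (seed, strain, rat) triple
# is mixed through Lehmer-style multiplicative rounds mod 2^31 - 1, so
# substreams from nearby master seeds do not collide or overlap in
# structured ways. All arithmetic stays exact in doubles (< 2^53).
derive_rat_seed <- function(seed, strain_index, rat_index) {
  p <- 2147483647
  x <- (as.numeric(seed) %% p) + 1
  x <- (48271 * x + 104729 * strain_index) %% p
  x <- (48271 * x + 7919 * rat_index) %% p
  as.integer((48271 * x) %% p)
}

# One rat's full event stream, using the current RNG state.
simulate_rat <- function(rat_id, strain, params, design) {
  ss <- design$structure
  seg_dur <- ss$segment_duration_s
  n_seg <- ss$n_segments
  dur <- ss$session_duration_s
  vi <- design$vi_mean_s

  rat_effect <- rnorm(1, 0, params$rat_rate_sd_log)

  times <- list(); types <- list(); sessions <- list()
  ptr <- 0L
  push <- function(t, type, session) {
    if (length(t) == 0) return(invisible(NULL))
    ptr <<- ptr + 1L
    times[[ptr]] <<- t
    types[[ptr]] <<- rep(type, length(t))
    sessions[[ptr]] <<- rep(session, length(t))
    invisible(NULL)
  }

  for (sess in seq_len(design$n_sessions)) {
    correct_times <- numeric(0)
    for (k in seq_len(n_seg) - 1L) {
      sigma_k <- max(0, params$segment_dispersion_sd_log +
                       params$dispersion_trend_per_segment * k)
      mult <- exp(rnorm(1, 0, sigma_k))
      rate <- params$base_lever_rate * exp(rat_effect) * mult
      seg_start <- k * seg_dur

      if (rate > 0) {
        press_t <- sample_renewal_times(params, rate, seg_dur) + seg_start
        if (length(press_t) > 0) {
          incorrect <- runif(length(press_t)) < params$incorrect_lever_frac
          push(press_t[!incorrect], "correct_lever", sess)
          push(press_t[incorrect], "incorrect_lever", sess)
          correct_times <- c(correct_times, press_t[!incorrect])
        }
      }

      door_lambda <- params$incorrect_door_rate / 60 * seg_dur * mult
      n_door <- rpois(1, door_lambda)
      if (n_door > 0) {
        push(seg_start + sort(runif(n_door)) * seg_dur, "incorrect_door", sess)
      }
    }

    # VI schedule: scan correct presses against successive availabilities.
    ct <- sort(correct_times)
    draw_wait <- function() min(max(rexp(1, 1 / vi), 1), 3 * vi)
    avail <- draw_wait()
    j <- 1L
    n_ct <- length(ct)
    while (j <= n_ct) {
      while (j <= n_ct && ct[j] < avail) j <- j + 1L
      if (j > n_ct) break
      hit <- ct[j]
      push(hit, "reinforcer", sess)
      door_t <- hit + rlnorm(1, log(1.5), 0.4)
      if (door_t < dur) push(door_t, "correct_door", sess)
      avail <- hit + draw_wait()
      j <- j + 1L
    }
  }

  tibble::tibble(
    rat_id = rat_id,
    strain = strain,
    session = unlist(sessions) %||% integer(0),
    time_s = unlist(times) %||% numeric(0),
    event_type = unlist(types) %||% character(0)
  )
}

# Renewal-process press times within one segment: draw mixture IRTs in
# chunks until their cumulative sum exceeds the segment duration.
sample_renewal_times <- function(params, rate, seg_dur) {
  mean_irt <- 60 / rate
  out <- numeric(0)
  total <- 0
  while (total < seg_dur) {
    n_chunk <- max(10L, ceiling((seg_dur - total) / mean_irt * 1.4) + 10L)
    irts <- r_irt_mixture(n_chunk, params, rate)
    out <- c(out, irts)
    total <- total + sum(irts)
  }
  t_all <- cumsum(out)
  t_all[t_all < seg_dur]
}
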