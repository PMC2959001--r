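small_design <- function(nA = 3, nB = 2, n_sessions = 2) {
  simulation_design(n_rats = c(SHR = nA, WKY = nB), n_sessions = n_sessions)
}

calm_params <- function(burst_prob = 0.2) {
  strain_params(base_lever_rate = 6, rat_rate_sd_log = 0.2,
                segment_dispersion_sd_log = 0.2, burst_prob = burst_prob,
                incorrect_door_rate = 1, incorrect_lever_frac = 0.2)
}

test_that("strain parameter validation enforces the documented bounds", {
  expect_error(strain_params(base_lever_rate = -1), ">= 0")
  expect_error(strain_params(10, burst_prob = 1.2), "\\[0, 1\\]")
  expect_error(strain_params(10, burst_irt_mean_s = 0.8),
               "impulsiveness threshold")
  expect_error(strain_params(10, nonburst_irt_mean_s = 0.5),
               "impulsiveness threshold")
  expect_error(strain_params(NaN), "finite")
  expect_error(simulation_design(n_rats = c(SHR = 0, WKY = 5)),
               "at least one rat")
})

test_that("IRT mixture hits its target mean and degenerates correctly", {
  p <- calm_params(burst_prob = 0.3)
  # plain exponential when burst_prob = 0
  withr::with_seed(1, {
    x0 <- r_irt_mixture(1e5, calm_params(burst_prob = 0), target_rate = 12)
    expect_equal(mean(x0), 5, tolerance = 0.02)
    # all-burst when burst_prob = 1
    x1 <- r_irt_mixture(1e4, calm_params(burst_prob = 1), target_rate = 12)
    expect_equal(mean(x1), 0.3, tolerance = 0.05)
    # mixture mean matches 60/target_rate within 2%
    xm <- r_irt_mixture(1e5, p, target_rate = 10)
    expect_equal(mean(xm), 6, tolerance = 0.02)
    # floor-rescale branch (required non-burst mean < 0.67 s) still
    # matches the target mean
    xf <- r_irt_mixture(1e5, p, target_rate = 150)
    expect_equal(mean(xf), 0.4, tolerance = 0.02)
    expect_true(all(xm > 0) && all(xf > 0))
  })
  expect_error(r_irt_mixture(10, p, target_rate = 0), "positive")
  expect_error(r_irt_mixture(10, p, target_rate = -3), "positive")
})

test_that("zero rates emit zero events", {
  ev <- simulate_experiment(
    small_design(),
    params = list(SHR = strain_params(0), WKY = strain_params(0)),
    seed = 5
  )
  expect_equal(nrow(ev), 0)
  expect_named(ev, c("rat_id", "strain", "session", "time_s", "event_type"))
})

test_that("simulated streams satisfy every event-model invariant", {
  d <- small_design(3, 3, 2)
  ev <- simulate_experiment(d, list(SHR = calm_params(), WKY = calm_params()),
                            seed = 9)
  expect_silent(operantiiv:::validate_events(ev, d$structure))
  expect_true(all(ev$time_s >= 0 & ev$time_s < 5400))
  expect_true(all(ev$event_type %in% c(
    "correct_lever", "incorrect_lever", "correct_door", "incorrect_door",
    "reinforcer")))
  # sorted within rat-session
  by_rs <- split(ev$time_s, paste(ev$rat_id, ev$session))
  expect_true(all(vapply(by_rs, function(t) !is.unsorted(t), logical(1))))
  # every reinforcer coincides with a correct lever press
  reinf <- ev[ev$event_type == "reinforcer", ]
  pressed <- ev[ev$event_type == "correct_lever", ]
  key <- paste(pressed$rat_id, pressed$session, pressed$time_s)
  expect_true(all(paste(reinf$rat_id, reinf$session, reinf$time_s) %in% key))
  # reinforcers are spaced at least 1 s apart (VI wait floor)
  gaps <- unlist(lapply(split(reinf$time_s, paste(reinf$rat_id, reinf$session)),
                        diff))
  expect_true(all(gaps >= 1))
})

test_that("identical seed reproduces the stream; new rats do not perturb old ones", {
  d <- small_design()
  p <- list(SHR = calm_params(), WKY = calm_params())
  ev1 <- simulate_experiment(d, p, seed = 123)
  ev2 <- simulate_experiment(d, p, seed = 123)
  expect_identical(ev1, ev2)
  ev3 <- simulate_experiment(d, p, seed = 124)
  expect_false(identical(ev1, ev3))

  # adding a rat to a strain leaves existing rats' events unchanged
  bigger <- simulate_experiment(small_design(nA = 4), p, seed = 123)
  expect_identical(
    dplyr::filter(bigger, rat_id != "SHR_04"),
    ev1
  )
})

test_that("simulation does not disturb the caller's RNG stream", {
  withr::with_seed(77, {
    r1 <- runif(1)
    invisible(simulate_experiment(small_design(1, 1, 1),
                                  list(SHR = calm_params(),
                                       WKY = calm_params()), seed = 3))
    r2 <- runif(1)
  })
  withr::with_seed(77, expected <- runif(2))
  expect_identical(c(r1, r2), expected)
})

test_that("mean press rate is recovered when dispersion knobs are off", {
  p <- strain_params(base_lever_rate = 10, rat_rate_sd_log = 0,
                     segment_dispersion_sd_log = 0, burst_prob = 0.3,
                     incorrect_door_rate = 0, incorrect_lever_frac = 0.2)
  ev <- simulate_experiment(simulation_design(),
                            list(SHR = p, WKY = p), seed = 21)
  lever <- dplyr::filter(ev, event_type %in% c("correct_lever",
                                               "incorrect_lever"))
  n_cells <- 31 * 5 * 5 # rats x sessions x segments
  mean_per_segment <- nrow(lever) / n_cells
  expect_equal(mean_per_segment, 10 * 18, tolerance = 0.05)
})

test_that("the shipped config file reproduces the preset experiment", {
  cfg <- read_sim_config(system.file("extdata", "default-sim-config.yml",
                                     package = "operantiiv"))
  expect_equal(cfg$design$n_rats, c(SHR = 16L, WKY = 15L))
  expect_equal(cfg$design$vi_mean_s, 180)
  expect_equal(unclass(cfg$params$SHR), unclass(shr_like_params()))
  expect_equal(unclass(cfg$params$WKY), unclass(wky_like_params()))

  # identical parameters => identical stream at a fixed seed
  d_small <- simulation_design(n_rats = c(SHR = 2, WKY = 1), n_sessions = 1)
  expect_identical(
    simulate_experiment(d_small, cfg$params, seed = 8),
    simulate_experiment(d_small, seed = 8)
  )
})
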