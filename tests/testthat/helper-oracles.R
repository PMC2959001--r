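# Independent brute-force oracles and small fixture builders used
# across the suite. These deliberately avoid the package's own code
# paths (explicit loops, direct sums of squares).

# Mean absolute deviation, written as an explicit loop.
mad_oracle <- function(x) {
  m <- sum(x) / length(x)
  acc <- 0
  for (v in x) acc <- acc + abs(v - m)
  acc / length(x)
}

# Eta-squared from explicit sums of squares.
eta2_oracle <- function(y, g) {
  grand <- mean(y)
  ssb <- 0
  for (lv in unique(g)) {
    yg <- y[g == lv]
    ssb <- ssb + length(yg) * (mean(yg) - grand)^2
  }
  ssb / sum((y - grand)^2)
}

# Two-group rank-sum z statistic (normal approximation, no continuity
# correction); its square equals the tie-free Kruskal-Wallis H.
ranksum_z_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2); n <- n1 + n2
  r <- rank(c(x1, x2))
  w <- sum(r[seq_len(n1)])
  (w - n1 * (n + 1) / 2) / sqrt(n1 * n2 * (n + 1) / 12)
}

# Dispersion table built directly from per-rat-session values: `y` is
# a matrix (rats x sessions), rownames are rat ids.
make_pd_tbl <- function(y, strain, trait = "hyperactivity") {
  stopifnot(nrow(y) == length(strain))
  ids <- rownames(y) %||% sprintf("r%02d", seq_len(nrow(y)))
  tidyr::crossing(rat = seq_len(nrow(y)), session = seq_len(ncol(y))) |>
    dplyr::mutate(
      rat_id = ids[rat], strain = strain[rat], trait = trait,
      pd = y[cbind(rat, session)], session_mean = NA_real_
    ) |>
    dplyr::select(rat_id, strain, session, trait, pd, session_mean)
}

# Trait table built from a rat x session x segment array of counts,
# same counts for all three traits unless overridden.
make_trait_tbl <- function(arr, strain) {
  d <- dim(arr)
  tidyr::crossing(rat = seq_len(d[1]), session = seq_len(d[2]),
                  segment = seq_len(d[3])) |>
    dplyr::mutate(
      rat_id = sprintf("r%02d", rat), strain = strain[rat],
      hyperactivity = arr[cbind(rat, session, segment)],
      impulsiveness = arr[cbind(rat, session, segment)],
      inattention = arr[cbind(rat, session, segment)]
    ) |>
    dplyr::select(rat_id, strain, session, segment,
                  hyperactivity, impulsiveness, inattention)
}

# Event tibble builder for hand-constructed cases.
make_events <- function(time_s, event_type, rat_id = "r01", strain = "SHR",
                        session = 1L) {
  tibble::tibble(rat_id = rat_id, strain = strain,
                 session = as.integer(session),
                 time_s = time_s, event_type = event_type)
}

`%||%` <- rlang::`%||%`
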