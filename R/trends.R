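# Repeated-measures trend analyses: dispersion over sessions (days)
# and over segments within sessions.

# Univariate repeated-measures ANOVA with rat as subject: between
# factor `strain`, within factor `within` (categorical). Returns the
# three effect tests. Requires listwise completeness.
rm_anova <- function(df, within_name) {
  df$strain_f <- factor(df$strain)
  df$within_f <- factor(df$within)
  df$rat_f <- factor(df$rat_id)
  counts <- table(df$rat_f)
  if (length(unique(counts)) != 1 || any(counts != nlevels(df$within_f))) {
    abort(sprintf(
      "Unbalanced design: every rat must have exactly one value per %s.",
      within_name
    ))
  }
  fit <- aov(y ~ strain_f * within_f + Error(rat_f), data = df)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: rat_f"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  term <- function(tab, nm) {
    i <- match(nm, trimws(rownames(tab)))
    tibble::tibble(df1 = tab$Df[i],
                   F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  dplyr::bind_rows(
    dplyr::mutate(term(between, "strain_f"), term = "strain",
                  df2 = between$Df[match("Residuals", trimws(rownames(between)))]),
    dplyr::mutate(term(within, "within_f"), term = within_name,
                  df2 = within$Df[match("Residuals", trimws(rownames(within)))]),
    dplyr::mutate(term(within, "strain_f:within_f"), term = "interaction",
                  df2 = within$Df[match("Residuals", trimws(rownames(within)))])
  ) |>
    dplyr::select("term", "df1", "df2", "F", "p")
}

# Per-strain linear slope of `y` on `index`, treating the rat as the
# repeated unit: one OLS slope per rat, summarized across rats
# (mean, SE = sd/sqrt(n), two-sided t test). A pooled row aggregates
# all rats. SE = 0 (all rats share one exact slope) is degenerate:
# p is NA with a warning.
per_strain_slopes <- function(df) {
  rat_slopes <- df |>
    dplyr::summarise(
      slope = {
        x <- .data$index - mean(.data$index)
        sum(x * .data$y) / sum(x^2)
      },
      .by = c("rat_id", "strain")
    )
  summarize_slopes <- function(d, label) {
    n <- nrow(d)
    beta <- mean(d$slope)
    se <- if (n > 1) sd(d$slope) / sqrt(n) else NA_real_
    if (!is.na(se) && se == 0) {
      warn(sprintf("Slope SE is 0 for %s (all rats share one exact slope); p set to NA.",
                   label))
      p <- NA_real_
    } else if (is.na(se)) {
      p <- NA_real_
    } else {
      p <- 2 * pt(-abs(beta / se), df = n - 1)
    }
    tibble::tibble(strain = label, n_rats = n, beta = beta, se = se, p = p)
  }
  dplyr::bind_rows(
    df |>
      dplyr::distinct(.data$strain) |>
      dplyr::arrange(.data$strain) |>
      dplyr::pull("strain") |>
      purrr::map(~ summarize_slopes(dplyr::filter(rat_slopes, .data$strain == .x), .x)),
    summarize_slopes(rat_slopes, "pooled")
  )
}

new_trend_fit <- function(trait, scope, effects, slopes, slope_scale, log_offset) {
  structure(
    list(trait = trait, scope = scope, effects = effects, slopes = slopes,
         slope_scale = slope_scale, log_offset = log_offset),
    class = "trend_fit"
  )
}

#' Dispersion trend among sessions (day-to-day)
#'
#' Tests whether dispersion changes across consecutive daily sessions
#' and whether that change differs by strain. Dispersion is
#' log-transformed (`log(pd + log_offset)`) and analyzed with a
#' univariate repeated-measures ANOVA (rat as subject, between-subject
#' factor strain, within-subject factor session as a categorical
#' level), giving p-values for strain, session and their interaction.
#' A linear-in-session slope per strain (and pooled) is fit on the
#' log-transformed values, rat by rat, for sign reporting.
#'
#' @inheritParams glm_log_pd
#' @return A `trend_fit` object; [tidy()] returns the per-strain
#'   slopes, [glance()] the effect p-values.
#' @export
among_sessions_model <- function(pd_tbl, trait, log_offset = 1) {
  df <- pd_tbl |>
    dplyr::filter(.data$trait == !!trait) |>
    dplyr::transmute(.data$rat_id, .data$strain,
                     within = .data$session, index = .data$session,
                     y = log(.data$pd + log_offset))
  if (nrow(df) == 0) abort(sprintf("No rows for trait \"%s\".", trait))
  new_trend_fit(
    trait, "among_sessions",
    effects = rm_anova(df, "session"),
    slopes = per_strain_slopes(df),
    slope_scale = "log", log_offset = log_offset
  )
}

#' Dispersion trend within sessions (segment-to-segment)
#'
#' Tests whether dispersion changes across segments within the session.
#' Input is the segment-resolved deviation table
#' ([segment_deviation_table()]): one mean absolute deviation per rat
#' per segment, averaged over sessions. The repeated-measures ANOVA
#' (rat as subject, between factor strain, within factor segment) is
#' run on log-transformed deviations; the per-strain linear slopes on
#' segment index 1..K are fit on the raw deviations by default, where
#' a unit of slope is counts per segment (`slope_scale = "log"`
#' switches to the transformed scale).
#'
#' @param segdev_tbl Segment-deviation table from
#'   [segment_deviation_table()].
#' @param trait Trait to analyze.
#' @param log_offset Offset for the ANOVA's log transform (default 1).
#' @param slope_scale Scale of the reported linear slopes: `"raw"`
#'   (default) or `"log"`.
#' @return A `trend_fit` object.
#' @export
within_sessions_model <- function(segdev_tbl, trait, log_offset = 1,
                                  slope_scale = c("raw", "log")) {
  slope_scale <- match.arg(slope_scale)
  base <- segdev_tbl |>
    dplyr::filter(.data$trait == !!trait) |>
    dplyr::transmute(.data$rat_id, .data$strain,
                     within = .data$segment, index = .data$segment,
                     raw = .data$mean_abs_dev,
                     y = log(.data$mean_abs_dev + log_offset))
  if (nrow(base) == 0) abort(sprintf("No rows for trait \"%s\".", trait))
  slope_df <- base
  if (slope_scale == "raw") slope_df$y <- slope_df$raw
  new_trend_fit(
    trait, "within_sessions",
    effects = rm_anova(base, "segment"),
    slopes = per_strain_slopes(slope_df),
    slope_scale = slope_scale, log_offset = log_offset
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s, %s (slopes on %s scale)\n",
              x$trait, gsub("_", " ", x$scope), x$slope_scale))
  cat("Effects:\n"); print(x$effects, ...)
  cat("Slopes:\n"); print(x$slopes, ...)
  invisible(x)
}

#' @rdname within_sessions_model
#' @param x A `trend_fit` object.
#' @param ... Unused.
#' @export
tidy.trend_fit <- function(x, ...) {
  dplyr::mutate(x$slopes, trait = x$trait, scope = x$scope,
                slope_scale = x$slope_scale, .before = 1)
}

#' @rdname within_sessions_model
#' @export
glance.trend_fit <- function(x, ...) {
  x$effects |>
    dplyr::select("term", "p") |>
    tidyr::pivot_wider(names_from = "term", values_from = "p",
                       names_prefix = "p_") |>
    dplyr::mutate(trait = x$trait, scope = x$scope, .before = 1)
}
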