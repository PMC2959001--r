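#' Kruskal-Wallis rank comparison
#'
#' Thin, contract-enforcing wrapper around [stats::kruskal.test()]:
#' midranks across the pooled sample, tie-corrected H statistic,
#' p-value from the chi-squared distribution with `groups - 1` degrees
#' of freedom. The fully tied input (all values identical), where the
#' tie-correction denominator vanishes, is defined as `H = 0, p = 1`
#' (no rank separation).
#'
#' @param values Numeric vector of observations.
#' @param groups Vector of group labels, same length as `values`.
#' @return A one-row tibble with columns `H`, `df`, `p`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have the same length.")
  }
  g <- factor(groups)
  if (nlevels(g) < 2) abort("Need at least two groups.")
  if (any(tabulate(g, nbins = nlevels(g)) == 0)) {
    abort("Every group must be nonempty.")
  }
  if (!all(is.finite(values))) abort("`values` must be finite.")
  if (length(unique(values)) == 1) {
    return(tibble::tibble(H = 0, df = nlevels(g) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, g)
  tibble::tibble(
    H = unname(kt$statistic),
    df = as.integer(kt$parameter),
    p = unname(kt$p.value)
  )
}

# Per-rat averages of log-transformed dispersion for one trait.
per_rat_log_pd <- function(pd_tbl, trait, log_offset) {
  if (!trait %in% unique(as.character(pd_tbl$trait))) {
    abort(sprintf("Trait \"%s\" not present in the dispersion table.", trait))
  }
  pd_tbl |>
    dplyr::filter(.data$trait == !!trait) |>
    dplyr::summarise(y = mean(log(.data$pd + log_offset)),
                     .by = c("rat_id", "strain"))
}

check_two_strains <- function(tbl) {
  s <- unique(tbl$strain)
  if (length(s) != 2) {
    abort(sprintf("Exactly two strains required; found %d (%s).",
                  length(s), paste(s, collapse = ", ")))
  }
  s
}

#' Linear model on log-transformed dispersion
#'
#' Group comparison of dispersion on the log scale: each rat's
#' per-session dispersion values are transformed as
#' `log(pd + log_offset)` and averaged over sessions (one value per
#' rat), then a one-way fixed-effect linear model `y ~ strain` is fit
#' on the per-rat averages. Returns the strain F test with
#' `(1, N - 2)` degrees of freedom and the fitted strain means of `y`
#' with t-based 95% confidence half-widths (pooled residual SD), on
#' both the log and back-transformed scales.
#'
#' @param pd_tbl Dispersion table from [dispersion_table()].
#' @param trait One of `"hyperactivity"`, `"impulsiveness"`,
#'   `"inattention"`.
#' @param log_offset Offset added before the log transform (default 1;
#'   dispersion can be exactly 0 for constant sessions).
#' @return A list with `F`, `df1`, `df2`, `p` and `means`, a tibble
#'   with one row per strain (`strain`, `n`, `mean_log`,
#'   `ci95_halfwidth`, `mean_backtransformed`).
#' @export
glm_log_pd <- function(pd_tbl, trait, log_offset = 1) {
  per_rat <- per_rat_log_pd(pd_tbl, trait, log_offset)
  check_two_strains(per_rat)
  n_by <- dplyr::count(per_rat, .data$strain)
  if (any(n_by$n < 2)) {
    abort("Each strain needs at least 2 rats (no residual degrees of freedom otherwise).")
  }
  fit <- lm(y ~ strain, data = per_rat)
  an <- anova(fit)
  df2 <- an$Df[2]
  sigma <- sqrt(an$`Mean Sq`[2])
  means <- per_rat |>
    dplyr::summarise(n = dplyr::n(), mean_log = mean(.data$y),
                     .by = "strain") |>
    dplyr::mutate(
      ci95_halfwidth = qt(0.975, df2) * sigma / sqrt(.data$n),
      mean_backtransformed = exp(.data$mean_log) - log_offset
    ) |>
    dplyr::arrange(.data$strain)
  list(
    F = an$`F value`[1], df1 = an$Df[1], df2 = df2,
    p = an$`Pr(>F)`[1], means = means
  )
}

#' Proportion of dispersion variance explained by strain
#'
#' Eta-squared from the one-way decomposition on per-rat averages of
#' log-transformed dispersion: between-strain sum of squares divided by
#' the total sum of squares. Zero total variance is defined as 0, with
#' a warning.
#'
#' @inheritParams glm_log_pd
#' @return A single number in `[0, 1]`.
#' @export
variance_proportion <- function(pd_tbl, trait, log_offset = 1) {
  per_rat <- per_rat_log_pd(pd_tbl, trait, log_offset)
  check_two_strains(per_rat)
  ss_total <- sum((per_rat$y - mean(per_rat$y))^2)
  if (ss_total == 0) {
    warn("Zero total variance; variance proportion defined as 0.")
    return(0)
  }
  fit <- lm(y ~ strain, data = per_rat)
  ss_between <- sum((stats::fitted(fit) - mean(per_rat$y))^2)
  ss_between / ss_total
}

#' Strain comparison of phenotypic dispersion
#'
#' The full between-strain comparison for one or more traits:
#' Kruskal-Wallis ranking of dispersion (by default on per-rat
#' session-averaged values, one value per rat, to avoid
#' pseudo-replication), the linear model on log-transformed dispersion
#' with strain means and 95% CIs ([glm_log_pd()]), and the variance
#' proportion explained by strain ([variance_proportion()]).
#'
#' @param pd_tbl Dispersion table from [dispersion_table()] with
#'   exactly two strains.
#' @param traits Character vector of traits to compare (default all
#'   three).
#' @param log_offset Offset for the log transform (default 1).
#' @param kw_unit Observational unit for the rank test: `"rat"`
#'   (session-averaged, default) or `"rat_session"` (one value per
#'   rat-session).
#' @return An object of class `strain_comparison`. Use [tidy()] for
#'   the per-trait statistics table (one row per trait, mirroring a
#'   chi-squared / F / means-with-CI report), [glance()] for the
#'   settings, and [autoplot()] for a means-with-CI figure.
#' @examples
#' ev <- simulate_experiment(
#'   simulation_design(n_rats = c(SHR = 5, WKY = 5), n_sessions = 2),
#'   seed = 7
#' )
#' pd <- dispersion_table(extract_traits(ev))
#' tidy(compare_strains(pd))
#' @export
compare_strains <- function(pd_tbl, traits = TRAITS, log_offset = 1,
                            kw_unit = c("rat", "rat_session")) {
  kw_unit <- match.arg(kw_unit)
  strains <- check_two_strains(pd_tbl)
  rows <- purrr::map(traits, function(tr) {
    kw_data <- if (kw_unit == "rat") {
      pd_tbl |>
        dplyr::filter(.data$trait == !!tr) |>
        dplyr::summarise(value = mean(.data$pd), .by = c("rat_id", "strain"))
    } else {
      pd_tbl |>
        dplyr::filter(.data$trait == !!tr) |>
        dplyr::transmute(.data$rat_id, .data$strain, value = .data$pd)
    }
    kw <- kruskal_wallis(kw_data$value, kw_data$strain)
    gl <- glm_log_pd(pd_tbl, tr, log_offset)
    tibble::tibble(
      trait = tr,
      kw_H = kw$H, kw_df = kw$df, kw_p = kw$p,
      glm_F = gl$F, glm_df1 = gl$df1, glm_df2 = gl$df2, glm_p = gl$p,
      eta2 = variance_proportion(pd_tbl, tr, log_offset),
      means = list(gl$means)
    )
  })
  structure(
    list(
      table = dplyr::bind_rows(rows),
      strains = sort(strains),
      settings = list(log_offset = log_offset, kw_unit = kw_unit)
    ),
    class = "strain_comparison"
  )
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf(
    "<strain_comparison> %s vs %s (log offset %g, Kruskal-Wallis unit: %s)\n",
    x$strains[1], x$strains[2], x$settings$log_offset, x$settings$kw_unit
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname compare_strains
#' @param x A `strain_comparison` object.
#' @param ... Unused.
#' @export
tidy.strain_comparison <- function(x, ...) {
  wide_means <- x$table |>
    dplyr::select("trait", "means") |>
    tidyr::unnest("means") |>
    tidyr::pivot_wider(
      id_cols = "trait", names_from = "strain",
      values_from = c("mean_log", "ci95_halfwidth", "mean_backtransformed"),
      names_glue = "{.value}_{strain}"
    )
  x$table |>
    dplyr::select(-"means") |>
    dplyr::left_join(wide_means, by = "trait")
}

#' @rdname compare_strains
#' @export
glance.strain_comparison <- function(x, ...) {
  tibble::tibble(
    strain_a = x$strains[1], strain_b = x$strains[2],
    n_traits = nrow(x$table),
    log_offset = x$settings$log_offset,
    kw_unit = x$settings$kw_unit
  )
}
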