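test_that("Kruskal-Wallis H matches the closed-form rank computation", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12) # 3.857 to 3 d.p.
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(kw$p, pchisq(27 / 7, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(kw$df, 1L)
})

test_that("Kruskal-Wallis is rank-based: invariant under monotone transforms", {
  withr::with_seed(23, {
    for (i in 1:20) {
      x <- rnorm(25)
      g <- rep(c("a", "b"), c(13, 12))
      h0 <- kruskal_wallis(x, g)$H
      expect_equal(kruskal_wallis(exp(x), g)$H, h0, tolerance = 1e-10)
      expect_equal(kruskal_wallis(x^3, g)$H, h0, tolerance = 1e-10)
      expect_equal(kruskal_wallis(rank(x), g)$H, h0, tolerance = 1e-10)
    }
  })
})

test_that("two-group tie-free H equals the squared rank-sum z statistic", {
  withr::with_seed(31, {
    for (i in 1:25) {
      x1 <- rnorm(16); x2 <- rnorm(15)
      h <- kruskal_wallis(c(x1, x2), rep(c("a", "b"), c(16, 15)))$H
      expect_equal(h, ranksum_z_oracle(x1, x2)^2, tolerance = 1e-10)
    }
  })
})

test_that("degenerate Kruskal-Wallis inputs follow the contract", {
  expect_equal(kruskal_wallis(rep(2, 10), rep(c("a", "b"), 5)),
               tibble::tibble(H = 0, df = 1L, p = 1))
  expect_error(kruskal_wallis(1:3, c("a", "a", "a")), "two groups")
  expect_error(kruskal_wallis(1:3, 1:2), "same length")
})

test_that("log-dispersion linear model reduces to the pooled t test", {
  withr::with_seed(47, {
    y <- matrix(exp(rnorm(31 * 5, 3, 0.5)), nrow = 31)
  })
  pd <- make_pd_tbl(y, strain = rep(c("SHR", "WKY"), c(16, 15)))
  gl <- glm_log_pd(pd, "hyperactivity")
  per_rat <- rowMeans(log(y + 1))
  tt <- stats::t.test(per_rat[1:16], per_rat[17:31], var.equal = TRUE)
  expect_equal(gl$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(gl$p, tt$p.value, tolerance = 1e-10)
  expect_equal(gl$df2, 29)
  # group means of the transformed scale, with t-based CIs
  expect_equal(gl$means$mean_log,
               c(mean(per_rat[1:16]), mean(per_rat[17:31])), tolerance = 1e-12)
  s_pooled <- sqrt(((16 - 1) * stats::var(per_rat[1:16]) +
                      (15 - 1) * stats::var(per_rat[17:31])) / 29)
  expect_equal(gl$means$ci95_halfwidth,
               qt(0.975, 29) * s_pooled / sqrt(c(16, 15)), tolerance = 1e-10)
})

test_that("identical groups give F = 0 and equal means", {
  y <- matrix(rep(c(1, 2, 3), 2), nrow = 6, ncol = 1)
  pd <- make_pd_tbl(y, strain = rep(c("A", "B"), each = 3))
  gl <- glm_log_pd(pd, "hyperactivity")
  expect_equal(gl$F, 0)
  expect_equal(gl$means$mean_log[1], gl$means$mean_log[2])
  expect_error(glm_log_pd(make_pd_tbl(y[1:4, , drop = FALSE],
                                      strain = c("A", "A", "A", "B")),
                          "hyperactivity"),
               "at least 2 rats")
})

test_that("a known log-scale strain shift is recovered without bias", {
  withr::with_seed(61, {
    diffs <- replicate(200, {
      mu <- c(rep(1.5, 16), rep(1.0, 15)) # delta = 0.5 on the log scale
      y <- matrix(exp(rnorm(31 * 3, mu, 0.4)) - 1, nrow = 31)
      pd <- make_pd_tbl(pmax(y, 0), strain = rep(c("SHR", "WKY"), c(16, 15)))
      gl <- glm_log_pd(pd, "hyperactivity", log_offset = 1)
      gl$means$mean_log[gl$means$strain == "SHR"] -
        gl$means$mean_log[gl$means$strain == "WKY"]
    })
  })
  expect_equal(mean(diffs), 0.5, tolerance = 0.1)
})

test_that("variance proportion matches explicit sums of squares", {
  withr::with_seed(71, {
    for (i in 1:20) {
      y <- matrix(exp(rnorm(20 * 4, 2, 0.6)), nrow = 20)
      strain <- rep(c("A", "B"), each = 10)
      pd <- make_pd_tbl(y, strain)
      per_rat <- rowMeans(log(y + 1))
      expect_equal(variance_proportion(pd, "hyperactivity"),
                   eta2_oracle(per_rat, strain), tolerance = 1e-10)
    }
  })
  # all variance between groups -> 1
  y1 <- matrix(c(rep(2, 5), rep(5, 5)), ncol = 1)
  expect_equal(variance_proportion(
    make_pd_tbl(y1, rep(c("A", "B"), each = 5)), "hyperactivity"), 1)
  # no variance at all -> 0, with a warning
  y0 <- matrix(3, nrow = 6, ncol = 2)
  expect_warning(
    v <- variance_proportion(make_pd_tbl(y0, rep(c("A", "B"), 3)),
                             "hyperactivity"),
    "Zero total variance"
  )
  expect_equal(v, 0)
})

test_that("strain comparison assembles all statistics and is order-invariant", {
  withr::with_seed(83, {
    arr <- array(rpois(10 * 3 * 5, 25), dim = c(10, 3, 5))
  })
  tr <- make_trait_tbl(arr, strain = rep(c("SHR", "WKY"), each = 5))
  pd <- dispersion_table(tr)
  sc <- compare_strains(pd)
  td <- tidy(sc)
  expect_equal(nrow(td), 3)
  expect_true(all(td$kw_p >= 0 & td$kw_p <= 1))
  expect_true(all(td$eta2 >= 0 & td$eta2 <= 1))
  expect_true(all(td$kw_df == 1))

  # shuffling input rows and relabeling rats changes nothing
  withr::with_seed(84, pd_shuffled <- pd[sample(nrow(pd)), ])
  expect_equal(tidy(compare_strains(pd_shuffled)), td)
  pd_relab <- dplyr::mutate(pd, rat_id = paste0("x", rat_id))
  expect_equal(tidy(compare_strains(pd_relab)), td)

  # rat-session unit is exposed as an alternative
  sc2 <- compare_strains(pd, kw_unit = "rat_session")
  expect_equal(glance(sc2)$kw_unit, "rat_session")
  expect_error(compare_strains(dplyr::filter(pd, strain == "SHR")),
               "Exactly two strains")
})
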