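test_that("connectivity descriptives follow their definitions", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- 1:6
  d <- connectivity_descriptives(connectivity_matrix(w + t(w)))
  expect_equal(d$median, 3.5)
  expect_equal(d$mean, 3.5)
  expect_equal(d$mad, 1.5)   # median{2.5,1.5,0.5,0.5,1.5,2.5}
  expect_equal(d$sd, sd(1:6))
  # constant matrix: zero spread
  dc <- connectivity_descriptives(connectivity_matrix(matrix(2, 3, 3) - diag(2, 3)))
  expect_equal(c(dc$median, dc$mean, dc$mad, dc$sd), c(2, 2, 0, 0))
  # node relabelling leaves all four unchanged
  perm <- c(3, 1, 4, 2)
  wp <- (w + t(w))[perm, perm]
  dp <- connectivity_descriptives(connectivity_matrix(wp))
  expect_equal(dp[, 3:6], d[, 3:6])
})

test_that("density regression equals the normal-equations oracle", {
  x <- seq(0.1, 0.9, length.out = 40)
  df <- data.frame(density = x, m = 2 - x)
  fit <- suppressWarnings(fit_density_regression(df, "m"))  # perfect fit
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$slope, -1, tolerance = 1e-12)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-12)
  withr::with_seed(15, {
    df2 <- data.frame(density = runif(200), m = rnorm(200, 1, 0.3))
    df2$m <- df2$m + 0.4 * df2$density
    fit2 <- fit_density_regression(df2, "m")
    beta <- oracle_ols(df2$density, df2$m)
    expect_equal(c(fit2$intercept, fit2$slope), unname(beta),
                 tolerance = 1e-10)
    # independent response: adjusted R^2 hovers at 0 over replicates
    r2 <- replicate(100, {
      d <- data.frame(density = runif(500), m = rnorm(500))
      fit_density_regression(d, "m")$adj_r_squared
    })
    expect_lt(abs(mean(r2)), 0.02)
  })
  expect_error(fit_density_regression(data.frame(density = rep(0.5, 5),
                                                 m = rnorm(5)), "m"),
               "zero variance")
})

test_that("cross-threshold Spearman structure matches a midrank oracle", {
  subj <- sprintf("S%02d", 1:8)
  withr::with_seed(16, {
    v1 <- rnorm(8)
    df <- rbind(
      data.frame(subject = subj, q = 0.1, m = v1),
      data.frame(subject = subj, q = 0.2, m = v1),            # identical
      data.frame(subject = subj, q = 0.3, m = -v1),           # reversed
      data.frame(subject = subj, q = 0.4, m = round(rnorm(8), 0)),  # ties
      data.frame(subject = subj, q = 0.5, m = rep(1, 8))      # constant
    )
  })
  names(df)[3] <- "clustering"
  cc <- cross_threshold_correlations(df, "clustering")
  expect_equal(cc$rho["0.1", "0.2"], 1)
  expect_equal(cc$rho["0.1", "0.3"], -1)
  expect_equal(cc$rho["0.1", "0.4"],
               oracle_spearman(v1, df$clustering[df$q == 0.4]),
               tolerance = 1e-12)
  expect_true(is.na(cc$rho["0.1", "0.5"]))   # constant vector: undefined
  expect_identical(cc$rho, t(cc$rho))
})

test_that("permutation t-test agrees with exhaustive enumeration at 4 + 4", {
  withr::with_seed(17, { a <- rnorm(4); b <- rnorm(4, 1) })
  exact <- permutation_ttest(a, b)           # 70 splits -> enumerated
  expect_true(exact$exact)
  expect_equal(exact$p_value, oracle_perm_p(a, b), tolerance = 1e-12)
  mc <- permutation_ttest(a, b, n_permutations = 10000, seed = 4,
                          exact_max = 1)     # force Monte-Carlo
  expect_false(mc$exact)
  expect_lt(abs(mc$p_value - exact$p_value), 0.02)
  # identical samples: d = 0, p = 1
  same <- permutation_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$cohens_d, 0)
  expect_equal(same$p_value, 1)
  # shifted copy with unit SD: pooled-SD d near 1
  withr::with_seed(18, z <- rnorm(60, sd = 1))
  shift <- permutation_ttest(z + 1, z)
  expect_equal(shift$cohens_d, 1 / sd(z), tolerance = 1e-12)
  # label swap negates both t and d
  swap <- permutation_ttest(b, a)
  expect_equal(swap$t_stat, -exact$t_stat)
  expect_equal(swap$cohens_d, -exact$cohens_d)
})

test_that("paired sign-flip test is exact for small n and detects shifts", {
  withr::with_seed(19, a <- rnorm(10))
  same <- permutation_ttest(a, a, paired = TRUE)
  expect_equal(same$p_value, 1)
  expect_equal(same$cohens_d, 0)
  shifted <- permutation_ttest(a + 2, a, paired = TRUE)
  expect_true(shifted$exact)    # 2^10 flips enumerated
  expect_lt(shifted$p_value, 0.01)
  expect_error(permutation_ttest(a, a[1:5], paired = TRUE), "equal length")
})

test_that("group effect profiles flag significant runs and d sign changes", {
  # construct a sweep table with a planted contiguous effect at q >= 0.5
  qs <- seq(0.1, 0.9, 0.1)
  subj <- sprintf("S%02d", 1:16)
  grp <- rep(c("A", "B"), each = 8)
  withr::with_seed(20, {
    rows <- do.call(rbind, lapply(qs, function(q) {
      mu <- ifelse(grp == "B" & q >= 0.5, 2, 0)
      data.frame(subject = subj, group = grp, measure = "wpli", q = q,
                 clustering = rnorm(16, mu, 0.5))
    }))
  })
  prof <- group_effect_profile(rows, "clustering", measure = "wpli",
                               alpha = 0.01, n_permutations = 999, seed = 2)
  expect_identical(nrow(prof), length(qs))
  expect_true(all(prof$significant[prof$q >= 0.5]))
  runs <- attr(prof, "significant_runs")
  expect_gte(max(runs$length), 5)
  expect_false(attr(prof, "d_sign_change"))
  # antisymmetry under label swap
  rows2 <- rows; rows2$group <- ifelse(rows2$group == "A", "B", "A")
  prof2 <- group_effect_profile(rows2, "clustering", measure = "wpli",
                                alpha = 0.01, n_permutations = 999, seed = 2)
  expect_equal(prof2$cohens_d, -prof$cohens_d)
  # opposite-sign effects in two runs are flagged
  rows3 <- rows
  rows3$clustering <- rows3$clustering +
    ifelse(rows3$group == "B" & rows3$q <= 0.2, -4, 0)
  prof3 <- group_effect_profile(rows3, "clustering", measure = "wpli",
                                alpha = 0.01, n_permutations = 999, seed = 2)
  expect_true(attr(prof3, "d_sign_change"))
})

test_that("OMST vs matched-density comparison is paired and schema-complete", {
  subj <- sprintf("S%02d", 1:12)
  withr::with_seed(21, base <- rnorm(12, 2, 1))
  om <- data.frame(subject = subj, measure = "wpli",
                   cpl = base, clustering = base + 1)
  th <- data.frame(subject = subj, measure = "wpli",
                   cpl = base, clustering = base)
  out <- compare_omst_vs_matched(om, th, metrics = c("cpl", "clustering"),
                                 seed = 5)
  expect_identical(nrow(out), 2L)   # measures x metrics
  expect_equal(out$cohens_d[out$metric == "cpl"], 0)
  expect_equal(out$p_value[out$metric == "cpl"], 1)
  d_cl <- out$cohens_d[out$metric == "clustering"]
  expect_equal(d_cl, 1 / sd(base), tolerance = 1e-12)
  expect_lt(out$p_value[out$metric == "clustering"], 0.01)
  expect_error(compare_omst_vs_matched(om[-1, ], th), "unmatched")
})

test_that("permutation p-values are valid under exchangeability", {
  withr::with_seed(22, {
    ps <- replicate(300, {
      a <- rnorm(6); b <- rnorm(6)
      permutation_ttest(a, b)$p_value     # exact (924 splits)
    })
  })
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 300))
  }
})
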