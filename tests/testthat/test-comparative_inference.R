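test_that("pooled two-sample t matches the hand computation", {
  values <- c(1, 2, 3, 2, 3, 4)
  status <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- status_t_test(values, status, variant = "pooled_two_sample")
  # pooled s^2 = 1, se = sqrt(2/3), t = -1/se
  expect_equal(res$statistic_t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$mean_difference, -1)
})

test_that("identical groups give t = 0 without dividing by zero", {
  res <- status_t_test(c(5, 5, 5, 5), c(TRUE, TRUE, FALSE, FALSE),
                       variant = "pooled_two_sample")
  expect_equal(res$statistic_t, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_difference, 0)
})

test_that("paired variant reproduces stats::t.test on paired data", {
  set.seed(17)
  n <- 25
  non <- rnorm(n, 10, 2)
  inv <- non + 1.4 + rnorm(n, 0, 1.5)
  res <- status_t_test(c(non, inv), rep(c(FALSE, TRUE), each = n),
                       pairing = rep(seq_len(n), 2),
                       variant = "paired_differences")
  ref <- t.test(inv, non, paired = TRUE)
  expect_equal(res$statistic_t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$df, n - 1)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(res$mean_difference, unname(ref$estimate), tolerance = 1e-10)
})

test_that("hierarchy-free mixed model equals the pooled two-sample t", {
  g <- generate_pair_dataset(simulation_config(seed = 31, n_pairs = 40L))
  long <- pairs_to_long(g$pairs, "ldt")
  fit <- nested_taxonomy_lmm(g$species, "ldt", hierarchy = "none")
  tt <- status_t_test(long$value, long$status == "invasive",
                      variant = "pooled_two_sample")
  expect_equal(fit$statistic_t, tt$statistic_t, tolerance = 1e-6)
  expect_equal(fit$fixed_effect_status, tt$mean_difference, tolerance = 1e-6)
  expect_equal(fit$satterthwaite_df, tt$df)
})

test_that("paired mixed model recovers variance components (ANOVA oracle)", {
  set.seed(99)
  J <- 200
  pair_eff <- rnorm(J, 0, sqrt(3))
  non <- 10 + pair_eff + rnorm(J, 0, 1)
  inv <- 10 + 1.4 + pair_eff + rnorm(J, 0, 1)
  pairs <- data.frame(pair_id = sprintf("p%03d", seq_len(J)),
                      ldt_noninv = non, ldt_inv = inv,
                      set_noninv = NA_real_, set_inv = NA_real_)
  fit <- paired_lmm(pairs, "ldt")
  mom <- anova_mom_components(pairs_to_long(pairs, "ldt"))
  expect_lt(abs(fit$var_between - mom["var_pair"]) / mom["var_pair"], 0.15)
  expect_lt(abs(fit$var_residual - mom["var_res"]) / mom["var_res"], 0.15)
  expect_equal(fit$icc,
               fit$var_between / (fit$var_between + fit$var_residual))
  expect_lt(abs(fit$fixed_effect_status - 1.4), 2 * fit$se_fixed)
})

test_that("zero between-pair variance is a valid boundary fit with icc 0", {
  set.seed(12)
  J <- 60
  pairs <- data.frame(pair_id = sprintf("p%02d", seq_len(J)),
                      ldt_noninv = rnorm(J, 10, 1),
                      ldt_inv = rnorm(J, 10.5, 1),
                      set_noninv = NA_real_, set_inv = NA_real_)
  fit <- paired_lmm(pairs, "ldt")
  expect_true(fit$boundary)
  expect_equal(fit$icc, 0, tolerance = 1e-6)
  expect_lt(abs(fit$fixed_effect_status - 0.5), 2 * fit$se_fixed)
})

test_that("paired mixed model converges to the pooled t as pair variance vanishes", {
  # pair means are all equal, so the pair variance component estimates to 0
  J <- 30
  non <- rep(c(9, 11), length.out = J)
  inv <- 21 - non
  pairs <- data.frame(pair_id = sprintf("p%02d", seq_len(J)),
                      ldt_noninv = non, ldt_inv = inv,
                      set_noninv = NA_real_, set_inv = NA_real_)
  fit <- paired_lmm(pairs, "ldt")
  long <- pairs_to_long(pairs, "ldt")
  tt <- status_t_test(long$value, long$status == "invasive",
                      variant = "pooled_two_sample")
  expect_equal(fit$statistic_t, tt$statistic_t, tolerance = 1e-6)
})

test_that("paired-model ICC recovers generating values across the range", {
  for (icc in c(0.1, 0.2, 0.5)) {
    est <- vapply(1:20, function(i) {
      g <- generate_pair_dataset(simulation_config(
        seed = 40000 + 100 * icc * 10 + i, n_pairs = 500L,
        target_icc_ldt = icc,
        between_split = c(order = 0, family = 0, pair = 1)))
      paired_lmm(g$pairs, "ldt")$icc
    }, numeric(1))
    expect_lt(abs(mean(est) - icc), 0.05)
  }
})

test_that("REML log-likelihood of the fixed-effects model matches lme4 at the boundary", {
  # equal pair means force the pair variance to its zero boundary
  non <- rep(c(9, 11), 10)
  d <- data.frame(value = c(rbind(non, 21 - non)),
                  status = factor(rep(c("noninvasive", "invasive"), 20),
                                  levels = c("noninvasive", "invasive")),
                  pair_id = rep(sprintf("p%02d", 1:20), each = 2))
  fit_mm <- suppressMessages(
    lmerTest::lmer(value ~ status + (1 | pair_id), data = d, REML = TRUE))
  expect_true(lme4::isSingular(fit_mm))
  fit_lm <- lm(value ~ status, data = d)
  expect_equal(thermopair:::reml_loglik_lm(fit_lm),
               as.numeric(logLik(fit_mm)), tolerance = 1e-6)
})

test_that("likelihood-ratio sequence is non-negative and label-invariant", {
  g <- generate_pair_dataset(simulation_config(seed = 55, n_pairs = 60L))
  lr <- lr_test_sequence(g$species, "ldt")
  expect_gte(lr$order_vs_none$statistic_L, 0)
  expect_gte(lr$family_vs_order$statistic_L, 0)
  expect_true(all(c(lr$order_vs_none$p_value,
                    lr$family_vs_order$p_value) >= 0))

  relabeled <- g$species
  relabeled$order <- paste0("X_", relabeled$order)
  relabeled$family <- paste0("Y_", relabeled$family)
  lr2 <- lr_test_sequence(relabeled, "ldt")
  expect_equal(lr$order_vs_none$statistic_L, lr2$order_vs_none$statistic_L,
               tolerance = 1e-8)
  expect_equal(lr$family_vs_order$statistic_L,
               lr2$family_vs_order$statistic_L, tolerance = 1e-8)
})

test_that("LR statistics stay below 3.84 for most null replicates", {
  hits <- vapply(1:100, function(i) {
    g <- generate_pair_dataset(simulation_config(
      seed = 60000 + i, n_pairs = 30L,
      between_split = c(order = 0, family = 0, pair = 1)))
    lr <- lr_test_sequence(g$species, "ldt")
    c(lr$order_vs_none$statistic_L, lr$family_vs_order$statistic_L)
  }, numeric(2))
  # boundary null: the chi-square(1) test is conservative
  expect_gte(mean(hits[1, ] <= 3.84), 0.9)
  expect_gte(mean(hits[2, ] <= 3.84), 0.9)
})

test_that("injected family variance shows up in the family component", {
  g <- generate_pair_dataset(simulation_config(
    seed = 77, n_pairs = 80L,
    sd_between_ldt = 3,
    between_split = c(order = 0.05, family = 0.9, pair = 0.05)))
  fit_fam <- nested_taxonomy_lmm(g$species, "ldt", "family_in_order")
  expect_gt(fit_fam$var_between, 0)

  # permuting family labels destroys the component
  perm <- g$species
  set.seed(1)
  perm$family <- sample(perm$family)
  fit_perm <- nested_taxonomy_lmm(perm, "ldt", "family_in_order")
  expect_gt(fit_fam$var_components[["order_taxon:family_taxon"]],
            fit_perm$var_components[["order_taxon:family_taxon"]])
})

test_that("single-group hierarchies fall back with a warning", {
  g <- generate_pair_dataset(simulation_config(seed = 5, n_pairs = 10L,
                                               n_orders = 1L,
                                               families_per_order = 1L))
  expect_warning(fit <- nested_taxonomy_lmm(g$species, "ldt", "order"),
                 "falling back")
  expect_equal(fit$grouping, "none")
})

test_that("difference correlation matches hand and textbook computations", {
  d <- data.frame(d_ldt = c(1, 2, 3), d_set = c(-1, -3, -2))
  res <- difference_correlation(d)
  expect_equal(res$r, -0.5, tolerance = 1e-12)

  # perfect anti-correlation
  d2 <- data.frame(d_ldt = c(1, 2, 3, 4), d_set = -2.5 * c(1, 2, 3, 4))
  res2 <- difference_correlation(d2)
  expect_equal(res2$r, -1, tolerance = 1e-12)
  expect_equal(res2$concordance_fraction, 1)

  set.seed(123)
  for (i in 1:10) {
    x <- rnorm(50); y <- rnorm(50)
    r <- difference_correlation(data.frame(d_ldt = x, d_set = y))$r
    expect_equal(r, pearson_textbook(x, y), tolerance = 1e-12)
  }

  expect_error(difference_correlation(
    data.frame(d_ldt = c(1, 1, 1), d_set = c(1, 2, 3))), "zero variance")
  expect_error(difference_correlation(
    data.frame(d_ldt = c(1, 2), d_set = c(1, 2))), "at least 3")
})

test_that("zero differences count as non-concordant", {
  d <- data.frame(d_ldt = c(1, 0, 2, -1), d_set = c(-1, -2, 3, 2))
  res <- difference_correlation(d)
  expect_equal(res$concordance_fraction, 0.5)  # pairs 1 and 4 only
})

test_that("normality diagnostics report correct skewness and kurtosis", {
  sym <- normality_diagnostics(c(1, 2, 3, 4))
  expect_equal(sym$skewness, 0, tolerance = 1e-12)

  x <- c(0, 0, 0, 10)
  rep_ <- normality_diagnostics(x)
  m2 <- mean((x - mean(x))^2)
  expect_equal(rep_$skewness, mean((x - mean(x))^3) / m2^1.5)
  expect_gt(rep_$skewness, 0)
  ref <- shapiro.test(x)
  expect_equal(rep_$shapiro_w, unname(ref$statistic))
  expect_error(normality_diagnostics(rep(2, 10)), "constant")
})

test_that("Shapiro-Wilk holds its level on normal samples", {
  p <- vapply(1:100, function(i) {
    set.seed(7000 + i)
    normality_diagnostics(rnorm(100))$shapiro_p
  }, numeric(1))
  expect_gte(mean(p > 0.05), 0.9)
})

test_that("residual diagnostics: zero noise, centered residuals, shrunk BLUPs", {
  # noise-free: value determined by status + pair effect
  J <- 20
  pair_eff <- seq(-2, 2, length.out = J)
  pairs <- data.frame(pair_id = sprintf("p%02d", seq_len(J)),
                      ldt_noninv = 10 + pair_eff,
                      ldt_inv = 11.4 + pair_eff,
                      set_noninv = NA_real_, set_inv = NA_real_)
  # a noise-free layout is numerically degenerate for the optimizer;
  # convergence gripes are expected and the residuals are still exact
  fit0 <- suppressWarnings(paired_lmm(pairs, "ldt"))
  diag0 <- residual_diagnostics(fit0)
  expect_lt(max(abs(diag0$observations$residual)), 1e-6)

  g <- generate_pair_dataset(simulation_config(seed = 66, n_pairs = 50L))
  fit <- paired_lmm(g$pairs, "ldt")
  diag <- residual_diagnostics(fit)
  expect_lt(abs(mean(diag$observations$residual)), 1e-8 * 10)

  # BLUPs shrink toward zero relative to raw pair-mean deviations
  long <- pairs_to_long(g$pairs, "ldt")
  resp <- long$value - ave(long$value, long$status)
  raw_dev <- tapply(resp, long$pair_id, mean) - mean(resp)
  blup <- diag$random_effects$blup[
    match(names(raw_dev), diag$random_effects$level)]
  expect_true(all(abs(blup) <= abs(raw_dev) + 1e-8))
})

test_that("maximum-likelihood switch keeps the sequence internally consistent", {
  g <- generate_pair_dataset(simulation_config(seed = 21, n_pairs = 40L))
  fit_ml <- nested_taxonomy_lmm(g$species, "ldt", "none", reml = FALSE)
  ref <- lm(value ~ status, data = thermopair:::species_long(g$species, "ldt"))
  expect_equal(fit_ml$log_likelihood, as.numeric(logLik(ref)),
               tolerance = 1e-8)
  lr_ml <- lr_test_sequence(g$species, "ldt", reml = FALSE)
  expect_gte(lr_ml$order_vs_none$statistic_L, 0)
  expect_gte(lr_ml$family_vs_order$statistic_L, 0)
})
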