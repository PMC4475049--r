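#' Compare a trait between invasive and non-invasive species by t-test
#'
#' Two variants mirror the two ways a paired design can be analysed. The
#' `pooled_two_sample` variant is the classical equal-variance two-sample t on
#' the status groups, ignoring the pairing. The `paired_differences` variant
#' is the one-sample t of the per-pair differences (invasive minus
#' non-invasive) against zero, with `n_pairs - 1` degrees of freedom.
#'
#' @param values numeric trait values, one per species.
#' @param status logical (or 0/1) invasive flag per species.
#' @param pairing pair identifiers per species; required for the paired
#'   variant.
#' @param variant `"paired_differences"` (default) or `"pooled_two_sample"`.
#' @return list of class `ttest_result`: `statistic_t`, `df`, `p_value`,
#'   `mean_difference` (invasive minus non-invasive), `variant`, `n`.
#' @export
status_t_test <- function(values, status, pairing = NULL,
                          variant = c("paired_differences",
                                      "pooled_two_sample")) {
  variant <- match.arg(variant)
  status <- as.logical(status)
  stopifnot(length(values) == length(status))
  ok <- is.finite(values) & !is.na(status)
  values <- values[ok]; status <- status[ok]

  if (variant == "pooled_two_sample") {
    x <- values[status]; y <- values[!status]
    if (length(x) < 2L || length(y) < 2L)
      stop("need at least 2 values per status group")
    md <- mean(x) - mean(y)
    df <- length(x) + length(y) - 2L
    s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
    if (s2 == 0) {
      if (md == 0) return(ttest_result(0, df, 1, 0, variant,
                                       length(x) + length(y)))
      stop("zero within-group variance with non-zero mean difference")
    }
    t <- md / sqrt(s2 * (1 / length(x) + 1 / length(y)))
    return(ttest_result(t, df, 2 * stats::pt(-abs(t), df), md, variant,
                        length(x) + length(y)))
  }

  if (is.null(pairing)) stop("paired_differences variant requires pairing ids")
  pairing <- pairing[ok]
  sp <- split(seq_along(values), pairing)
  d <- vapply(sp, function(idx) {
    if (sum(status[idx]) == 0L || sum(!status[idx]) == 0L) return(NA_real_)
    mean(values[idx][status[idx]]) - mean(values[idx][!status[idx]])
  }, numeric(1))
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) return(ttest_result(0, n - 1L, 1, 0, variant, n))
    stop("zero variance of paired differences with non-zero mean")
  }
  t <- md / (sdd / sqrt(n))
  ttest_result(t, n - 1L, 2 * stats::pt(-abs(t), n - 1L), md, variant, n)
}

ttest_result <- function(t, df, p, md, variant, n) {
  structure(list(statistic_t = unname(t), df = unname(df),
                 p_value = unname(p), mean_difference = unname(md),
                 variant = variant, n = n),
            class = "ttest_result")
}

#' Paired-design linear mixed model (paired t-test analogue)
#'
#' Fits `value ~ status + (1 | pair)` by REML. Unlike the paired t-test, the
#' random pair intercept separates residual variation within pairs from
#' variation between pairs, giving the intraclass correlation
#' `ICC = sigma2_pair / (sigma2_pair + sigma2_res)` that measures how similar
#' the two members of a pair are. The status effect is tested with
#' Satterthwaite degrees of freedom.
#'
#' @param pairs pair table (see [match_pairs()]) or a long table with columns
#'   `pair_id`, `status`, `value`.
#' @param trait `"ldt"` or `"set"`; ignored when `pairs` is already long.
#' @param reml fit by REML (default) or maximum likelihood.
#' @return list of class `mixed_model_fit`: `fixed_effect_status` (invasive
#'   minus non-invasive), `se_fixed`, `statistic_t`, `satterthwaite_df`,
#'   `p_value`, `var_between`, `var_residual`, `icc`, `log_likelihood`,
#'   `grouping = "pair"`, `n_pairs`, `boundary` (TRUE when the pair variance
#'   hit zero) and the underlying `model`.
#' @export
paired_lmm <- function(pairs, trait = c("ldt", "set"), reml = TRUE) {
  long <- if (all(c("pair_id", "status", "value") %in% names(pairs)))
    pairs else pairs_to_long(pairs, match.arg(trait))
  long$status <- factor(long$status, levels = c("noninvasive", "invasive"))
  if (length(unique(long$pair_id)) < 3L) stop("need at least 3 pairs")

  fit <- withCallingHandlers(
    lmerTest::lmer(value ~ status + (1 | pair_id), data = long, REML = reml),
    message = function(m) {
      if (grepl("boundary", conditionMessage(m))) invokeRestart("muffleMessage")
    })
  mixed_fit_from_lmer(fit, grouping = "pair",
                      n_pairs = length(unique(long$pair_id)))
}

mixed_fit_from_lmer <- function(fit, grouping, n_pairs = NA_integer_) {
  sm <- stats::coef(summary(fit))
  row <- grep("^status", rownames(sm))
  stopifnot(length(row) == 1L)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_res <- vc$vcov[vc$grp == "Residual"]
  comp <- vc[vc$grp != "Residual", , drop = FALSE]
  var_between <- sum(comp$vcov)
  components <- stats::setNames(comp$vcov, comp$grp)
  structure(list(
    fixed_effect_status = unname(sm[row, "Estimate"]),
    se_fixed = unname(sm[row, "Std. Error"]),
    statistic_t = unname(sm[row, "t value"]),
    satterthwaite_df = unname(sm[row, "df"]),
    p_value = unname(sm[row, "Pr(>|t|)"]),
    var_between = var_between,
    var_residual = var_res,
    var_components = components,
    icc = var_between / (var_between + var_res),
    log_likelihood = as.numeric(stats::logLik(fit)),
    grouping = grouping,
    n_pairs = n_pairs,
    boundary = lme4::isSingular(fit),
    model = fit
  ), class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf(
    "Mixed model (grouping: %s): status effect = %.4f (SE %.4f), t = %.3f, df = %.1f, p = %.3g\n",
    x$grouping, x$fixed_effect_status, x$se_fixed, x$statistic_t,
    x$satterthwaite_df, x$p_value))
  cat(sprintf("  var between = %.4f, var residual = %.4f, ICC = %.3f%s\n",
              x$var_between, x$var_residual, x$icc,
              if (isTRUE(x$boundary)) " [boundary fit]" else ""))
  invisible(x)
}

species_long <- function(species_table, trait = c("ldt", "set")) {
  trait <- match.arg(trait)
  col <- c(ldt = "ldt_c", set = "set_dd")[[trait]]
  stopifnot(col %in% names(species_table))
  d <- data.frame(
    value = species_table[[col]],
    status = factor(ifelse(as.logical(species_table$invasive),
                           "invasive", "noninvasive"),
                    levels = c("noninvasive", "invasive")),
    order_taxon = as.character(species_table$order),
    family_taxon = as.character(species_table$family),
    stringsAsFactors = FALSE
  )
  d[is.finite(d$value), , drop = FALSE]
}

#' Mixed model on the nested taxonomic hierarchy
#'
#' Fits `trait ~ status` with a random-intercept structure of increasing
#' taxonomic depth: none (a plain linear model, equivalent to the pooled
#' two-sample t-test), a random intercept per order, or random intercepts per
#' order and per family nested within order. This accounts for the varying
#' relatedness of species within pairs. A hierarchy level with fewer than two
#' groups falls back to the next simpler structure with a warning.
#'
#' @param species_table one row per species with columns `order`, `family`,
#'   `invasive`, and `ldt_c`/`set_dd`.
#' @param trait `"ldt"` or `"set"`.
#' @param hierarchy `"none"`, `"order"`, or `"family_in_order"`.
#' @param reml fit by REML (default) or maximum likelihood; the reported
#'   log-likelihood follows the same criterion so that nested structures
#'   stay comparable.
#' @return a `mixed_model_fit`; for `hierarchy = "none"` the Satterthwaite df
#'   is the exact OLS residual df and `var_between = 0`.
#' @export
nested_taxonomy_lmm <- function(species_table, trait = c("ldt", "set"),
                                hierarchy = c("none", "order",
                                              "family_in_order"),
                                reml = TRUE) {
  trait <- match.arg(trait)
  hierarchy <- match.arg(hierarchy)
  d <- species_long(species_table, trait)

  if (hierarchy != "none" && length(unique(d$order_taxon)) < 2L) {
    warning("fewer than 2 orders; falling back to hierarchy = 'none'")
    hierarchy <- "none"
  }
  if (hierarchy == "family_in_order" &&
      length(unique(paste(d$order_taxon, d$family_taxon))) < 2L) {
    warning("fewer than 2 families; falling back to hierarchy = 'order'")
    hierarchy <- "order"
  }

  if (hierarchy == "none") {
    fit <- stats::lm(value ~ status, data = d)
    sm <- stats::coef(summary(fit))
    return(structure(list(
      fixed_effect_status = unname(sm[2, "Estimate"]),
      se_fixed = unname(sm[2, "Std. Error"]),
      statistic_t = unname(sm[2, "t value"]),
      satterthwaite_df = fit$df.residual,
      p_value = unname(sm[2, "Pr(>|t|)"]),
      var_between = 0,
      var_residual = sum(stats::resid(fit)^2) / fit$df.residual,
      var_components = stats::setNames(numeric(0), character(0)),
      icc = 0,
      log_likelihood = if (reml) reml_loglik_lm(fit)
        else as.numeric(stats::logLik(fit)),
      grouping = "none",
      n_pairs = NA_integer_,
      boundary = FALSE,
      model = fit
    ), class = "mixed_model_fit"))
  }

  form <- if (hierarchy == "order")
    value ~ status + (1 | order_taxon)
  else
    value ~ status + (1 | order_taxon) + (1 | order_taxon:family_taxon)
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = d, REML = reml),
    message = function(m) {
      if (grepl("boundary", conditionMessage(m))) invokeRestart("muffleMessage")
    })
  mixed_fit_from_lmer(fit, grouping = hierarchy)
}

# REML log-likelihood of an OLS fit on the same scale as lme4's REML
# criterion: -2 l = log|X'X| + (n - p) * (1 + log(2 pi RSS / (n - p))).
reml_loglik_lm <- function(fit) {
  X <- stats::model.matrix(fit)
  n <- nrow(X); p <- ncol(X)
  rss <- sum(stats::resid(fit)^2)
  -0.5 * (as.numeric(determinant(crossprod(X))$modulus) +
            (n - p) * (1 + log(2 * pi * rss / (n - p))))
}

#' Likelihood-ratio sequence over nested random-effect structures
#'
#' Fits the three nested structures — (i) no random effect, (ii) a random
#' intercept per order, (iii) orders plus families within orders — on
#' identical data with identical fixed effects, and reports
#' `L = 2 (l_alt - l_null)` for (ii) vs (i) and (iii) vs (ii), each on 1 df.
#' Likelihoods are REML with the same fixed-effect design, so they are
#' comparable across random structures. Negative statistics (possible at the
#' variance boundary) are clipped to zero and noted.
#'
#' @inheritParams nested_taxonomy_lmm
#' @return list of two `lr_test_result` objects (`order_vs_none`,
#'   `family_vs_order`), each with `statistic_L`, `df`, `p_value`,
#'   `model_null`, `model_alt`, `clipped`.
#' @export
lr_test_sequence <- function(species_table, trait = c("ldt", "set"),
                             reml = TRUE) {
  trait <- match.arg(trait)
  fits <- lapply(c("none", "order", "family_in_order"), function(h)
    nested_taxonomy_lmm(species_table, trait, h, reml = reml))
  ll <- vapply(fits, `[[`, numeric(1), "log_likelihood")
  step <- function(null, alt, lab0, lab1) {
    L <- 2 * (ll[alt] - ll[null])
    clipped <- L < 0
    L <- max(L, 0)
    structure(list(statistic_L = L, df = 1L,
                   p_value = stats::pchisq(L, 1, lower.tail = FALSE),
                   model_null = lab0, model_alt = lab1, clipped = clipped),
              class = "lr_test_result")
  }
  list(order_vs_none = step(1, 2, "none", "order"),
       family_vs_order = step(2, 3, "order", "family_in_order"))
}

#' Pearson correlation of the paired LDT and SET differences
#'
#' Tests whether pairs in which the invasive species has the higher LDT also
#' tend to have the lower SET (an inverse relationship between the two
#' thermal requirements). Also reports the fraction of pairs whose
#' differences have strictly opposite signs (higher LDT with lower SET or
#' vice versa); pairs with a zero difference count as non-concordant.
#'
#' @param differences data frame with columns `d_ldt` and `d_set`
#'   (see [pair_differences()]); incomplete pairs are dropped.
#' @return list of class `correlation_result`: `r`, `p_value`, `n`,
#'   `concordance_fraction`.
#' @export
difference_correlation <- function(differences) {
  stopifnot(all(c("d_ldt", "d_set") %in% names(differences)))
  ok <- is.finite(differences$d_ldt) & is.finite(differences$d_set)
  x <- differences$d_ldt[ok]; y <- differences$d_set[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a difference vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(x),
    concordance_fraction = mean(sign(x) * sign(y) < 0)
  ), class = "correlation_result")
}

#' Normality diagnostics for a trait vector
#'
#' Sample skewness (g1), excess kurtosis (g2, normal = 0) and the
#' Shapiro-Wilk test.
#'
#' @param values numeric vector, at least 4 finite non-constant values.
#' @return list of class `normality_report`: `skewness`, `kurtosis`
#'   (excess), `shapiro_w`, `shapiro_p`, `n`.
#' @export
normality_diagnostics <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 4L) stop("need at least 4 finite values")
  if (stats::sd(x) == 0) stop("constant vector")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  sw <- stats::shapiro.test(x)
  structure(list(
    skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2 - 3,
    shapiro_w = unname(sw$statistic),
    shapiro_p = sw$p.value,
    n = n
  ), class = "normality_report")
}

#' Residual diagnostics for a fitted mixed model
#'
#' Per-observation fitted values and residuals, plus the predicted random
#' intercepts (BLUPs) per group — shrunk toward zero relative to the raw
#' group means. Use [plot_residual_diagnostics()] for the residual-vs-fitted
#' panels.
#'
#' @param fit a `mixed_model_fit`.
#' @return list of class `residual_diagnostics`: `observations` (data frame
#'   with `fitted`, `residual`) and `random_effects` (data frame with
#'   `grouping`, `level`, `blup`; empty for a fixed-effects-only fit).
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  m <- fit$model
  obs <- data.frame(fitted = as.numeric(stats::fitted(m)),
                    residual = as.numeric(stats::resid(m)))
  if (inherits(m, "merMod")) {
    re <- lme4::ranef(m)
    rand <- do.call(rbind, lapply(names(re), function(g) {
      data.frame(grouping = g, level = rownames(re[[g]]),
                 blup = re[[g]][["(Intercept)"]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    rand <- data.frame(grouping = character(0), level = character(0),
                       blup = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(rand) <- NULL
  structure(list(observations = obs, random_effects = rand),
            class = "residual_diagnostics")
}

#' Plot residuals against fitted values
#'
#' @param diag output of [residual_diagnostics()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `diag`.
#' @export
plot_residual_diagnostics <- function(diag, ...) {
  stopifnot(inherits(diag, "residual_diagnostics"))
  graphics::plot(diag$observations$fitted, diag$observations$residual,
                 xlab = "Fitted value", ylab = "Residual", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(diag)
}
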