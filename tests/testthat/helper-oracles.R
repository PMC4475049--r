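# Independent oracles used across the suite; deliberately brute-force and
# separate from the package's own code paths.

# OLS via the normal equations on (x, y)
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  c(intercept = a, slope = b)
}

# textbook Pearson correlation
pearson_textbook <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# numerical integration of the diurnal sine curve above a threshold
sine_dd_numeric <- function(t_min, t_max, ldt, n_steps = 20000L) {
  m <- (t_max + t_min) / 2
  w <- (t_max - t_min) / 2
  tau <- (seq_len(n_steps) - 0.5) / n_steps
  mean(pmax(0, m + w * sin(2 * pi * tau) - ldt))
}

# brute-force tightest shared taxonomic rank between two trait-table rows
brute_tightest_rank <- function(a, b) {
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  if (a$order != b$order) return(NA_character_)
  if (a$genus == b$genus && a$family == b$family) return("genus")
  if (!blank(a$tribe) && !blank(b$tribe) && a$tribe == b$tribe &&
      a$family == b$family) return("tribe")
  if (!blank(a$subfamily) && !blank(b$subfamily) &&
      a$subfamily == b$subfamily && a$family == b$family) return("subfamily")
  if (a$family == b$family) return("family")
  NA_character_
}

# brute-force pairing oracle: for one non-invasive row, the invasive
# candidate set at the tightest attainable rank
brute_match <- function(ni, invasives) {
  ranks <- c(genus = 1, tribe = 2, subfamily = 3, family = 4)
  cand <- invasives[invasives$continent == ni$continent, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  rk <- vapply(seq_len(nrow(cand)),
               function(j) brute_tightest_rank(ni, cand[j, ]), character(1))
  if (all(is.na(rk))) return(NULL)
  best <- names(ranks)[min(ranks[rk[!is.na(rk)]])]
  list(rank = best, ids = sort(cand$species_id[!is.na(rk) & rk == best]))
}

# balanced one-way ANOVA method-of-moments variance components for paired
# data (2 members per pair), after removing the status means
anova_mom_components <- function(long) {
  resp <- long$value - ave(long$value, long$status)
  grp <- split(resp, long$pair_id)
  J <- length(grp)
  gm <- mean(resp)
  msb <- 2 * sum((vapply(grp, mean, numeric(1)) - gm)^2) / (J - 1)
  msw <- sum(vapply(grp, function(v) sum((v - mean(v))^2), numeric(1))) / J
  c(var_pair = max((msb - msw) / 2, 0), var_res = msw)
}

make_tr <- function(ldt, set_dd, species = "sp", stage = "egg_to_adult") {
  thermopair:::new_thermal_requirement(species, stage, ldt, set_dd)
}
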