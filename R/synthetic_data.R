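#' Configuration of the synthetic pair-data generator
#'
#' Default parameters match the aggregate statistics of the real 100-pair
#' comparison the package emulates: a mean paired LDT difference of 1.4
#' degrees C, a mean paired SET difference of -39.3 day-degrees, intraclass
#' correlations of 0.217 (LDT) and 0.222 (SET), a correlation of -0.276
#' between the paired differences, and 12% of pairs lacking SET. The residual
#' (within-pair) spreads are back-calculated from the published paired t
#' statistics: `sd(d_ldt) = 1.4 * sqrt(100) / 4.38` gives
#' `sd_res_ldt = 3.196/sqrt(2) = 2.260` degrees C, and
#' `sd(d_set) = 39.3/1.52 * sqrt(88)` gives `sd_res_set = 171.5` day-degrees.
#' Between-pair variance follows from the target ICC,
#' `sigma2_B = icc/(1-icc) * sigma2_res`, and is split across order, family
#' and pair-specific components in the proportions `between_split`.
#'
#' @param seed integer seed; all randomness in the generators flows from it.
#' @param n_pairs number of species pairs (default 100).
#' @param effect_ldt mean invasive-minus-non-invasive LDT difference,
#'   degrees C.
#' @param effect_set mean SET difference, day-degrees (negative: invasive
#'   species develop faster).
#' @param sd_res_ldt,sd_res_set within-pair residual SDs per trait.
#' @param target_icc_ldt,target_icc_set intraclass correlations; ignored for
#'   a trait when the corresponding `sd_between_*` is given.
#' @param sd_between_ldt,sd_between_set optional direct between-pair SDs
#'   (alternative parameterisation to the target ICCs).
#' @param rho_diff correlation between `d_ldt` and `d_set` within a pair.
#' @param set_missing_fraction fraction of pairs whose SET is missing.
#' @param mean_ldt,mean_set grand means of the traits.
#' @param n_orders,families_per_order taxonomy shape for the nested analyses.
#' @param between_split proportions of the between-pair variance attributed
#'   to order, family and pair-specific components (must sum to 1).
#' @param temperatures,replicates,rate_noise_sd design of the
#'   development-data generator: rearing temperatures (degrees C), replicates
#'   per temperature, Gaussian noise SD on the rate scale (1/day).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_pairs = 100L,
                              effect_ldt = 1.4,
                              effect_set = -39.3,
                              sd_res_ldt = 2.260,
                              sd_res_set = 171.5,
                              target_icc_ldt = 0.217,
                              target_icc_set = 0.222,
                              sd_between_ldt = NULL,
                              sd_between_set = NULL,
                              rho_diff = -0.276,
                              set_missing_fraction = 0.12,
                              mean_ldt = 10,
                              mean_set = 400,
                              n_orders = 5L,
                              families_per_order = 4L,
                              between_split = c(order = 0.3, family = 0.3,
                                                pair = 0.4),
                              temperatures = c(15, 20, 25, 30),
                              replicates = 10L,
                              rate_noise_sd = 0.002) {
  stopifnot(sd_res_ldt >= 0, sd_res_set >= 0,
            target_icc_ldt >= 0, target_icc_ldt < 1,
            target_icc_set >= 0, target_icc_set < 1,
            rho_diff >= -1, rho_diff <= 1,
            set_missing_fraction >= 0, set_missing_fraction < 1,
            n_pairs >= 1, n_orders >= 1, families_per_order >= 1,
            abs(sum(between_split) - 1) < 1e-8, all(between_split >= 0),
            rate_noise_sd >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

between_sd <- function(cfg, trait) {
  direct <- cfg[[paste0("sd_between_", trait)]]
  if (!is.null(direct)) return(direct)
  icc <- cfg[[paste0("target_icc_", trait)]]
  res <- cfg[[paste0("sd_res_", trait)]]
  res * sqrt(icc / (1 - icc))
}

#' Generate a balanced nested taxonomy label table
#'
#' @param n_orders,families_per_order,species_per_family counts (all >= 1).
#' @param seed unused placeholder for interface symmetry; the table is fully
#'   deterministic.
#' @return data frame with `order`, `family`, `species_id`.
#' @export
generate_taxonomy <- function(n_orders, families_per_order, species_per_family,
                              seed = NULL) {
  stopifnot(n_orders >= 1, families_per_order >= 1, species_per_family >= 1)
  g <- expand.grid(sp = seq_len(species_per_family),
                   fam = seq_len(families_per_order),
                   ord = seq_len(n_orders))
  data.frame(
    order = sprintf("order_%02d", g$ord),
    family = sprintf("family_%02d_%02d", g$ord, g$fam),
    species_id = sprintf("sp_%02d_%02d_%02d", g$ord, g$fam, g$sp),
    stringsAsFactors = FALSE
  )
}

#' Generate development-time observations under the linear rate model
#'
#' For each rearing temperature and replicate, a development rate is drawn as
#' `(T - true_ldt)/true_set` plus Gaussian noise on the rate scale (additive
#' rate noise matches the linear model under which LDT and SET are
#' estimated); non-positive draws are resampled so that development times
#' `1/rate` stay finite and positive. Deterministic given the seed.
#'
#' @param true_ldt,true_set generating LDT (degrees C) and SET (day-degrees).
#' @param temperatures rearing temperatures; all must exceed `true_ldt`.
#' @param replicates replicates per temperature.
#' @param rate_noise_sd Gaussian noise SD on the rate scale (1/day).
#' @param seed integer seed.
#' @param species_id,stage labels carried into the records.
#' @return data frame of observations (`species_id`, `population_id`,
#'   `study_id`, `stage`, `temperature`, `development_time`).
#' @export
generate_development_dataset <- function(true_ldt, true_set,
                                         temperatures = c(15, 20, 25, 30),
                                         replicates = 10L,
                                         rate_noise_sd = 0.002,
                                         seed = 1L,
                                         species_id = "sim_species",
                                         stage = "egg_to_adult") {
  stopifnot(rate_noise_sd >= 0, replicates >= 1, true_set > 0)
  if (any(temperatures <= true_ldt))
    stop("all design temperatures must exceed the true LDT (",
         true_ldt, " degC)")
  set.seed(seed)
  temp <- rep(temperatures, each = replicates)
  rate <- (temp - true_ldt) / true_set +
    stats::rnorm(length(temp), 0, rate_noise_sd)
  while (any(rate <= 0))  # truncation to positive rates by resampling
    rate[rate <= 0] <- (temp[rate <= 0] - true_ldt) / true_set +
      stats::rnorm(sum(rate <= 0), 0, rate_noise_sd)
  data.frame(
    species_id = species_id,
    population_id = "pop_1",
    study_id = "study_1",
    stage = stage,
    temperature = temp,
    development_time = 1 / rate,
    stringsAsFactors = FALSE
  )
}

#' Generate a pair-structured species trait table
#'
#' Draws, per pair: a baseline LDT (and SET) composed of order, family and
#' pair-specific Gaussian effects whose summed variance realises the target
#' ICC; a shared within-pair component; and a bivariate-normal pair of trait
#' differences `(d_ldt, d_set)` with means `(effect_ldt, effect_set)`, SDs
#' `sqrt(2) * sd_res`, and correlation `rho_diff`. The two species of a pair
#' then sit at `baseline + shared -/+ d/2`, which makes the within-pair
#' species variance exactly `sd_res^2` and the between-pair covariance the
#' baseline variance, so the population ICC equals the configured target. A
#' `set_missing_fraction` share of pairs get their SET values set to `NA`
#' (completely at random). Each pair receives its own genus on a shared
#' continent, so the table pairs back up at genus rank under [match_pairs()].
#'
#' @param config a [simulation_config()].
#' @return list with `species` (one row per species, readable by
#'   [match_pairs()]), `pairs` (one row per pair with both members' traits
#'   and the true differences), and `config`.
#' @export
generate_pair_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_pairs

  draw_trait <- function(trait, delta) {
    sB <- between_sd(cfg, trait)
    sds <- sqrt(cfg$between_split) * sB
    s_res <- cfg[[paste0("sd_res_", trait)]]
    n_fam <- cfg$n_orders * cfg$families_per_order
    ord_idx <- ((seq_len(n) - 1L) %% cfg$n_orders) + 1L
    fam_idx <- ((seq_len(n) - 1L) %% n_fam) + 1L
    u_ord <- stats::rnorm(cfg$n_orders, 0, sds[["order"]])[ord_idx]
    u_fam <- stats::rnorm(n_fam, 0, sds[["family"]])[fam_idx]
    u_pair <- stats::rnorm(n, 0, sds[["pair"]])
    shared <- stats::rnorm(n, 0, s_res / sqrt(2))
    base <- cfg[[paste0("mean_", trait)]] + u_ord + u_fam + u_pair + shared
    list(noninv = base - delta / 2, inv = base + delta / 2,
         ord_idx = ord_idx, fam_idx = fam_idx)
  }

  # correlated within-pair differences; sd(d) = sqrt(2) * sd_res per trait
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  d_ldt <- cfg$effect_ldt + sqrt(2) * cfg$sd_res_ldt * z1
  d_set <- cfg$effect_set + sqrt(2) * cfg$sd_res_set *
    (cfg$rho_diff * z1 + sqrt(1 - cfg$rho_diff^2) * z2)

  ldt <- draw_trait("ldt", d_ldt)
  set <- draw_trait("set", d_set)
  miss <- stats::runif(n) < cfg$set_missing_fraction
  set$noninv[miss] <- NA_real_
  set$inv[miss] <- NA_real_

  continents <- c("Europe", "North_America", "Asia", "Africa", "Oceania",
                  "South_America")
  cont <- sample(continents, n, replace = TRUE,
                 prob = c(0.36, 0.43, 0.15, 0.02, 0.02, 0.02))

  order_lab <- sprintf("order_%02d", ldt$ord_idx)
  family_lab <- sprintf("family_%02d", ldt$fam_idx)
  genus_lab <- sprintf("genus_%03d", seq_len(n))
  id_non <- sprintf("P%03d_N", seq_len(n))
  id_inv <- sprintf("P%03d_I", seq_len(n))

  species <- data.frame(
    species_id = c(id_non, id_inv),
    order = rep(order_lab, 2L),
    family = rep(family_lab, 2L),
    subfamily = NA_character_,
    tribe = NA_character_,
    genus = rep(genus_lab, 2L),
    continent = rep(cont, 2L),
    invasive = rep(c(0L, 1L), each = n),
    flags = "",
    ldt_c = c(ldt$noninv, ldt$inv),
    set_dd = c(set$noninv, set$inv),
    stringsAsFactors = FALSE
  )

  pairs <- data.frame(
    pair_id = sprintf("pair_%03d", seq_len(n)),
    noninvasive_id = id_non,
    invasive_ids = id_inv,
    relatedness_rank = "genus",
    continent = cont,
    order_taxon = order_lab,
    family_taxon = family_lab,
    ldt_noninv = ldt$noninv,
    ldt_inv = ldt$inv,
    set_noninv = set$noninv,
    set_inv = set$inv,
    stringsAsFactors = FALSE
  )
  pairs$d_ldt <- pairs$ldt_inv - pairs$ldt_noninv
  pairs$d_set <- pairs$set_inv - pairs$set_noninv

  list(species = species, pairs = pairs, config = cfg)
}
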