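detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  if (grepl("\t", header)) "\t" else ","
}

read_table_strict <- function(path, required, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) delimiter <- detect_delim(path)
  d <- utils::read.table(path, header = TRUE, sep = delimiter,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""),
                         comment.char = "", quote = "\"")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  d
}

#' Read a development-observation table
#'
#' Delimited text (comma or tab, auto-detected) with header columns
#' `species_id`, `population_id`, `study_id`, `stage`, `temperature_c`,
#' `development_time_d`. Malformed rows (missing or non-finite temperature,
#' non-positive development time) are never silently dropped: they are
#' collected, with their file line numbers and a reason, into the `rejects`
#' element.
#'
#' @param path input file.
#' @param delimiter `","` or `"\t"`; auto-detected when `NULL`.
#' @return list with `observations` (validated data frame with columns
#'   `species_id`, `population_id`, `study_id`, `stage`, `temperature`,
#'   `development_time`) and `rejects` (data frame `line`, `reason`).
#' @export
read_observations <- function(path, delimiter = NULL) {
  req <- c("species_id", "population_id", "study_id", "stage",
           "temperature_c", "development_time_d")
  d <- read_table_strict(path, req, delimiter)
  temp <- suppressWarnings(as.numeric(d$temperature_c))
  dt <- suppressWarnings(as.numeric(d$development_time_d))
  bad_temp <- !is.finite(temp)
  bad_time <- !is.finite(dt) | dt <= 0
  bad <- bad_temp | bad_time
  rejects <- data.frame(
    line = which(bad) + 1L,  # +1 for the header line
    reason = ifelse(bad_temp[bad], "missing or non-finite temperature",
                    "missing, non-finite or non-positive development time"),
    stringsAsFactors = FALSE
  )
  obs <- data.frame(
    species_id = as.character(d$species_id[!bad]),
    population_id = as.character(d$population_id[!bad]),
    study_id = as.character(d$study_id[!bad]),
    stage = as.character(d$stage[!bad]),
    temperature = temp[!bad],
    development_time = dt[!bad],
    stringsAsFactors = FALSE
  )
  list(observations = obs, rejects = rejects)
}

#' Read a species trait table
#'
#' Delimited text with header columns `species_id`, `order`, `family`,
#' `subfamily`, `tribe`, `genus`, `continent`, `invasive` (0/1), `flags`
#' (semicolon list, empty for none), `ldt_c`, `set_dd`.
#'
#' @inheritParams read_observations
#' @return data frame readable by [match_pairs()].
#' @export
read_species_traits <- function(path, delimiter = NULL) {
  req <- c("species_id", "order", "family", "genus", "continent",
           "invasive", "ldt_c", "set_dd")
  d <- read_table_strict(path, req, delimiter)
  if (!"subfamily" %in% names(d)) d$subfamily <- NA_character_
  if (!"tribe" %in% names(d)) d$tribe <- NA_character_
  if (!"flags" %in% names(d)) d$flags <- ""
  d$flags[is.na(d$flags)] <- ""
  d$ldt_c <- suppressWarnings(as.numeric(d$ldt_c))
  d$set_dd <- suppressWarnings(as.numeric(d$set_dd))
  d
}

#' Write a delimited table
#'
#' @param x data frame.
#' @param path output file.
#' @param delimiter field separator (default comma).
#' @return invisibly, `path`.
#' @export
write_delim_table <- function(x, path, delimiter = ",") {
  utils::write.table(x, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Estimate thermal requirements for every species in an observation table
#'
#' For each species/population/stage group, fits the rate regression and
#' derives LDT and SET; aggregates populations of the same species/stage with
#' outlier screening; then selects one species-level value across stages
#' (whole development preferred). Groups with too few temperatures or a
#' non-positive slope are skipped and reported in the `skipped` attribute.
#'
#' @param observations validated observation data frame (see
#'   [read_observations()]).
#' @param min_temperatures,on_means passed to [fit_rate_regression()].
#' @param outlier_k passed to [aggregate_populations()].
#' @return data frame with `species_id`, `stage`, `ldt_c`, `set_dd`,
#'   `se_ldt`, `se_set`, `n_sources`, `source`; attribute `skipped` lists
#'   groups that could not be fitted and why.
#' @export
estimate_thermal_requirements <- function(observations, min_temperatures = 3,
                                          outlier_k = 3, on_means = FALSE) {
  skipped <- character(0)
  by_species <- split(observations, observations$species_id)
  rows <- lapply(by_species, function(sp_obs) {
    by_stage <- split(sp_obs, sp_obs$stage)
    stage_ests <- list()
    for (stage_obs in by_stage) {
      pop_ests <- list()
      for (pop_obs in split(stage_obs,
                            paste(stage_obs$population_id,
                                  stage_obs$study_id))) {
        est <- tryCatch(
          derive_thermal_constants(
            fit_rate_regression(pop_obs, min_temperatures, on_means)),
          error = function(e) {
            skipped <<- c(skipped, conditionMessage(e))
            NULL
          })
        if (!is.null(est)) pop_ests[[length(pop_ests) + 1L]] <- est
      }
      if (length(pop_ests) > 0)
        stage_ests[[length(stage_ests) + 1L]] <-
          aggregate_populations(pop_ests, outlier_k)
    }
    if (length(stage_ests) == 0L) return(NULL)
    tr <- select_stage_values(stage_ests)
    data.frame(species_id = tr$species_id, stage = tr$stage,
               ldt_c = tr$ldt, set_dd = tr$set_dd,
               se_ldt = tr$se_ldt, se_set = tr$se_set,
               n_sources = tr$n_sources, source = tr$source,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(species_id = character(0), stage = character(0),
                      ldt_c = numeric(0), set_dd = numeric(0),
                      se_ldt = numeric(0), se_set = numeric(0),
                      n_sources = integer(0), source = character(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Run the full comparative analysis on a pair table
#'
#' The three analyses applied to each trait — the paired-difference t-test,
#' the paired-design mixed model with its ICC, the nested-taxonomy mixed
#' model with the likelihood-ratio sequence (when taxonomy columns are
#' present) — plus the Pearson correlation of the paired differences and
#' normality diagnostics.
#'
#' @param pairs pair table (from [match_pairs()] or
#'   [generate_pair_dataset()]); taxonomy-dependent analyses need
#'   `order_taxon`/`family_taxon` columns or a `species` table.
#' @param species optional species trait table for the nested-taxonomy
#'   analyses.
#' @return nested list of result objects, one block per trait, plus the
#'   difference correlation.
#' @export
compare_pairs <- function(pairs, species = NULL) {
  res <- list()
  for (trait in c("ldt", "set")) {
    long <- pairs_to_long(pairs, trait)
    block <- list(
      paired_t = status_t_test(long$value, long$status == "invasive",
                               long$pair_id, "paired_differences"),
      pooled_t = status_t_test(long$value, long$status == "invasive",
                               variant = "pooled_two_sample"),
      paired_lmm = paired_lmm(long),
      normality = normality_diagnostics(long$value)
    )
    if (!is.null(species)) {
      block$nested_lmm <- nested_taxonomy_lmm(species, trait,
                                              "family_in_order")
      block$lr_sequence <- lr_test_sequence(species, trait)
    }
    res[[trait]] <- block
  }
  res$difference_correlation <-
    difference_correlation(pair_differences(pairs))
  res
}

# deterministic polynomial fingerprint of the configuration (not crypto)
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

results_to_records <- function(results) {
  flatten <- function(x, prefix = character(0)) {
    if (inherits(x, c("ttest_result", "mixed_model_fit", "lr_test_result",
                      "correlation_result", "normality_report"))) {
      rec <- unclass(x)
      rec$model <- NULL
      rec$var_components <- as.list(rec$var_components)
      return(stats::setNames(list(rec), paste(prefix, collapse = ".")))
    }
    if (is.list(x))
      return(do.call(c, lapply(names(x), function(nm)
        flatten(x[[nm]], c(prefix, nm)))))
    stats::setNames(list(x), paste(prefix, collapse = "."))
  }
  flatten(results)
}

#' Write a structured results report
#'
#' Machine-readable JSON with stable key order, plus an optional
#' human-readable summary listing statistic, df and p per analysis and
#' trait. Reports carry the package version and a hash of the configuration,
#' never a timestamp, so identical runs produce byte-identical files.
#'
#' @param results output of [compare_pairs()] (or any nested list of result
#'   objects).
#' @param path JSON output file.
#' @param summary_path optional text summary file.
#' @param config optional configuration list hashed into the report.
#' @return invisibly, `path`.
#' @export
write_results_report <- function(results, path, summary_path = NULL,
                                 config = NULL) {
  records <- results_to_records(results)
  payload <- list(
    package = "thermopair",
    version = as.character(utils::packageVersion("thermopair")),
    config_hash = config_hash(deparse(config)),
    analyses = records
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(summary_path)) {
    lines <- c("thermopair analysis report", "")
    for (nm in names(records)) {
      r <- records[[nm]]
      if (!is.list(r)) next
      stat <- r$statistic_t %||% r$statistic_L %||% r$r
      df <- r$satterthwaite_df %||% r$df %||% r$n
      p <- r$p_value %||% r$shapiro_p
      if (is.null(stat) || is.null(p)) next
      lines <- c(lines, sprintf("%-40s stat = %8.4f  df/n = %8.2f  p = %.4g",
                                nm, stat, as.numeric(df), p))
    }
    writeLines(lines, summary_path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the estimate - pair - compare pipeline
#'
#' Orchestrates the full workflow: optional estimation of thermal
#' requirements from rearing observations, pair assembly from the trait
#' table, and the comparative analyses, writing all artifacts into an output
#' directory with per-stage logging (records read and rejected, pairs
#' formed, relatedness-rank tally, unmatched species). Deterministic: two
#' runs from the same inputs produce byte-identical reports.
#'
#' @param traits_path species trait table (see [read_species_traits()]).
#' @param out_dir output directory, created if needed.
#' @param observations_path optional development-observation table; when
#'   given, a thermal-requirements table is estimated and written as well.
#' @param min_temperatures,outlier_k estimation settings.
#' @param delimiter input delimiter (auto-detected when `NULL`).
#' @return invisibly, a list with the pair table, the results, and the paths
#'   written.
#' @export
run_pipeline <- function(traits_path, out_dir,
                         observations_path = NULL,
                         min_temperatures = 3, outlier_k = 3,
                         delimiter = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (!is.null(observations_path)) {
    message("[estimate] reading observations from ", observations_path)
    obs <- read_observations(observations_path, delimiter)
    message("[estimate] ", nrow(obs$observations), " records, ",
            nrow(obs$rejects), " rejected")
    tr <- estimate_thermal_requirements(obs$observations, min_temperatures,
                                        outlier_k)
    paths$thermal_requirements <- file.path(out_dir,
                                            "thermal_requirements.csv")
    write_delim_table(tr, paths$thermal_requirements)
  }

  message("[pair] reading traits from ", traits_path)
  traits <- read_species_traits(traits_path, delimiter)
  pairs <- match_pairs(traits)
  plog <- attr(pairs, "log")
  message("[pair] ", nrow(pairs), " pairs formed; ",
          length(plog$unmatched_noninvasive), " non-invasive unmatched; ",
          length(plog$excluded_flagged), " excluded by flags")
  paths$pairs <- file.path(out_dir, "pairs.csv")
  write_delim_table(pairs, paths$pairs)

  message("[compare] running analyses")
  results <- compare_pairs(pairs, species = traits)
  paths$report <- file.path(out_dir, "results.json")
  paths$summary <- file.path(out_dir, "results_summary.txt")
  write_results_report(results, paths$report, paths$summary,
                       config = list(traits_path = basename(traits_path),
                                     min_temperatures = min_temperatures,
                                     outlier_k = outlier_k))
  invisible(list(pairs = pairs, results = results, paths = paths))
}
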