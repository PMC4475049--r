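#' Match non-invasive species to related invasive species
#'
#' Builds the comparison units of the source-area approach: each eligible
#' non-invasive species is matched to invasive species from the same continent
#' at the tightest available taxonomic rank — same genus, tribe, sub-family or
#' family, in this order of preference. When several invasive species tie at
#' the tightest rank, all are included and their trait values averaged, which
#' is more conservative than choosing one subjectively or at random. A
#' non-invasive species is used at most once; the same invasive species may
#' serve in several pairs. Species flagged as biological-control/intentional
#' introductions, stored-product pests or cryptogenic, and species without an
#' LDT value, are excluded before matching; exclusions, unmatched species and
#' invasive reuse counts are recorded in the `log` attribute.
#'
#' @param records data frame with columns `species_id`, `order`, `family`,
#'   `subfamily`, `tribe`, `genus`, `continent`, `invasive` (0/1 or logical),
#'   `flags` (semicolon-separated; empty = none), `ldt_c`, `set_dd`.
#' @return data frame of pairs: `pair_id`, `noninvasive_id`, `invasive_ids`
#'   (semicolon-joined), `relatedness_rank`, `continent`, `ldt_noninv`,
#'   `ldt_inv`, `set_noninv`, `set_inv`, `d_ldt`, `d_set` (invasive minus
#'   non-invasive; `NA` where either member lacks SET), with a `log`
#'   attribute.
#' @export
match_pairs <- function(records) {
  stopifnot(is.data.frame(records))
  req <- c("species_id", "order", "family", "genus", "continent",
           "invasive", "ldt_c", "set_dd")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0)
    stop("trait table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"subfamily" %in% names(records)) records$subfamily <- NA_character_
  if (!"tribe" %in% names(records)) records$tribe <- NA_character_
  if (!"flags" %in% names(records)) records$flags <- ""
  if (anyDuplicated(records$species_id))
    stop("duplicate species_id in trait table: ",
         paste(unique(records$species_id[duplicated(records$species_id)]),
               collapse = ", "))
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  bad_tax <- blank(records$order) | blank(records$family) |
    blank(records$genus)
  if (any(bad_tax))
    stop("missing order/family/genus for: ",
         paste(records$species_id[bad_tax], collapse = ", "))

  records$invasive <- as.logical(as.integer(as.logical(records$invasive)))
  flagged <- !blank(records$flags)
  no_ldt <- !is.finite(records$ldt_c)
  eligible <- records[!flagged & !no_ldt, , drop = FALSE]

  inv <- eligible[eligible$invasive, , drop = FALSE]
  non <- eligible[!eligible$invasive, , drop = FALSE]

  ranks <- c("genus", "tribe", "subfamily", "family")
  pair_rows <- vector("list", nrow(non))
  unmatched <- character(0)

  for (i in seq_len(nrow(non))) {
    ni <- non[i, ]
    cand <- inv[inv$continent == ni$continent & inv$order == ni$order, ,
                drop = FALSE]
    hit <- NULL
    hit_rank <- NA_character_
    for (rk in ranks) {
      if (rk != "family") {
        # missing intermediate ranks are skipped, not treated as mismatches
        if (blank(ni[[rk]])) next
        same <- !blank(cand[[rk]]) & cand[[rk]] == ni[[rk]] &
          cand$family == ni$family
      } else {
        same <- cand$family == ni$family
      }
      if (any(same)) {
        hit <- cand[same, , drop = FALSE]
        hit_rank <- rk
        break
      }
    }
    if (is.null(hit)) {
      unmatched <- c(unmatched, ni$species_id)
      next
    }
    set_inv_vals <- hit$set_dd[is.finite(hit$set_dd)]
    set_inv <- if (length(set_inv_vals) > 0) mean(set_inv_vals) else NA_real_
    set_non <- if (is.finite(ni$set_dd)) ni$set_dd else NA_real_
    pair_rows[[i]] <- data.frame(
      noninvasive_id = ni$species_id,
      invasive_ids = paste(hit$species_id, collapse = ";"),
      relatedness_rank = hit_rank,
      continent = ni$continent,
      ldt_noninv = ni$ldt_c,
      ldt_inv = mean(hit$ldt_c),
      set_noninv = set_non,
      set_inv = set_inv,
      stringsAsFactors = FALSE
    )
  }

  pairs <- do.call(rbind, pair_rows[!vapply(pair_rows, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- data.frame(
      pair_id = character(0), noninvasive_id = character(0),
      invasive_ids = character(0), relatedness_rank = character(0),
      continent = character(0), ldt_noninv = numeric(0),
      ldt_inv = numeric(0), set_noninv = numeric(0), set_inv = numeric(0),
      d_ldt = numeric(0), d_set = numeric(0), stringsAsFactors = FALSE
    )
  } else {
    pairs <- cbind(pair_id = sprintf("pair_%03d", seq_len(nrow(pairs))),
                   pairs, stringsAsFactors = FALSE)
    pairs$d_ldt <- pairs$ldt_inv - pairs$ldt_noninv
    pairs$d_set <- pairs$set_inv - pairs$set_noninv
    rownames(pairs) <- NULL
  }

  reuse <- table(unlist(strsplit(pairs$invasive_ids, ";", fixed = TRUE)))
  attr(pairs, "log") <- list(
    excluded_flagged = records$species_id[flagged],
    excluded_no_ldt = records$species_id[no_ldt & !flagged],
    unmatched_noninvasive = unmatched,
    invasive_reuse = reuse[reuse > 1],
    rank_tally = table(pairs$relatedness_rank)
  )
  pairs
}

#' Per-pair trait differences
#'
#' Differences are invasive minus non-invasive. `d_set` is `NA` where either
#' member lacks a SET value, which is what yields the smaller SET sample in
#' mixed pair sets.
#'
#' @param pairs pair table from [match_pairs()].
#' @return data frame with `pair_id`, `d_ldt`, `d_set`.
#' @export
pair_differences <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0)
  data.frame(pair_id = pairs$pair_id,
             d_ldt = pairs$ldt_inv - pairs$ldt_noninv,
             d_set = pairs$set_inv - pairs$set_noninv,
             stringsAsFactors = FALSE)
}

#' Reshape a pair table to one row per species
#'
#' Long format used by the mixed-model analyses: two rows per pair, one per
#' invasive status, carrying the pair identifier.
#'
#' @param pairs pair table from [match_pairs()] or
#'   [generate_pair_dataset()]`$pairs`.
#' @param trait `"ldt"` or `"set"`.
#' @return data frame with `pair_id`, `status` (factor, levels
#'   `noninvasive`, `invasive`), `value`; pairs with a missing value for the
#'   chosen trait are dropped.
#' @export
pairs_to_long <- function(pairs, trait = c("ldt", "set")) {
  trait <- match.arg(trait)
  cols <- paste0(trait, c("_noninv", "_inv"))
  stopifnot(all(cols %in% names(pairs)))
  ok <- is.finite(pairs[[cols[1]]]) & is.finite(pairs[[cols[2]]])
  p <- pairs[ok, , drop = FALSE]
  out <- data.frame(
    pair_id = rep(p$pair_id, 2L),
    status = factor(rep(c("noninvasive", "invasive"), each = nrow(p)),
                    levels = c("noninvasive", "invasive")),
    value = c(p[[cols[1]]], p[[cols[2]]]),
    stringsAsFactors = FALSE
  )
  if (all(c("order_taxon", "family_taxon") %in% names(p))) {
    out$order_taxon <- rep(p$order_taxon, 2L)
    out$family_taxon <- rep(p$family_taxon, 2L)
  }
  out
}
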