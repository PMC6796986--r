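#' Per-exon, per-mode targetability records
#'
#' Condenses a scored candidate table (both editor modes) into one record per
#' inner exon: for each mode, the best predicted efficiency among guides
#' passing the off-target cap, the best (lowest) off-target score among
#' guides passing the efficiency floor, and whether the exon is targetable
#' under both active thresholds ("targetable" = at least one guide with
#' efficiency strictly above `eff_floor` and off-target score at most
#' `ot_cap`).
#'
#' @param candidates Scored candidate table covering one or both modes (rows
#'   from [score_guides()], `mode` column in `{"ABE","BE3"}`).
#' @param ot_cap Off-target score cap (inclusive, default 10).
#' @param eff_floor Efficiency floor in percent (strict, default 30).
#' @return A data.frame with one row per exon_key and columns
#'   `abe_best_efficiency`, `abe_best_offtarget`, `abe_targetable`,
#'   `be3_best_efficiency`, `be3_best_offtarget`, `be3_targetable`.
#'   Best values are `NA` when no guide of that mode passes the respective
#'   other-axis filter.
#' @export
targetability_records <- function(candidates, ot_cap = 10, eff_floor = 30) {
  if (any(is.na(candidates$offtarget_score))) {
    stop("candidates must be scored before building targetability records")
  }
  keys <- sort(unique(candidates$exon_key))
  if (length(keys) == 0L) {
    return(data.frame(exon_key = character(0),
                      abe_best_efficiency = numeric(0), abe_best_offtarget = numeric(0),
                      abe_targetable = logical(0),
                      be3_best_efficiency = numeric(0), be3_best_offtarget = numeric(0),
                      be3_targetable = logical(0), stringsAsFactors = FALSE))
  }
  one_mode <- function(sub) {
    pass_ot <- sub[sub$offtarget_score <= ot_cap, , drop = FALSE]
    pass_eff <- sub[sub$predicted_efficiency > eff_floor, , drop = FALSE]
    list(
      best_eff = if (nrow(pass_ot)) max(pass_ot$predicted_efficiency) else NA_real_,
      best_ot = if (nrow(pass_eff)) min(pass_eff$offtarget_score) else NA_real_,
      targetable = any(sub$predicted_efficiency > eff_floor &
                         sub$offtarget_score <= ot_cap)
    )
  }
  rows <- lapply(keys, function(k) {
    abe <- one_mode(candidates[candidates$exon_key == k & candidates$mode == "ABE", , drop = FALSE])
    be3 <- one_mode(candidates[candidates$exon_key == k & candidates$mode == "BE3", , drop = FALSE])
    data.frame(
      exon_key = k,
      abe_best_efficiency = abe$best_eff, abe_best_offtarget = abe$best_ot,
      abe_targetable = abe$targetable,
      be3_best_efficiency = be3$best_eff, be3_best_offtarget = be3$best_ot,
      be3_targetable = be3$targetable,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative exon counts versus efficiency threshold
#'
#' For each efficiency threshold `t` on the grid, counts the inner exons with
#' at least one guide of predicted efficiency `>= t` among guides passing the
#' off-target cap used to build the records. The curve is non-increasing
#' in `t`.
#'
#' @param records Table from [targetability_records()].
#' @param grid Numeric vector of efficiency thresholds (default 0-100 step 1).
#' @return Data.frame `threshold`, `abe_count`, `be3_count`.
#' @export
cumulative_by_efficiency <- function(records, grid = 0:100) {
  data.frame(
    threshold = grid,
    abe_count = vapply(grid, function(t) {
      sum(!is.na(records$abe_best_efficiency) & records$abe_best_efficiency >= t)
    }, integer(1)),
    be3_count = vapply(grid, function(t) {
      sum(!is.na(records$be3_best_efficiency) & records$be3_best_efficiency >= t)
    }, integer(1))
  )
}

#' Cumulative exon counts versus off-target threshold
#'
#' For each off-target threshold `x` on the grid, counts the inner exons with
#' at least one guide of off-target score `<= x` among guides passing the
#' efficiency floor used to build the records. The curve is non-decreasing
#' in `x`.
#'
#' @param records Table from [targetability_records()].
#' @param grid Numeric vector of score thresholds (default 0-20 step 0.5).
#' @return Data.frame `threshold`, `abe_count`, `be3_count`.
#' @export
cumulative_by_offtarget <- function(records, grid = seq(0, 20, by = 0.5)) {
  data.frame(
    threshold = grid,
    abe_count = vapply(grid, function(x) {
      sum(!is.na(records$abe_best_offtarget) & records$abe_best_offtarget <= x)
    }, integer(1)),
    be3_count = vapply(grid, function(x) {
      sum(!is.na(records$be3_best_offtarget) & records$be3_best_offtarget <= x)
    }, integer(1))
  )
}

#' ABE-versus-BE3 overlap report
#'
#' Among exons targetable by both editors under the active thresholds, counts
#' how often ABE's best guide has strictly higher predicted efficiency than
#' BE3's, and strictly lower off-target score. Ties are reported in separate
#' buckets rather than assigned to either side, so
#' `abe_higher_eff + be3_higher_eff + eff_ties = both` (and likewise for the
#' off-target comparison).
#'
#' @param records Table from [targetability_records()].
#' @return List with counts `both`, `abe_only`, `be3_only`, `abe_higher_eff`,
#'   `be3_higher_eff`, `eff_ties`, `abe_lower_ot`, `be3_lower_ot`, `ot_ties`
#'   and the fractions `abe_higher_eff_frac`, `abe_lower_ot_frac` (of `both`;
#'   `NA` when `both` is 0).
#' @export
overlap_report <- function(records) {
  both <- records[records$abe_targetable & records$be3_targetable, , drop = FALSE]
  n_both <- nrow(both)
  abe_higher <- sum(both$abe_best_efficiency > both$be3_best_efficiency)
  be3_higher <- sum(both$be3_best_efficiency > both$abe_best_efficiency)
  abe_lower <- sum(both$abe_best_offtarget < both$be3_best_offtarget)
  be3_lower <- sum(both$be3_best_offtarget < both$abe_best_offtarget)
  list(
    both = n_both,
    abe_only = sum(records$abe_targetable & !records$be3_targetable),
    be3_only = sum(records$be3_targetable & !records$abe_targetable),
    abe_higher_eff = abe_higher, be3_higher_eff = be3_higher,
    eff_ties = n_both - abe_higher - be3_higher,
    abe_lower_ot = abe_lower, be3_lower_ot = be3_lower,
    ot_ties = n_both - abe_lower - be3_lower,
    abe_higher_eff_frac = if (n_both > 0) abe_higher / n_both else NA_real_,
    abe_lower_ot_frac = if (n_both > 0) abe_lower / n_both else NA_real_
  )
}
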