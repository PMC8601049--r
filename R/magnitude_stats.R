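#' Magnitude summary table (measure x behavior)
#'
#' Sample mean and SD (n - 1 denominator) of the per-cycle deformation
#' magnitude delta, maximum and minimum, per measure and behavior — the
#' shape of a published chew-vs-drink magnitude table. By linearity,
#' `mean(delta) = mean(max) - mean(min)` holds exactly in every row.
#' Empty groups are emitted with n = 0 and `NA` statistics; SD is `NA`
#' when n < 2.
#'
#' @param summaries a `cycle_summary` (possibly several behaviors).
#' @return data.frame with columns `measure`, `behavior`, `n`,
#'   `delta_mean`, `delta_sd`, `max_mean`, `max_sd`, `min_mean`,
#'   `min_sd`, in deterministic row order (total, R1..R5, W1..W4 by
#'   behavior).
#' @export
summarize_magnitudes <- function(summaries) {
  empty <- data.frame(measure = character(0), behavior = character(0),
                      n = integer(0), delta_mean = numeric(0),
                      delta_sd = numeric(0), max_mean = numeric(0),
                      max_sd = numeric(0), min_mean = numeric(0),
                      min_sd = numeric(0))
  behaviors <- sort(unique(as.character(summaries$behavior)))
  if (!length(behaviors)) return(empty)
  grid <- expand.grid(behavior = behaviors, measure = measure_levels(),
                      stringsAsFactors = FALSE)[, c("measure", "behavior")]
  grid <- grid[order(match(grid$measure, measure_levels()), grid$behavior), ]
  stat_row <- function(m, b) {
    s <- summaries[summaries$measure == m & summaries$behavior == b, ]
    n <- nrow(s)
    sd_or_na <- function(v) if (n >= 2) stats::sd(v) else NA_real_
    data.frame(measure = m, behavior = b, n = n,
               delta_mean = if (n) mean(s$delta) else NA_real_,
               delta_sd = if (n) sd_or_na(s$delta) else NA_real_,
               max_mean = if (n) mean(s$max_norm) else NA_real_,
               max_sd = if (n) sd_or_na(s$max_norm) else NA_real_,
               min_mean = if (n) mean(s$min_norm) else NA_real_,
               min_sd = if (n) sd_or_na(s$min_norm) else NA_real_)
  }
  out <- do.call(rbind, Map(stat_row, grid$measure, grid$behavior))
  rownames(out) <- NULL
  out
}

#' Stratified permutation comparison of deformation magnitudes
#'
#' Two-sided test of the difference in group means of the per-cycle
#' delta between behaviors, with behavior labels shuffled within strata
#' (individuals) only. This is the package's documented replacement for
#' a linear mixed-effects model with individual as random effect: the
#' statistic is the plain mean difference, the stratified shuffle
#' respects the repeated-measures structure, and direction is reported
#' via the sign of the observed difference.
#'
#' @param values_a,values_b numeric vectors (per-cycle deltas of one
#'   measure, group A and B).
#' @param strata_a,strata_b stratum labels; `NULL` for a single stratum.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `observed` (mean difference A - B), `p_value`
#'   (two-sided, add-one estimator), `n_perm`, `seed`, group sizes.
#' @export
compare_magnitudes <- function(values_a, values_b,
                               strata_a = NULL, strata_b = NULL,
                               n_perm = 999, seed = 1) {
  if (!length(values_a) || !length(values_b))
    stop("input error: both groups must be nonempty")
  stat <- function(a, b) mean(a) - mean(b)
  stratified_permutation(values_a, values_b, strata_a, strata_b,
                         stat, n_perm, seed, larger_is_extreme = FALSE)
}
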