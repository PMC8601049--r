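# Standardized cycle time lives on a circle of circumference 100%:
# 0% and 100% are the same instant (maximum gape). All circular math is
# done in radians with the fixed mapping 1% = 3.6 degrees.

pct_to_rad <- function(p) p * (2 * pi / 100)
rad_to_pct <- function(r) (r * (100 / (2 * pi))) %% 100

#' Circular mean of standardized cycle times
#'
#' Direction of the mean resultant vector of unit vectors at the sample
#' angles, mapped back to percent of cycle. Two events at 5% and 95% of
#' the cycle average to 0% (both near maximum gape), not to the
#' misleading linear mean of 50%. When the resultant length is below
#' `tol` the mean direction is undefined and `NA` is returned with a
#' warning, never 0%.
#'
#' @param values numeric vector of percents in `[0, 100)`.
#' @param tol resultant-length tolerance below which the mean is
#'   undefined.
#' @return circular mean in `[0, 100)`, or `NA` when undefined.
#' @export
circ_mean <- function(values, tol = 1e-9) {
  if (!length(values)) stop("input error: empty circular sample")
  if (any(values < 0 | values >= 100))
    stop("standardized times must lie in [0, 100)")
  th <- pct_to_rad(values)
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  if (R < tol) {
    warning("circular mean undefined: resultant length ~ 0")
    return(NA_real_)
  }
  rad_to_pct(atan2(S, C))
}

#' Circular distance between two standardized times
#'
#' Minimal separation on the 100%-circumference circle:
#' `min(|a - b|, 100 - |a - b|)`, in `[0, 50]`. Events at 5% and 95% of
#' the cycle are 10% apart, not 90%.
#'
#' @param a,b percents in `[0, 100)` (vectorized).
#' @return circular distance in percent of cycle, in `[0, 50]`.
#' @export
circ_distance <- function(a, b) {
  if (any(c(a, b) < 0 | c(a, b) >= 100))
    stop("standardized times must lie in [0, 100)")
  d <- abs(a - b)
  pmin(d, 100 - d)
}

#' Circular descriptive statistics
#'
#' Mean direction, mean resultant length R, circular variance (1 - R)
#' and circular SD (`sqrt(-2 log R)`, mapped to percent of cycle) of a
#' sample of standardized times.
#'
#' @inheritParams circ_mean
#' @return object of class `circ_summary`: list with `circ_mean`
#'   (percent or NA), `R`, `variance`, `circ_sd` (percent), `n`,
#'   `undefined`.
#' @export
circ_dispersion <- function(values, tol = 1e-9) {
  if (!length(values)) stop("input error: empty circular sample")
  if (any(values < 0 | values >= 100))
    stop("standardized times must lie in [0, 100)")
  th <- pct_to_rad(values)
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- min(sqrt(C^2 + S^2), 1)
  undefined <- R < tol
  structure(list(
    circ_mean = if (undefined) NA_real_ else rad_to_pct(atan2(S, C)),
    R = R,
    variance = 1 - R,
    circ_sd = if (R > 0) sqrt(-2 * log(R)) * (100 / (2 * pi)) else Inf,
    n = length(values),
    undefined = undefined), class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("circular summary (n=%d): mean %s%%, R=%.3f, var=%.3f, SD=%s%%\n",
              x$n,
              if (x$undefined) "undefined" else sprintf("%.2f", x$circ_mean),
              x$R, x$variance,
              if (is.finite(x$circ_sd)) sprintf("%.2f", x$circ_sd) else "Inf"))
  invisible(x)
}

# shared engine: permute group labels within strata, recompute a
# two-sample statistic, and return the add-one permutation p-value
stratified_permutation <- function(values_a, values_b, strata_a, strata_b,
                                   stat_fn, n_perm, seed,
                                   larger_is_extreme = TRUE) {
  strata_a <- strata_a %||% rep("all", length(values_a))
  strata_b <- strata_b %||% rep("all", length(values_b))
  stopifnot(length(strata_a) == length(values_a),
            length(strata_b) == length(values_b))
  vals <- c(values_a, values_b)
  grp <- rep(c("A", "B"), c(length(values_a), length(values_b)))
  str <- c(as.character(strata_a), as.character(strata_b))
  # a stratum with only one group contributes nothing to a label shuffle
  keep_strata <- names(which(vapply(split(grp, str),
                                    function(g) length(unique(g)) > 1,
                                    logical(1))))
  dropped <- setdiff(unique(str), keep_strata)
  if (length(dropped)) {
    warning("strata with a single behavior excluded: ",
            paste(dropped, collapse = ", "))
    keep <- str %in% keep_strata
    vals <- vals[keep]; grp <- grp[keep]; str <- str[keep]
  }
  if (!any(grp == "A") || !any(grp == "B"))
    stop("input error: both groups must be nonempty after stratum exclusion")
  observed <- stat_fn(vals[grp == "A"], vals[grp == "B"])
  idx_by_stratum <- split(seq_along(vals), str)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- grp
      for (idx in idx_by_stratum) g[idx] <- sample(g[idx])
      stat_fn(vals[g == "A"], vals[g == "B"])
    }, numeric(1))
  })
  extreme <- if (larger_is_extreme) perm_stats >= observed
             else abs(perm_stats) >= abs(observed)
  # undefined permuted statistics (e.g. a zero resultant) count as extreme
  extreme[is.na(extreme)] <- TRUE
  list(observed = observed,
       p_value = (1 + sum(extreme)) / (1 + n_perm),
       n_perm = n_perm, seed = seed,
       n_a = sum(grp == "A"), n_b = sum(grp == "B"),
       excluded_strata = dropped)
}

#' Stratified permutation test for circular timing differences
#'
#' Compares the circular means of two samples of standardized times
#' (e.g. chew vs drink timings of a deformation extremum). The test
#' statistic is the circular distance between the group circular means;
#' the null distribution is built by shuffling behavior labels within
#' strata (individuals) only, respecting the repeated-measures
#' structure. This is the package's documented replacement for a
#' circular mixed-effects model: it asks the same scientific question
#' (do the behaviors differ in timing, with individual as stratum)
#' without a parametric circular likelihood.
#'
#' @param sample_a,sample_b numeric vectors of percents in `[0, 100)`.
#' @param strata_a,strata_b stratum labels (e.g. individual ids), same
#'   lengths as the samples; `NULL` for a single stratum.
#' @param n_perm number of permutations.
#' @param seed integer seed (the test is bit-reproducible given it).
#' @return list with `observed` (circular distance between group means,
#'   percent), `p_value` (add-one estimator
#'   `(1 + #extreme) / (1 + n_perm)`), `n_perm`, `seed`, group sizes,
#'   and any excluded strata.
#' @export
circ_permutation_test <- function(sample_a, sample_b,
                                  strata_a = NULL, strata_b = NULL,
                                  n_perm = 999, seed = 1) {
  if (!length(sample_a) || !length(sample_b))
    stop("input error: both samples must be nonempty")
  stat <- function(a, b) {
    ma <- suppressWarnings(circ_mean(a))
    mb <- suppressWarnings(circ_mean(b))
    if (is.na(ma) || is.na(mb)) return(NA_real_)
    circ_distance(ma, mb)
  }
  stratified_permutation(sample_a, sample_b, strata_a, strata_b,
                         stat, n_perm, seed, larger_is_extreme = TRUE)
}
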