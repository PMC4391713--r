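#' Flow-vs-in-situ recovery comparison
#'
#' Quantifies how much of the in-situ (IHC-derived) cell density a
#' flow-cytometric yield recovers: recovery = 100 x flow / IHC and deficit
#' = 100 - recovery. A recovery above 100% is physically suspect and is
#' flagged rather than rejected.
#'
#' @param flow_density Flow-derived density, cells/mm^3 (vectorised).
#' @param ihc_density In-situ density for the same marker and site,
#'   cells/mm^3.
#' @param marker Optional marker label(s) carried into the output.
#' @return A tibble with `marker`, `ihc_density`, `flow_density`,
#'   `recovery_percent`, `deficit_percent` (one decimal is the reporting
#'   convention; raw values are returned) and `flagged`.
#' @examples
#' compare_recovery(2708, 15000)   # deficit 81.9%
#' @export
compare_recovery <- function(flow_density, ihc_density, marker = NA_character_) {
  if (any(ihc_density <= 0)) {
    abort_input("`ihc_density` must be positive to define a recovery.")
  }
  rec <- 100 * flow_density / ihc_density
  tibble(
    marker = marker,
    ihc_density = ihc_density,
    flow_density = flow_density,
    recovery_percent = rec,
    deficit_percent = 100 - rec,
    flagged = rec > 100
  )
}

#' Ordinary-least-squares concordance of two counting methods
#'
#' Regresses automated counts on manual counts for the same regions and
#' summarises agreement by the fitted slope, intercept and r^2 (squared
#' Pearson correlation). Perfect concordance is slope 1, intercept 0,
#' r^2 1.
#'
#' @param data Optional data frame containing the two columns.
#' @param manual,automated Numeric vectors, or (if `data` is supplied)
#'   unquoted column names.
#' @return A `concordance_fit` object with elements `slope`, `intercept`,
#'   `r_squared`, `n_pairs` and the underlying `lm` fit; has [tidy()],
#'   [glance()] and [ggplot2::autoplot()] methods.
#' @examples
#' fit <- ols_concordance(manual = c(10, 14, 9, 11),
#'                        automated = c(12, 15, 9, 14))
#' glance(fit)
#' @export
ols_concordance <- function(data = NULL, manual, automated) {
  if (!is.null(data)) {
    manual <- eval_tidy(enquo(manual), data)
    automated <- eval_tidy(enquo(automated), data)
  }
  n <- length(manual)
  if (n != length(automated)) abort_input("Paired vectors must have equal length.")
  if (n < 3) abort_input("At least 3 pairs are required for a regression.")
  if (sd(manual) == 0) {
    abort_input("Manual counts have zero variance; the slope is undefined.")
  }
  fit <- lm(automated ~ manual, data = tibble(manual = manual,
                                              automated = automated))
  structure(
    list(fit = fit,
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = unname(summary(fit)$r.squared),
         n_pairs = n),
    class = "concordance_fit"
  )
}

#' @export
print.concordance_fit <- function(x, ...) {
  cat(sprintf(
    "Concordance fit (n = %d pairs): slope %.3f, intercept %.3g, r^2 %.3f\n",
    x$n_pairs, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @rdname ols_concordance
#' @param x A `concordance_fit`.
#' @param ... Unused.
#' @export
tidy.concordance_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname ols_concordance
#' @export
glance.concordance_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope,
         intercept = x$intercept, nobs = x$n_pairs)
}

#' Paired t test on manual vs automated counts
#'
#' Two-sided paired t test on the per-region differences, with explicit
#' conventions for the degenerate cases: identical vectors give t = 0,
#' p = 1; constant non-zero differences (zero variance, non-zero mean)
#' give an infinite statistic, p reported as 0 and flagged.
#'
#' @param manual,automated Paired numeric vectors (n >= 2).
#' @return A one-row tibble: `t_stat`, `df`, `p_value`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_t <- function(manual, automated) {
  if (length(manual) != length(automated)) {
    abort_input("Paired vectors must have equal length.")
  }
  n <- length(manual)
  if (n < 2) abort_input("At least 2 pairs are required.")
  d <- automated - manual
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble(t_stat = 0, df = n - 1, p_value = 1,
                    mean_diff = 0, degenerate = TRUE))
    }
    return(tibble(t_stat = sign(mean(d)) * Inf, df = n - 1, p_value = 0,
                  mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(automated, manual, paired = TRUE)
  tibble(t_stat = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_diff = unname(tt$estimate),
         degenerate = FALSE)
}

#' Mann-Whitney rank-sum comparison of two groups
#'
#' Wilcoxon rank-sum (Mann-Whitney) test: exact two-sided p (doubled
#' one-sided tail, capped at 1) when the combined sample is small (<= 20)
#' and untied, otherwise the normal approximation with mid-rank tie
#' correction.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param exact_max Combined sample size up to which the exact distribution
#'   is used. Default 20.
#' @return A one-row tibble: `u_stat` (U of `group_a`), `p_value`,
#'   `exact`.
#' @examples
#' mann_whitney(1:5, 11:15)  # complete separation: U = 0, p = 0.0079
#' @export
mann_whitney <- function(group_a, group_b, exact_max = 20) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort_input("Both groups must be non-empty.")
  }
  n_tot <- length(group_a) + length(group_b)
  tied <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- n_tot <= exact_max && !tied
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = use_exact, correct = TRUE)
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1 # fully tied groups carry no evidence either way
  tibble(u_stat = unname(wt$statistic), p_value = min(p, 1),
         exact = use_exact)
}
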