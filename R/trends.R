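# Replicate-level trend statistics: single linear regressions of each
# response (compound abundance, class total, index) on temperature or pH,
# Spearman rank correlations, one-way ANOVA with Tukey post-hoc comparisons,
# and inversion of a fitted calibration line.

#' Ordinary least-squares trend of a response on a condition
#'
#' Fits `y ~ x` on replicate-level points (e.g. 5 temperatures x 3
#' replicates = 15 points). Pairs with a missing value are dropped. A
#' constant response yields `r_squared = 0`, `p_value = 1` (no evidence of a
#' trend); a constant condition is a precondition error. The p-value is the
#' standard two-sided test of zero slope on n - 2 degrees of freedom.
#'
#' @param x Numeric condition values (>= 2 distinct after NA removal).
#' @param y Numeric response values; >= 3 complete pairs required.
#' @param response_id Optional label stored in the result.
#' @param alpha Significance threshold (default 0.05).
#' @return An object of class `trend_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n_points`, `significant`, plus standard
#'   errors, the coefficient covariance matrix and residual sd needed for
#'   inverse prediction.
#' @export
fit_linear_trend <- function(x, y, response_id = "y", alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete (x, y) pairs", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("condition values are constant; a trend cannot be fit",
         call. = FALSE)
  }
  out <- list(response_id = response_id, n_points = n, alpha = alpha)
  if (stats::var(y) == 0) {
    out$slope <- 0
    out$intercept <- y[1L]
    out$r_squared <- 0
    out$p_value <- 1
    out$slope_se <- 0
    out$intercept_se <- 0
    out$sigma <- 0
    out$vcov <- matrix(0, 2, 2,
                       dimnames = list(c("(Intercept)", "x"),
                                       c("(Intercept)", "x")))
  } else {
    fit <- stats::lm(y ~ x)
    # a perfectly collinear response is a legitimate input here (zero-noise
    # simulations); silence summary.lm's "essentially perfect fit" warning
    sm <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    cf <- stats::coef(sm)
    out$slope <- cf["x", "Estimate"]
    out$intercept <- cf["(Intercept)", "Estimate"]
    out$r_squared <- sm$r.squared
    out$p_value <- cf["x", "Pr(>|t|)"]
    out$slope_se <- cf["x", "Std. Error"]
    out$intercept_se <- cf["(Intercept)", "Std. Error"]
    out$sigma <- sm$sigma
    out$vcov <- sm$cov.unscaled * sm$sigma^2
  }
  out$significant <- is.finite(out$p_value) && out$p_value < alpha
  class(out) <- "trend_fit"
  out
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> %s: slope %.4g, intercept %.4g, R^2 %.3f, p %.3g (n = %d)%s\n",
    x$response_id, x$slope, x$intercept, x$r_squared, x$p_value, x$n_points,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' standard t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' n - 2 degrees of freedom (two-sided). Constant input has no defined rank
#' correlation and is reported as missing.
#'
#' @param x,y Numeric vectors; >= 3 complete pairs required.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Tests for differences in a response across condition levels and reports
#' all pairwise level comparisons with Tukey-adjusted p-values (studentized
#' range distribution, pooled within-group variance). With zero within-group
#' variance everywhere the F statistic is undefined and the result is
#' flagged degenerate.
#'
#' @param values Numeric response values.
#' @param groups Factor (or coercible) of condition levels; >= 2 groups with
#'   >= 2 values each.
#' @param alpha Significance threshold for the comparison table.
#' @return List with `f_statistic`, `p_value`, `df` (numerator,
#'   denominator), `comparisons` (data frame: `level_a`, `level_b`, `diff`,
#'   `p_adj`, `significant`) and `degenerate`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group needs >= 2 values", call. = FALSE)
  }
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0)) {
    return(list(f_statistic = NA_real_, p_value = NA_real_,
                df = c(nlevels(groups) - 1L,
                       length(values) - nlevels(groups)),
                comparisons = data.frame(level_a = character(0),
                                         level_b = character(0),
                                         diff = numeric(0),
                                         p_adj = numeric(0),
                                         significant = logical(0)),
                degenerate = TRUE))
  }
  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  comparisons <- data.frame(
    level_a = vapply(pair, `[`, character(1), 1L),
    level_b = vapply(pair, `[`, character(1), 2L),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    row.names = NULL
  )
  list(f_statistic = sm[["F value"]][1L],
       p_value = sm[["Pr(>F)"]][1L],
       df = c(sm[["Df"]][1L], sm[["Df"]][2L]),
       comparisons = comparisons,
       degenerate = FALSE)
}

# Replicate-level response matrix of a series: one row per profile, one
# column per response (compound relative abundances, class totals, indices).
series_response_matrix <- function(series, carbon_range = c(10, 18),
                                   undetected_as = NA_real_) {
  prs <- series$profiles
  keys <- unique(unlist(lapply(prs, function(p) p$measurements$fa_key)))
  rows <- lapply(prs, function(p) {
    m <- p$measurements
    ab <- m$value[match(keys, m$fa_key)]
    ab[is.na(ab)] <- undetected_as
    names(ab) <- keys
    idx <- index_set(p, carbon_range = carbon_range)
    c(ab, unlist(idx[1, fa_index_names]))
  })
  mat <- do.call(rbind, rows)
  data.frame(
    condition_value = vapply(prs, function(p) p$condition_value, numeric(1)),
    replicate_id = vapply(prs, function(p) p$replicate_id, character(1)),
    mat, check.names = FALSE
  )
}

#' Trend report for an experiment series
#'
#' Fits [fit_linear_trend()] of every response -- each compound's relative
#' abundance, the three class totals and every index -- against the series'
#' condition, on replicate-level points. Responses undefined in more than
#' `max_missing` of the replicates are skipped with a warning (e.g. a RAN15
#' that is undefined because normal-C15 is never detected). Undefined values
#' in retained responses are dropped pairwise.
#'
#' @param series An [experiment_series()] on the `"total_3OH_FAs"` basis.
#' @param alpha Significance threshold (default 0.05).
#' @param carbon_range Index scope (default C10--C18).
#' @param max_missing Fraction of replicates allowed to be missing before a
#'   response is skipped (default 0.5).
#' @return Data frame: `response`, `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`, `significant`.
#' @export
trend_report <- function(series, alpha = 0.05, carbon_range = c(10, 18),
                         max_missing = 0.5) {
  stopifnot(inherits(series, "experiment_series"))
  rm_ <- series_response_matrix(series, carbon_range = carbon_range)
  x <- rm_$condition_value
  resp_cols <- setdiff(names(rm_), c("condition_value", "replicate_id"))
  out <- lapply(resp_cols, function(nm) {
    y <- rm_[[nm]]
    n_missing <- sum(!is.finite(y))
    if (n_missing > max_missing * length(y)) {
      warning("response '", nm, "' undefined in ", n_missing, "/", length(y),
              " replicates; skipped", call. = FALSE)
      return(NULL)
    }
    ft <- fit_linear_trend(x, y, response_id = nm, alpha = alpha)
    data.frame(response = nm, slope = ft$slope, intercept = ft$intercept,
               r_squared = ft$r_squared, p_value = ft$p_value,
               n = ft$n_points, significant = ft$significant)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Invert a fitted calibration line
#'
#' Inverse prediction: given a fitted trend `y = intercept + slope * x` and
#' an observed index value `y0`, estimates the condition
#' `x_hat = (y0 - intercept) / slope` with a first-order (delta-method)
#' confidence interval propagating the slope/intercept covariance. Refuses
#' to invert a non-significant fit: a slope indistinguishable from zero has
#' no usable inverse.
#'
#' @param fit A [fit_linear_trend()] result with `significant = TRUE`.
#' @param y0 Observed response (index) value.
#' @param level Confidence level for the interval (default 0.95).
#' @return List with `x_hat`, `se`, `lower`, `upper`, `level`.
#' @export
invert_calibration <- function(fit, y0, level = 0.95) {
  stopifnot(inherits(fit, "trend_fit"))
  if (!isTRUE(fit$significant)) {
    stop("calibration fit is not significant at alpha = ", fit$alpha,
         " (p = ", signif(fit$p_value, 3),
         "); refusing inverse prediction from a slope indistinguishable ",
         "from zero", call. = FALSE)
  }
  if (fit$slope == 0) stop("slope is zero; cannot invert", call. = FALSE)
  x_hat <- (y0 - fit$intercept) / fit$slope
  # gradient of x_hat wrt (intercept, slope): (-1/b1, -x_hat/b1)
  g <- c(-1 / fit$slope, -x_hat / fit$slope)
  v <- as.numeric(t(g) %*% fit$vcov %*% g)
  se <- sqrt(max(v, 0))
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$n_points - 2L)
  list(x_hat = x_hat, se = se,
       lower = x_hat - tq * se, upper = x_hat + tq * se,
       level = level)
}
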