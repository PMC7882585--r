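#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Two-sided rank-sum test reporting the U statistic for the first sample,
#' the signed z value from the normal approximation (always tie-corrected,
#' continuity correction on by default), and the p-value. Swapping the
#' samples flips the sign of z but leaves p unchanged.
#'
#' @param x,y Numeric samples (each at least one value).
#' @param correction `"continuity"` (default) or `"none"`.
#' @return A one-row tibble: `U`, `z`, `p_value`, `n_x`, `n_y`.
#' @export
mann_whitney <- function(x, y, correction = c("continuity", "none")) {
  correction <- match.arg(correction)
  if (length(x) < 1 || length(y) < 1) abort("Both samples need at least one value.")
  if (anyNA(x) || anyNA(y)) abort("Samples must not contain NA.")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    warn("All values tied across both samples; p = 1.")
    return(tibble(U = U, z = 0, p_value = 1, n_x = n1, n_y = n2))
  }
  cc <- if (correction == "continuity") sign(U - mu) * 0.5 else 0
  z <- (U - mu - cc) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  tibble(U = U, z = z, p_value = min(1, p), n_x = n1, n_y = n2)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of a vector of p-values, with the usual monotonicity
#' enforcement and capping at 1 (delegates to [stats::p.adjust()] after
#' validating the input range). Missing values are propagated.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  pv <- pvalues[!is.na(pvalues)]
  if (any(pv < 0 | pv > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(pvalues, method = "BH")
}

#' Screen environmental variables between two groups
#'
#' Per-variable two-group comparison: group means and SDs, Mann-Whitney U,
#' signed z, raw p, and the table-wise Benjamini-Hochberg q, with a
#' significance flag at `q < 0.05`. Intended as a descriptive screen of
#' which covariates differ between fragments, not as confirmatory tests.
#'
#' @param env A data frame with `site_id`, numeric variables, and a group
#'   column.
#' @param group Name of the grouping column (default `"group"`); must have
#'   exactly two levels.
#' @param variables Optional subset of variables to screen.
#' @return A tibble of class `screening_table`, one row per variable:
#'   `variable`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `U`, `z`, `p_value`,
#'   `q_value`, `significant`.
#' @export
screen_variables <- function(env, group = "group", variables = NULL) {
  env <- as_tibble(env)
  if (!group %in% names(env)) abort(paste0("No grouping column `", group, "`."))
  g <- as.character(env[[group]])
  lev <- sort(unique(g))
  if (length(lev) != 2) abort("Screening needs exactly two groups.")
  variables <- variables %||%
    setdiff(names(env)[vapply(env, is.numeric, logical(1))], c("site_id", group))
  rows <- lapply(variables, function(v) {
    xa <- env[[v]][g == lev[1]]
    xb <- env[[v]][g == lev[2]]
    mw <- mann_whitney(xa, xb)
    tibble(variable = v,
           mean_a = mean(xa), sd_a = sd(xa),
           mean_b = mean(xb), sd_b = sd(xb),
           U = mw$U, z = mw$z, p_value = mw$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < 0.05
  class(out) <- c("screening_table", class(out))
  attr(out, "groups") <- lev
  out
}

#' Stepwise AIC model selection for standardised beta deviation
#'
#' Fits an ordinary least-squares model of a per-site response (typically
#' `beta_dev`) on candidate predictors (typically rotated PC-axis scores),
#' then performs bidirectional stepwise search on the Akaike information
#' criterion starting from the full additive model, stopping at a local
#' AIC optimum. Standardised beta-coefficients (all variables z-scored)
#' are reported alongside the raw coefficients.
#'
#' @param data A data frame holding the response and candidate columns.
#' @param response Name of the response column.
#' @param candidates Character vector of candidate predictor columns.
#' @return An object of class `beta_model`: `selected` (character vector of
#'   retained terms), `coefficients` (tibble: `term`, `estimate`,
#'   `std_beta`, `t_value`, `p_value`), `aic` (final), `aic_full`,
#'   `adj_r_squared`, `anova_trace` (the step path), `model` (the final
#'   `lm`).
#' @export
stepwise_aic <- function(data, response, candidates) {
  data <- as.data.frame(data)
  miss <- setdiff(c(response, candidates), names(data))
  if (length(miss) > 0)
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(data) <= length(candidates) + 2)
    abort("Need more sites than candidate predictors + 2.")
  X <- as.matrix(data[candidates])
  if (qr(cbind(1, X))$rank < length(candidates) + 1) {
    abort(paste0("Rank-deficient candidate design; aliased term(s) among: ",
                 paste(candidates, collapse = ", ")))
  }
  full_formula <- as.formula(paste(response, "~", paste(candidates, collapse = "+")))
  full <- lm(full_formula, data = data)
  step_fit <- MASS::stepAIC(full, direction = "both", trace = 0,
                            scope = list(lower = as.formula(paste(response, "~ 1")),
                                         upper = full_formula))
  sel <- attr(stats::terms(step_fit), "term.labels")
  sm <- summary(step_fit)
  co <- sm$coefficients
  sd_y <- sd(data[[response]])
  std_beta <- vapply(rownames(co), function(tm) {
    if (tm == "(Intercept)") return(NA_real_)
    unname(co[tm, "Estimate"] * sd(data[[tm]]) / sd_y)
  }, numeric(1))
  structure(list(
    selected = sel,
    coefficients = tibble(term = rownames(co),
                          estimate = co[, "Estimate"],
                          std_beta = std_beta,
                          t_value = co[, "t value"],
                          p_value = co[, "Pr(>|t|)"]),
    aic = AIC(step_fit),
    aic_full = AIC(full),
    adj_r_squared = sm$adj.r.squared,
    anova_trace = step_fit$anova,
    model = step_fit
  ), class = "beta_model")
}

#' @export
print.beta_model <- function(x, ...) {
  cat("Stepwise-AIC linear model: ",
      if (length(x$selected) == 0) "(intercept only)" else
        paste(x$selected, collapse = " + "),
      "\nAIC ", round(x$aic, 2), " (full model ", round(x$aic_full, 2),
      "), adjusted R-squared ", round(x$adj_r_squared, 3), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}
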