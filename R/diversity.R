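#' Exponential Shannon diversity (Hill number of order 1)
#'
#' Computes the effective number of species `exp(H)` from an abundance
#' vector, where `H` is Shannon entropy on natural logarithms. With
#' `bias_correction = "chao_shen"`, `H` is replaced by the Chao-Shen
#' coverage-adjusted Horvitz-Thompson estimator, which corrects the downward
#' small-sample bias of the plug-in entropy; corrected estimates may exceed
#' the observed species richness.
#'
#' @param counts Non-negative abundance vector with at least one positive
#'   entry. Integer counts are required for the Chao-Shen correction (it uses
#'   the singleton count).
#' @param bias_correction `"none"` (plug-in) or `"chao_shen"`.
#' @return A single effective-species number. For `"none"` it lies in
#'   `[1, number of observed species]`.
#' @references Chao, A. & Shen, T.-J. (2003) Nonparametric estimation of
#'   Shannon's index of diversity when there are unseen species in sample.
#'   Environmental and Ecological Statistics 10, 429-443.
#' @export
#' @examples
#' hill_shannon(c(5, 5, 5, 5))        # uniform: equals richness, 4
#' hill_shannon(c(4, 2, 1, 1))        # ~3.3636
hill_shannon <- function(counts, bias_correction = c("none", "chao_shen")) {
  bias_correction <- match.arg(bias_correction)
  if (any(!is.finite(counts)) || any(counts < 0))
    abort("`counts` must be finite and non-negative.")
  x <- counts[counts > 0]
  if (length(x) == 0) abort("All-zero abundance vector: diversity undefined.")
  if (bias_correction == "none") {
    p <- x / sum(x)
    return(exp(-sum(p * log(p))))
  }
  if (any(abs(x - round(x)) > 1e-8))
    abort("Chao-Shen correction requires integer counts.")
  n <- sum(x)
  f1 <- sum(x == 1)
  if (f1 == n) f1 <- n - 1  # all-singleton guard: keeps coverage positive
  C <- 1 - f1 / n
  pa <- C * x / n
  # Horvitz-Thompson weighting by the detection probability of each species
  H <- -sum(pa * log(pa) / (1 - (1 - pa)^n))
  exp(H)
}

#' Pooled (gamma) diversity of a site group
#'
#' Sums the abundance columns of all sites in a group and applies
#' [hill_shannon()] with the same bias-correction choice used for the
#' per-site alpha values, giving the regional effective species number.
#'
#' @param cm A [community_matrix()].
#' @param group_label Which group to pool; omit (`NULL`) to pool all sites.
#' @param bias_correction Passed to [hill_shannon()].
#' @return A single effective-species number.
#' @export
gamma_diversity <- function(cm, group_label = NULL,
                            bias_correction = c("none", "chao_shen")) {
  bias_correction <- match.arg(bias_correction)
  m <- unclass(cm)
  if (!is.null(group_label)) {
    g <- site_groups(cm)
    if (is.null(g)) abort("Community matrix has no group labels.")
    if (!group_label %in% g) abort(paste0("Unknown group: ", group_label))
    m <- m[g == group_label, , drop = FALSE]
  }
  hill_shannon(colSums(m), bias_correction = bias_correction)
}

#' Proportional beta-diversity (multiplicative turnover)
#'
#' The proportional species turnover `beta = 1 - alpha/gamma`: the fraction
#' of the regional effective diversity that is absent from a local site.
#' Values near 0 mean the site holds nearly the whole regional pool; values
#' near 1 mean only a small local subset. The value is not clamped: in
#' pathological abundance configurations (bias-corrected alpha exceeding
#' gamma) it can be negative, which is reported with a warning rather than
#' truncated.
#'
#' @param alpha Local effective species number(s), positive.
#' @param gamma Regional effective species number, positive.
#' @return `1 - alpha/gamma`, vectorised over `alpha`.
#' @export
proportional_beta <- function(alpha, gamma) {
  if (any(alpha <= 0) || any(gamma <= 0))
    abort("`alpha` and `gamma` must be positive.")
  beta <- 1 - alpha / gamma
  if (any(beta < 0))
    warn("Negative proportional beta-diversity value(s): alpha exceeds gamma.")
  beta
}
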