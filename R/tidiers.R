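#' @importFrom generics tidy glance
NULL

#' Tidy a PERMANOVA fit
#'
#' @param x A `permanova_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term (the `Residual` and `Total`
#'   rows are kept; their test columns are `NA`).
#' @export
tidy.permanova_fit <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.permanova_fit
#' @export
glance.permanova_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared[1], pseudo_f = x$pseudo_f[1],
         p_value = x$p_value[1], df = x$df[1],
         df_residual = x$df[x$term == "Residual"],
         n_perm = attr(x, "n_perm"))
}

#' Tidy a constrained ordination fit
#'
#' @param x A `cap_fit`.
#' @param ... Unused.
#' @return The per-term tibble (`term`, `df`, `sum_sq`, `explained_pct`,
#'   `pseudo_f`, `p_value`).
#' @export
tidy.cap_fit <- function(x, ...) x$terms

#' @rdname tidy.cap_fit
#' @export
glance.cap_fit <- function(x, ...) {
  tibble(total_inertia = x$total_inertia,
         constrained_fraction = x$constrained_fraction,
         constrained_pct = 100 * x$constrained_fraction,
         n_terms = sum(!x$terms$term %in% c("Residual", "Total")),
         n_perm = x$n_perm)
}

#' Tidy a varimax-rotated PCA
#'
#' @param x A `pca_varimax`.
#' @param ... Unused.
#' @return A long tibble of rotated loadings: `variable`, `axis`,
#'   `loading`, `communality`.
#' @export
tidy.pca_varimax <- function(x, ...) {
  L <- x$loadings
  tibble(variable = rep(rownames(L), ncol(L)),
         axis = rep(colnames(L), each = nrow(L)),
         loading = as.vector(L),
         communality = rep(x$communalities, ncol(L)))
}

#' @rdname tidy.pca_varimax
#' @export
glance.pca_varimax <- function(x, ...) {
  tibble(n_axes = x$n_axes, total_explained = x$total_explained,
         n_variables = length(x$variables))
}

#' Tidy a stepwise-AIC beta-deviation model
#'
#' @param x A `beta_model`.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `std_beta`,
#'   `t_value`, `p_value`).
#' @export
tidy.beta_model <- function(x, ...) x$coefficients

#' @rdname tidy.beta_model
#' @export
glance.beta_model <- function(x, ...) {
  tibble(adj_r_squared = x$adj_r_squared, aic = x$aic, aic_full = x$aic_full,
         n_selected = length(x$selected))
}

#' Summarise a diversity partition by group
#'
#' @param x A `diversity_partition`.
#' @param ... Unused.
#' @return One row per group: mean and SD of alpha, the group gamma, mean
#'   and SD of `beta_obs` and of `beta_dev`.
#' @export
glance.diversity_partition <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(as_tibble(x), .data$group),
                   n_sites = dplyr::n(),
                   mean_alpha = mean(.data$alpha), sd_alpha = sd(.data$alpha),
                   gamma = .data$gamma[1],
                   mean_beta = mean(.data$beta_obs), sd_beta = sd(.data$beta_obs),
                   mean_beta_dev = mean(.data$beta_dev, na.rm = TRUE),
                   sd_beta_dev = sd(.data$beta_dev, na.rm = TRUE),
                   .groups = "drop")
}
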