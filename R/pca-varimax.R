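#' Varimax-rotated principal component condensation
#'
#' Standardises the chosen variables to zero mean and unit variance,
#' eigen-decomposes their correlation matrix, retains the axes with
#' eigenvalue strictly greater than 1 (Kaiser criterion), and applies a
#' normalised varimax rotation to the retained loadings (Kaiser
#' normalisation, convergence 1e-6). Site scores are obtained by the
#' regression method, and a deterministic sign convention is applied: on
#' each rotated axis the variable with the largest absolute loading is
#' made positive, so axis scores are reproducible across runs and
#' platforms. Rotation leaves every variable's communality and the total
#' retained variance unchanged.
#'
#' @param env A data frame with a `site_id` column (or plain numeric data
#'   frame) of site-level variables.
#' @param variables Optional character vector selecting the variable subset
#'   to condense; default all numeric columns except `site_id`/`group`.
#' @param axis_names Optional character vector of interpretive axis labels
#'   (user metadata, never inferred); recycled onto the retained axes.
#' @param min_eigenvalue Retention threshold (strict inequality; default 1,
#'   the Kaiser criterion on a correlation matrix).
#' @return An object of class `pca_varimax`: `loadings` (variables x
#'   retained axes, rotated), `scores` (tibble: `site_id` + one column per
#'   axis), `eigenvalues` (all, unrotated), `explained` (per retained axis,
#'   post-rotation sums of squared loadings / number of variables),
#'   `total_explained`, `communalities`, `n_axes`, `axis_names`.
#' @export
pca_varimax <- function(env, variables = NULL, axis_names = NULL,
                        min_eigenvalue = 1) {
  env <- as_tibble(env)
  ids <- if ("site_id" %in% names(env)) env$site_id else
    paste0("site", seq_len(nrow(env)))
  variables <- variables %||% setdiff(names(env)[vapply(env, is.numeric, logical(1))],
                                      c("site_id", "group"))
  miss <- setdiff(variables, names(env))
  if (length(miss) > 0)
    abort(paste0("Unknown variable(s): ", paste(miss, collapse = ", ")))
  if (length(variables) < 2) abort("Need at least 2 variables.")
  X <- as.matrix(env[variables])
  if (any(!is.finite(X))) abort("Variables contain non-finite values.")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    abort(paste0("Constant variable(s): ",
                 paste(variables[sds == 0], collapse = ", ")))
  if (nrow(X) <= length(variables))
    warn("Fewer sites than variables + 1: PCA is poorly determined.")
  Z <- scale(X)
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  keep <- which(e$values > min_eigenvalue)
  if (length(keep) == 0) abort("No axis passes the eigenvalue threshold.")
  L <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), length(keep))
  rownames(L) <- variables

  if (length(keep) > 1) {
    rot <- stats::varimax(L, normalize = TRUE, eps = 1e-6)
    L <- unclass(rot$loadings)
  }
  # deterministic sign: dominant variable loads positively on each axis
  for (j in seq_len(ncol(L))) {
    lead <- which.max(abs(L[, j]))
    if (L[lead, j] < 0) L[, j] <- -L[, j]
  }
  # order axes by post-rotation explained variance, descending
  ssq <- colSums(L^2)
  ord <- order(ssq, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  ssq <- ssq[ord]
  n_axes <- ncol(L)
  ax <- paste0("PC", seq_len(n_axes))
  colnames(L) <- ax

  # regression-method scores: Z R^{-1} L; pseudo-inverse when the
  # correlation matrix is singular (more variables than sites)
  W <- tryCatch(solve(R, L), error = function(e) MASS::ginv(R) %*% L)
  S <- Z %*% W
  colnames(S) <- ax
  scores <- as_tibble(as.data.frame(S))
  scores <- dplyr::bind_cols(tibble(site_id = ids), scores)

  if (!is.null(axis_names)) {
    axis_names <- rep_len(axis_names, n_axes)
  }
  structure(list(
    loadings = L,
    scores = scores,
    eigenvalues = e$values,
    explained = ssq / length(variables),
    total_explained = sum(ssq) / length(variables),
    communalities = rowSums(L^2),
    n_axes = n_axes,
    axis_names = axis_names,
    variables = variables
  ), class = "pca_varimax")
}

#' @export
print.pca_varimax <- function(x, ...) {
  cat("Varimax-rotated PCA: ", x$n_axes, " axes retained (eigenvalue > 1), ",
      round(100 * x$total_explained), "% of variance\n", sep = "")
  print(round(x$loadings, 3))
  invisible(x)
}
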