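#' Constrained analysis of principal coordinates (distance-based RDA)
#'
#' Embeds the dissimilarity matrix by principal coordinates, keeps the
#' positive-eigenvalue axes (eigenvalue-weighted, so squared distances are
#' preserved on those axes), and regresses the site coordinates on
#' z-standardised environmental predictors. Each predictor's sequential
#' share of the total inertia (sum of positive eigenvalues) is reported
#' with a permutation pseudo-F test, along with the total constrained
#' fraction.
#'
#' @param dm A `comm_dist` (or symmetric dissimilarity matrix).
#' @param predictors Data frame of numeric predictors, one row per site, in
#'   the order they should enter the sequential decomposition.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param by `"terms"` (sequential, default) or `"margin"`.
#' @param condition_tol Condition-number threshold above which the predictor
#'   set is declared collinear.
#' @return An object of class `cap_fit`: `terms` (tibble with `term`, `df`,
#'   `sum_sq`, `explained_pct`, `pseudo_f`, `p_value`), `total_inertia`,
#'   `constrained_fraction`, `eigenvalues` (PCoA), `site_scores` (first two
#'   constrained axes), `biplot_scores` (predictor correlations with those
#'   axes), `n_perm`, `seed`.
#' @export
cap_fit <- function(dm, predictors, n_perm = 999, seed = NULL,
                    by = c("terms", "margin"), condition_tol = 1e8) {
  by <- match.arg(by)
  if (!inherits(dm, "comm_dist")) dm <- comm_dist(as.matrix(dm))
  predictors <- as.data.frame(predictors)
  n <- nrow(dm)
  if (nrow(predictors) != n) abort("`predictors` rows must align with `dm` sites.")
  if (!all(vapply(predictors, is.numeric, logical(1))))
    abort("All predictors must be numeric (pass PC-axis scores or covariates).")
  if (n < ncol(predictors) + 2)
    abort("Need at least p + 2 sites for p predictors.")
  sds <- vapply(predictors, sd, numeric(1))
  if (any(sds == 0))
    abort(paste0("Zero-variance predictor(s): ",
                 paste(names(predictors)[sds == 0], collapse = ", ")))
  Z <- as.data.frame(scale(predictors))
  sv <- svd(as.matrix(Z), nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > condition_tol) {
    cors <- abs(stats::cor(Z))
    diag(cors) <- 0
    worst <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    abort(paste0("Collinear predictors (condition number above threshold); ",
                 "most correlated pair: ", names(Z)[worst[1]], ", ",
                 names(Z)[worst[2]]))
  }

  pc <- pcoa(dm)
  Y <- pc$coordinates
  total <- sum(pc$eigenvalues[pc$eigenvalues > 0])
  Gp <- Y %*% t(Y)  # inner products on the representable (positive) part
  fit <- permutation_partition(Gp, Z, n_perm = n_perm, seed = seed,
                               total = total, by = by)
  tab <- fit$table
  tab$explained_pct <- 100 * tab$sum_sq / total
  tab <- tab[c("term", "df", "sum_sq", "explained_pct", "pseudo_f", "p_value")]

  # constrained axes: eigen-decomposition of the fitted inner products
  X <- stats::model.matrix(~ ., data = Z)
  qx <- qr(X)
  Yfit <- qr.fitted(qx, Y)
  ef <- eigen(Yfit %*% t(Yfit), symmetric = TRUE)
  n_ax <- min(2L, sum(ef$values > max(ef$values) * 1e-9))
  scores <- ef$vectors[, seq_len(n_ax), drop = FALSE] %*%
    diag(sqrt(pmax(ef$values[seq_len(n_ax)], 0)), n_ax)
  dimnames(scores) <- list(pc$site_ids, paste0("CAP", seq_len(n_ax)))
  biplot <- stats::cor(Z, scores)

  structure(list(terms = tab, total_inertia = total,
                 constrained_fraction = sum(diag(qr.fitted(qx, Gp))) / total,
                 eigenvalues = pc$eigenvalues,
                 site_scores = scores, biplot_scores = biplot,
                 group = attr(dm, "group"),
                 n_perm = fit$n_perm, seed = seed, by = by),
            class = "cap_fit")
}

#' @export
print.cap_fit <- function(x, ...) {
  cat("Constrained analysis of principal coordinates (",
      x$by, " terms, ", x$n_perm, " permutations)\n", sep = "")
  cat("Total inertia ", signif(x$total_inertia, 4), "; constrained fraction ",
      round(100 * x$constrained_fraction, 2), "%\n", sep = "")
  print(x$terms)
  invisible(x)
}
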