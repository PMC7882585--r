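#' Permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared dissimilarities among sites into
#' among-group (or, generally, model-term) and residual components and
#' tests each term with a permutation pseudo-F. Terms are entered
#' sequentially (Type I) in the order given, the conventional default for
#' permutational MANOVA; `by = "margin"` tests each term after all others.
#' The p-value counts the observed statistic in both numerator and
#' denominator, `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so it is
#' always positive and valid. When the requested number of permutations
#' exceeds the number of distinct row permutations (tiny designs), all
#' permutations are enumerated exactly instead, with a notice.
#'
#' @param dm A `comm_dist` (or symmetric dissimilarity matrix).
#' @param design A grouping vector/factor, or a data frame whose columns are
#'   the model terms in entry order (factors and numeric covariates allowed).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param by `"terms"` (sequential, default) or `"margin"`.
#' @return A tibble of class `permanova_fit`: one row per term plus
#'   `Residual` and `Total`, columns `term`, `df`, `sum_sq`, `r_squared`,
#'   `pseudo_f`, `p_value`; attributes record `n_perm`, `seed`, `by` and
#'   whether enumeration was exact.
#' @export
#' @examples
#' cm <- generate_scenario(scenario_truth(seed = 1, n_sites = 10,
#'                                        n_species = 60))$community
#' permanova(bray_curtis(cm), site_groups(cm), n_perm = 99, seed = 1)
permanova <- function(dm, design, n_perm = 999, seed = NULL,
                      by = c("terms", "margin")) {
  by <- match.arg(by)
  if (!inherits(dm, "comm_dist")) dm <- comm_dist(as.matrix(dm))
  if (!is.data.frame(design)) design <- data.frame(group = design)
  n <- nrow(dm)
  if (nrow(design) != n) abort("`design` rows must align with the sites of `dm`.")
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  G <- gower_center(unclass(dm))
  fit <- permutation_partition(G, design, n_perm = n_perm, seed = seed,
                               total = sum(diag(G)), by = by)
  out <- fit$table
  out$r_squared <- out$sum_sq / sum(diag(G))
  out <- out[c("term", "df", "sum_sq", "r_squared", "pseudo_f", "p_value")]
  class(out) <- c("permanova_fit", class(out))
  attr(out, "n_perm") <- fit$n_perm
  attr(out, "seed") <- seed
  attr(out, "by") <- by
  attr(out, "exact") <- fit$exact
  out
}

# Shared engine for permanova() and cap_fit(): sequential (or marginal)
# trace partition tr(H_j G) of a centred inner-product matrix G over the
# cumulative hat matrices of the model terms, with row/column
# co-permutation inference (McArdle & Anderson trace form).
permutation_partition <- function(G, design, n_perm, seed, total, by = "terms") {
  n <- nrow(G)
  terms <- names(design)
  k <- length(terms)
  constant <- vapply(design, function(col) length(unique(col)) < 2, logical(1))
  if (any(constant))
    abort(paste0("Constant term(s) in the design: ",
                 paste(terms[constant], collapse = ", ")))

  mm <- function(cols) {
    if (length(cols) == 0) return(matrix(1, n, 1))
    stats::model.matrix(stats::as.formula(paste("~", paste(cols, collapse = "+"))),
                        data = design)
  }
  hat <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    Q %*% t(Q)
  }
  # cumulative hat matrices and ranks
  Xfull <- mm(terms)
  rank_full <- qr(Xfull)$rank
  if (rank_full >= n) abort("Design is saturated: no residual degrees of freedom.")
  H_list <- vector("list", k)
  ranks <- integer(k)
  for (j in seq_len(k)) {
    Xj <- mm(terms[seq_len(j)])
    ranks[j] <- qr(Xj)$rank
    H_list[[j]] <- hat(Xj)
  }
  df_term <- diff(c(1L, ranks))
  if (any(df_term == 0))
    abort(paste0("Term(s) add no degrees of freedom (constant or aliased): ",
                 paste(terms[df_term == 0], collapse = ", ")))
  H_full <- H_list[[k]]
  df_res <- n - rank_full

  if (by == "margin") {
    H_drop <- lapply(seq_len(k), function(j) hat(mm(terms[-j])))
    rank_drop <- vapply(seq_len(k), function(j) qr(mm(terms[-j]))$rank, integer(1))
    df_term <- rank_full - rank_drop
  }

  stat_fun <- function(Gp) {
    fitted_full <- sum(H_full * Gp)
    res <- total - fitted_full
    if (by == "terms") {
      cum <- vapply(H_list, function(H) sum(H * Gp), numeric(1))
      ss <- diff(c(0, cum))
    } else {
      ss <- fitted_full - vapply(H_drop, function(H) sum(H * Gp), numeric(1))
    }
    list(ss = ss, res = res, F = (ss / df_term) / (res / df_res))
  }

  obs <- stat_fun(G)
  n_distinct <- factorial(n)
  exact <- is.finite(n_distinct) && n_distinct <= n_perm
  if (exact) {
    inform(paste0("Only ", n_distinct, " distinct permutations; ",
                  "using exact enumeration."))
    perms <- all_permutations(n)
    Fp <- vapply(perms, function(p) stat_fun(G[p, p])$F, numeric(length(obs$F)))
    Fp <- matrix(Fp, nrow = length(obs$F))
    p_val <- rowMeans(Fp >= obs$F - 1e-12)
    n_used <- n_distinct
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- rep(1, length(obs$F))  # the observed arrangement counts once
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      count <- count + (stat_fun(G[p, p])$F >= obs$F - 1e-12)
    }
    p_val <- count / (n_perm + 1)
    n_used <- n_perm
  }

  tab <- tibble(
    term = c(terms, "Residual", "Total"),
    df = c(df_term, df_res, n - 1L),
    sum_sq = c(obs$ss, obs$res, total),
    pseudo_f = c(obs$F, NA_real_, NA_real_),
    p_value = c(p_val, NA_real_, NA_real_)
  )
  list(table = tab, n_perm = n_used, exact = exact)
}

# All permutations of 1..n (n <= 9), as a list of integer vectors.
all_permutations <- function(n) {
  if (n > 9) abort("Exhaustive enumeration limited to n <= 9.")
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat("Permutational MANOVA (", attr(x, "by"), " terms, ",
      attr(x, "n_perm"), if (isTRUE(attr(x, "exact"))) " exact" else "",
      " permutations)\n", sep = "")
  print(as_tibble(x))
  invisible(x)
}
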