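#' Dufrene-Legendre indicator value analysis
#'
#' For every species and group: specificity `A` is the species' mean
#' abundance in the group divided by the sum of its group mean abundances
#' (unweighted per-site means, robust to unequal group sizes); fidelity `B`
#' is the fraction of the group's sites the species occupies; the indicator
#' value is `A * B`. Each species is assigned to the group maximising its
#' indicator value and that maximum is tested by permuting site-group
#' labels (exact enumeration replaces sampling on tiny designs, with a
#' notice). Species absent everywhere are flagged, not tested.
#'
#' @param cm A [community_matrix()].
#' @param groups Per-site group labels; default the matrix's `group`
#'   attribute.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed.
#' @return A tibble of class `indval_result`, one row per species:
#'   `species_id`, per-group `A_<g>`, `B_<g>`, `indval_<g>` columns, the
#'   max-group assignment `group`, `indval` (the maximum), `p_value`,
#'   `n_perm`. No multiple-testing correction is applied here; use
#'   [bh_fdr()] across species if required.
#' @export
indval <- function(cm, groups = NULL, n_perm = 999, seed = NULL) {
  stopifnot(inherits(cm, "community_matrix"))
  groups <- groups %||% site_groups(cm)
  if (is.null(groups)) abort("No group labels available.")
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2) abort("Need at least 2 groups.")
  if (any(table(groups) < 1)) abort("Every group needs at least 1 site.")
  m <- unclass(cm)
  n <- nrow(m)

  stat_all <- function(g) {
    # per-group unweighted mean abundance and occupancy fraction
    A_num <- vapply(lev, function(l) colMeans(m[g == l, , drop = FALSE]),
                    numeric(ncol(m)))
    B <- vapply(lev, function(l) colMeans(m[g == l, , drop = FALSE] > 0),
                numeric(ncol(m)))
    A <- A_num / pmax(rowSums(A_num), .Machine$double.eps)
    iv <- A * B
    list(A = A, B = B, iv = iv, max = apply(iv, 1, max))
  }

  obs <- stat_all(groups)
  present <- colSums(m) > 0

  n_distinct <- factorial(n)
  exact <- is.finite(n_distinct) && n_distinct <= n_perm
  if (exact) {
    inform(paste0("Only ", n_distinct, " distinct label permutations; ",
                  "using exact enumeration."))
    perms <- all_permutations(n)
    count <- rowSums(vapply(perms, function(p) stat_all(groups[p])$max >=
                              obs$max - 1e-12, logical(ncol(m))))
    p_val <- count / n_distinct
    n_used <- n_distinct
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- rep(1, ncol(m))
    for (b in seq_len(n_perm)) {
      count <- count + (stat_all(sample(groups))$max >= obs$max - 1e-12)
    }
    p_val <- count / (n_perm + 1)
    n_used <- n_perm
  }
  p_val[!present] <- NA_real_

  out <- tibble(species_id = colnames(m))
  for (l in lev) {
    out[[paste0("A_", l)]] <- unname(obs$A[, l])
    out[[paste0("B_", l)]] <- unname(obs$B[, l])
    out[[paste0("indval_", l)]] <- unname(obs$iv[, l])
  }
  out$group <- lev[apply(obs$iv, 1, which.max)]
  out$group[!present] <- NA_character_
  out$indval <- unname(obs$max)
  out$indval[!present] <- NA_real_
  out$p_value <- unname(p_val)
  out$n_perm <- n_used
  class(out) <- c("indval_result", class(out))
  attr(out, "seed") <- seed
  out
}
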