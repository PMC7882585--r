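#' Randomise a community matrix with fixed species occurrence frequencies
#'
#' The null model behind the standardised beta deviation: for each species
#' independently, the set of occupied sites is redrawn uniformly at random
#' among all site subsets of the same size, and the species' observed
#' positive abundances are randomly permuted onto the new sites. Per-species
#' occupancy count and per-species total abundance are therefore conserved
#' exactly (and with them every column sum and the grand total); per-site
#' richness and totals are not.
#'
#' @param cm A [community_matrix()].
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so repeated calls inside a randomisation loop differ).
#' @return A `community_matrix` of the same dimensions and group labels.
#' @export
null_randomize <- function(cm, seed = NULL) {
  stopifnot(inherits(cm, "community_matrix"))
  if (!is.null(seed)) set.seed(seed)
  m <- null_randomize_impl(unclass(cm))
  suppressMessages(community_matrix(m, group = site_groups(cm)))
}

# Fast path on a bare matrix; used inside the beta_dev loop.
null_randomize_impl <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    pos <- which(m[, j] > 0)
    k <- length(pos)
    if (k == 0) next
    new_sites <- if (k == n) seq_len(n) else sample.int(n, k)
    vals <- m[pos, j]
    out[new_sites, j] <- if (k > 1) vals[sample.int(k)] else vals
  }
  out
}

#' Diversity partition with null-model standardised beta deviation
#'
#' For each site group (e.g. reserve fragment): computes the per-site
#' exponential Shannon alpha, the pooled gamma, the proportional turnover
#' `beta_obs = 1 - alpha/gamma`, and standardises `beta_obs` against the
#' fixed-occurrence-frequency null model of [null_randomize()]. Each of the
#' `n_rand` randomisations is applied to the group's submatrix and the
#' per-site beta recomputed; by default the pooled gamma is recomputed
#' inside every randomisation so pooling effects propagate into the null
#' distribution (`fixed_gamma = TRUE` holds it at the observed value for
#' sensitivity analysis). The standardised deviation is
#' `beta_dev = (beta_obs - mean_null) / sd_null`.
#'
#' @param cm A [community_matrix()].
#' @param groups Optional per-site group labels; default the matrix's
#'   `group` attribute, or a single pooled group when absent.
#' @param n_rand Number of null randomisations (999 by default).
#' @param seed Integer seed making the whole partition reproducible.
#' @param bias_correction Passed to [hill_shannon()] for alpha and gamma.
#' @param fixed_gamma If `TRUE`, the observed gamma is reused inside the
#'   randomisations instead of being recomputed.
#' @param incidence_only If `TRUE`, abundances are reduced to
#'   presence/absence before every diversity computation (alpha and gamma
#'   then equal species richness).
#' @return A tibble of class `diversity_partition` with one row per site:
#'   `site_id`, `group`, `alpha`, `gamma`, `beta_obs`, `beta_null_mean`,
#'   `beta_null_sd`, `beta_dev`, `n_rand`, `seed`. Sites whose null SD is
#'   zero get `beta_dev = NA` with a warning.
#' @export
#' @examples
#' cm <- generate_scenario(scenario_truth(seed = 1, n_sites = 8,
#'                                        n_species = 40))$community
#' dp <- diversity_partition(cm, n_rand = 49, seed = 2)
#' head(dp)
diversity_partition <- function(cm, groups = NULL, n_rand = 999, seed = NULL,
                                bias_correction = c("none", "chao_shen"),
                                fixed_gamma = FALSE, incidence_only = FALSE) {
  stopifnot(inherits(cm, "community_matrix"))
  bias_correction <- match.arg(bias_correction)
  if (!is.numeric(n_rand) || n_rand < 1)
    abort("`n_rand` must be a positive integer.")
  n_rand <- as.integer(n_rand)
  groups <- groups %||% site_groups(cm) %||% rep("all", nrow(cm))
  if (length(groups) != nrow(cm))
    abort("`groups` length must equal the number of sites.")
  if (!is.null(seed)) set.seed(seed)

  res <- lapply(sort(unique(groups)), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2)
      abort(paste0("Group `", g, "` has fewer than 2 sites."))
    m <- unclass(cm)[idx, , drop = FALSE]
    if (incidence_only) m <- (m > 0) * 1
    # pooled vector; reduced to presence/absence in incidence mode so that
    # gamma is the pooled richness, matching the per-site alpha scale
    pool <- function(mm) if (incidence_only) (colSums(mm) > 0) * 1 else colSums(mm)
    alpha <- unname(apply(m, 1, hill_shannon, bias_correction = bias_correction))
    gamma <- hill_shannon(pool(m), bias_correction = bias_correction)
    beta_obs <- suppressWarnings(proportional_beta(alpha, gamma))

    sum_b <- sum_b2 <- numeric(length(idx))
    for (r in seq_len(n_rand)) {
      mr <- null_randomize_impl(m)
      if (incidence_only) mr <- (mr > 0) * 1
      # dead sites can arise in the null when all species leave a site
      occ <- rowSums(mr) > 0
      a_r <- rep(NA_real_, length(idx))
      a_r[occ] <- apply(mr[occ, , drop = FALSE], 1, hill_shannon,
                        bias_correction = bias_correction)
      g_r <- if (fixed_gamma) gamma else
        hill_shannon(pool(mr), bias_correction = bias_correction)
      b_r <- 1 - a_r / g_r
      b_r[is.na(b_r)] <- 1  # empty null site: no local diversity remains
      sum_b <- sum_b + b_r
      sum_b2 <- sum_b2 + b_r^2
    }
    mu <- sum_b / n_rand
    sdv <- sqrt(pmax(0, sum_b2 / n_rand - mu^2) * n_rand / max(1, n_rand - 1))
    bdev <- (beta_obs - mu) / sdv
    if (any(sdv == 0)) {
      warn(paste0("Zero null SD at site(s): ",
                  paste(rownames(m)[sdv == 0], collapse = ", "),
                  "; beta_dev set to NA."))
      bdev[sdv == 0] <- NA_real_
    }
    tibble(site_id = rownames(m), group = g, alpha = alpha, gamma = gamma,
           beta_obs = beta_obs, beta_null_mean = mu, beta_null_sd = sdv,
           beta_dev = bdev)
  })
  out <- dplyr::bind_rows(res)
  out$n_rand <- n_rand
  out$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  class(out) <- c("diversity_partition", class(out))
  attr(out, "bias_correction") <- bias_correction
  attr(out, "fixed_gamma") <- fixed_gamma
  out
}
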