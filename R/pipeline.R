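#' Build a run configuration
#'
#' Validates the configuration driving [run_study()]. Unknown keys are
#' rejected; a seed is mandatory because every stage downstream of data
#' acquisition is stochastic (null randomisations, permutation tests).
#'
#' @param seed Integer seed used for every stochastic stage.
#' @param scenario Named list of [scenario_truth()] arguments (its own
#'   `seed` defaults to the run seed), used when no input paths are given.
#' @param community_file,env_file Optional paths to a community CSV and a
#'   site-covariate CSV (with `site_id` and `group` columns) replacing the
#'   synthetic scenario.
#' @param n_rand Null-model randomisations for the beta deviation (999).
#' @param n_perm Permutations for PERMANOVA / CAP / IndVal (999).
#' @param bias_correction Alpha/gamma estimator, `"none"` or `"chao_shen"`.
#' @param transform Abundance transform for Bray-Curtis (`"sqrt"`).
#' @param cap_by `"terms"` or `"margin"` term tests in CAP.
#' @param n_local_axes Local PC-axes carried into the CAP predictor set (3,
#'   mirroring the convention of using the first local axes).
#' @param landscape_axes Indices of landscape PC-axes used in CAP (default
#'   the first three).
#' @param out_dir Output directory for the result bundle.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed,
                       scenario = list(),
                       community_file = NULL,
                       env_file = NULL,
                       n_rand = 999,
                       n_perm = 999,
                       bias_correction = "none",
                       transform = "sqrt",
                       cap_by = "terms",
                       n_local_axes = 3,
                       landscape_axes = 1:3,
                       out_dir = NULL) {
  if (missing(seed) || !is.finite(seed)) abort("`seed` is mandatory.")
  cfg <- list(seed = as.integer(seed), scenario = scenario,
              community_file = community_file, env_file = env_file,
              n_rand = as.integer(n_rand), n_perm = as.integer(n_perm),
              bias_correction = match.arg(bias_correction, c("none", "chao_shen")),
              transform = match.arg(transform, c("sqrt", "none")),
              cap_by = match.arg(cap_by, c("terms", "margin")),
              n_local_axes = as.integer(n_local_axes),
              landscape_axes = as.integer(landscape_axes),
              out_dir = out_dir)
  if (cfg$n_rand < 1 || cfg$n_perm < 1) abort("`n_rand` and `n_perm` must be >= 1.")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so typos fail fast rather than silently using
#' a default.
#'
#' @param path YAML file of [run_config()] keys.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  do.call(run_config, raw)
}

#' Write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full community-analysis workflow
#'
#' Executes, per fragment and jointly, the screen-condense-partition-model-
#' ordinate-indicate workflow: (i) two-group screening of all site
#' covariates (Mann-Whitney with table-wise BH-FDR); (ii) four
#' varimax-rotated PCAs (local and landscape variable sets, one per
#' fragment); (iii) diversity partition with null-model beta deviation per
#' fragment; (iv) stepwise-AIC linear model of beta deviation on the
#' fragment's PC-axis scores; (v) between-fragment PERMANOVA on Bray-Curtis
#' dissimilarities; (vi) per-fragment constrained ordination (CAP) on the
#' leading local axes plus selected landscape axes; (vii) indicator species
#' analysis between fragments. Results are returned as tibbles and, when
#' `config$out_dir` is set, written as CSVs with a JSON manifest.
#'
#' @param config A [run_config()] (or YAML path).
#' @return A list of class `study_result` with elements `screening`,
#'   `pca` (named list of `pca_varimax`), `partition`, `beta_models`,
#'   `permanova`, `cap` (named list), `indval`, `overlap`, `site_covariates`,
#'   `config`, and `manifest` when written.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage `", name, "` failed: ", conditionMessage(e)))
    })
  }

  dat <- stage("data", acquire_data(config))
  cm <- dat$cm
  covars <- dat$covariates
  groups <- site_groups(cm)
  lev <- sort(unique(groups))

  set.seed(config$seed)
  screening <- stage("screening", screen_variables(covars))

  # user data carry no local/landscape split: one PCA per fragment then
  split_scales <- length(dat$landscape_vars) > 0 &&
    !identical(sort(dat$landscape_vars), sort(dat$local_vars))
  pca <- stage("pca", {
    out <- list()
    for (g in lev) {
      sub <- covars[covars$group == g, , drop = FALSE]
      out[[paste0("local_", g)]] <- suppressWarnings(
        pca_varimax(sub, variables = dat$local_vars))
      if (split_scales)
        out[[paste0("landscape_", g)]] <- suppressWarnings(
          pca_varimax(sub, variables = dat$landscape_vars))
    }
    out
  })

  partition <- stage("partition",
    diversity_partition(cm, n_rand = config$n_rand, seed = config$seed,
                        bias_correction = config$bias_correction))

  beta_models <- stage("beta_models", {
    out <- list()
    for (g in lev) {
      scores <- rename_axes(pca[[paste0("local_", g)]]$scores, "local")
      if (split_scales)
        scores <- dplyr::inner_join(
          scores, rename_axes(pca[[paste0("landscape_", g)]]$scores, "landscape"),
          by = "site_id")
      df <- dplyr::inner_join(
        as_tibble(partition)[partition$group == g, c("site_id", "beta_dev")],
        scores, by = "site_id")
      cand <- setdiff(names(df), c("site_id", "beta_dev"))
      # leading axes only when the fragment has too few sites for all axes
      max_cand <- nrow(df) - 3
      if (length(cand) > max_cand) cand <- cand[seq_len(max_cand)]
      out[[g]] <- stepwise_aic(df, "beta_dev", cand)
    }
    out
  })

  dm <- stage("distance", bray_curtis(cm, transform = config$transform))
  perm <- stage("permanova",
    permanova(dm, groups, n_perm = config$n_perm, seed = config$seed))

  cap <- stage("cap", {
    out <- list()
    for (g in lev) {
      idx <- which(groups == g)
      sub_dm <- comm_dist(unclass(dm)[idx, idx], transform = config$transform)
      loc <- pca[[paste0("local_", g)]]$scores
      n_loc <- min(config$n_local_axes, ncol(loc) - 1)
      pred <- rename_axes(loc[, c(1, 1 + seq_len(n_loc))], "local")
      if (split_scales) {
        lan <- pca[[paste0("landscape_", g)]]$scores
        ax_lan <- config$landscape_axes[config$landscape_axes <= ncol(lan) - 1]
        pred <- dplyr::inner_join(pred,
                                  rename_axes(lan[, c(1, 1 + ax_lan)], "landscape"),
                                  by = "site_id")
      }
      pred <- pred[match(rownames(sub_dm), pred$site_id), , drop = FALSE]
      # leading predictors only when the fragment is too small for all
      max_pred <- nrow(sub_dm) - 2
      if (ncol(pred) - 1 > max_pred) pred <- pred[, seq_len(1 + max_pred)]
      out[[g]] <- cap_fit(sub_dm, pred[-1], n_perm = config$n_perm,
                          seed = config$seed, by = config$cap_by)
    }
    out
  })

  iv <- stage("indval", indval(cm, n_perm = config$n_perm, seed = config$seed))
  overlap <- stage("overlap", species_overlap(cm))

  result <- structure(list(
    screening = screening, pca = pca, partition = partition,
    beta_models = beta_models, permanova = perm, cap = cap, indval = iv,
    overlap = overlap, site_covariates = covars, config = config,
    manifest = NULL
  ), class = "study_result")

  if (!is.null(config$out_dir)) {
    tables <- c(
      list(screening = screening,
           partition = as_tibble(partition),
           permanova = as_tibble(perm),
           indval = as_tibble(iv),
           overlap = overlap,
           site_covariates = covars),
      setNames(lapply(lev, function(g) cap[[g]]$terms),
               paste0("cap_terms_", lev)),
      setNames(lapply(lev, function(g) beta_models[[g]]$coefficients),
               paste0("beta_model_", lev)),
      setNames(lapply(names(pca), function(nm) loadings_table(pca[[nm]])),
               paste0("pca_loadings_", names(pca))),
      setNames(lapply(names(pca), function(nm) pca[[nm]]$scores),
               paste0("pca_scores_", names(pca)))
    )
    # the hash describes the analysis, not where its files land
    result$manifest <- write_results(
      tables, config$out_dir, seed = config$seed,
      config = unclass(config)[setdiff(names(unclass(config)), "out_dir")])
  }
  result
}

rename_axes <- function(scores, prefix) {
  names(scores)[-1] <- paste0(prefix, "_", names(scores)[-1])
  scores
}

loadings_table <- function(p) {
  dplyr::bind_cols(tibble(variable = rownames(p$loadings)),
                   as_tibble(as.data.frame(p$loadings)))
}

# Acquire inputs: read user files when provided, otherwise generate the
# synthetic scenario; assemble the full per-site covariate table (observed
# environment plus the field-data derivations).
acquire_data <- function(config) {
  if (!is.null(config$community_file)) {
    if (is.null(config$env_file))
      abort("`env_file` is required with `community_file`.")
    env <- validate_env_table(readr::read_csv(config$env_file,
                                              show_col_types = FALSE))
    if (!"group" %in% names(env)) abort("`env_file` must contain a `group` column.")
    cm <- read_community_matrix(config$community_file)
    al <- align_tables(cm, env)
    cm <- al$cm; env <- al$env
    cm <- suppressMessages(community_matrix(unclass(cm), group = env$group))
    numvars <- setdiff(names(env)[vapply(env, is.numeric, logical(1))], "site_id")
    # user data: no local/landscape split is known; condense all variables
    return(list(cm = cm, covariates = env,
                local_vars = numvars, landscape_vars = numvars))
  }
  sc_args <- config$scenario
  if (is.null(sc_args$seed)) sc_args$seed <- config$seed
  sc <- generate_scenario(do.call(scenario_truth, sc_args))
  covariates <- assemble_covariates(sc)
  local_vars <- setdiff(
    names(covariates)[vapply(covariates, is.numeric, logical(1))],
    c(grep("^(habitat|edge|modified|dist_to)", names(covariates), value = TRUE)))
  landscape_vars <- grep("^(habitat|edge|modified|dist_to)", names(covariates),
                         value = TRUE)
  list(cm = sc$community, covariates = covariates,
       local_vars = local_vars, landscape_vars = landscape_vars,
       scenario = sc)
}

#' Assemble the per-site covariate table of a synthetic scenario
#'
#' Joins the observed environment proxies with every field-data derivation
#' the package computes: point-centred-quarter forest structure, Ellenberg
#' indicator means, plant richness, functional dispersion, and the
#' landscape metrics at both buffer radii (wide, suffixed `_200` / `_500`).
#'
#' @param sc A `scenario_data` from [generate_scenario()].
#' @return A site covariate tibble with `site_id` and `group`.
#' @export
assemble_covariates <- function(sc) {
  stopifnot(inherits(sc, "scenario_data"))
  env <- sc$env
  forest <- pcq_metrics(sc$pcq)
  ell <- suppressWarnings(ellenberg_means(sc$plants))
  fd <- suppressWarnings(functional_dispersion(sc$plants))
  rich <- tibble(site_id = rownames(sc$plants$incidence),
                 plant_richness = rowSums(sc$plants$incidence))
  lm_ <- landscape_metrics(sc$landscape)
  wide <- tidyr::pivot_wider(
    lm_[c("site_id", "radius_m", "habitat_diversity", "edge_density_m_ha",
          "modified_fraction")],
    names_from = "radius_m",
    values_from = c("habitat_diversity", "edge_density_m_ha", "modified_fraction"))
  dists <- unique(lm_[c("site_id", "dist_to_edge_m", "dist_to_canal_m",
                        "dist_to_industry_m")])
  out <- Reduce(function(a, b) dplyr::left_join(a, b, by = "site_id"),
                list(env, forest[setdiff(names(forest), "n_points")],
                     ell, fd, rich, wide, dists))
  validate_env_table(out)
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  cat("PERMANOVA between fragments: R2 =",
      round(x$permanova$r_squared[1], 3), ", p =",
      signif(x$permanova$p_value[1], 3), "\n")
  cat("Mean beta_obs by group:\n")
  print(dplyr::summarise(dplyr::group_by(as_tibble(x$partition), .data$group),
                         mean_beta = mean(.data$beta_obs),
                         mean_beta_dev = mean(.data$beta_dev, na.rm = TRUE)))
  invisible(x)
}
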