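#' Ground truth for a synthetic two-fragment community scenario
#'
#' Collects every parameter of the generator so that a simulated dataset
#' carries its own truth for recovery and calibration tests. The defaults
#' emulate the sampling design the package targets: two reserve fragments
#' of 30 light-trap sites each, a 392-species pool with log-normal base
#' abundances whose tail yields roughly 15% pooled singletons at default
#' effort (about 400 expected individuals per site), species with Gaussian
#' responses to a latent humidity-nutrient gradient, a moderate
#' between-fragment composition shift, and Poisson sampling noise (an
#' overdispersion toggle switches to negative binomial).
#'
#' @param seed Integer seed (mandatory; every draw flows from it).
#' @param n_sites Sites per fragment (default 30).
#' @param n_species Species-pool size (default 392).
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   species base abundances (relative expected counts per site).
#' @param effort Per-site sampling effort multiplier (scalar or one value
#'   per site; default 1).
#' @param n_gradients Number of latent environmental gradients (default 1;
#'   gradient values are standard normal across sites).
#' @param niche_sd SD of species niche optima along each gradient.
#' @param tolerance_range Range of species niche tolerances (uniform draw).
#' @param fragment_effect Multiplicative composition shift: affected
#'   species' expected counts are multiplied by this factor (half of them
#'   by its reciprocal) in the second fragment. `1` gives exchangeable
#'   fragments by construction.
#' @param fragment_frac Fraction of species affected by the shift.
#' @param env_loadings Loadings of the observed proxy variables on each
#'   latent gradient (one proxy variable per loading per gradient); noise
#'   SD is `sqrt(1 - loading^2)` so proxies have unit variance.
#' @param n_noise_vars Additional pure-noise environment variables.
#' @param overdispersion NB size parameter; `Inf` (default) means Poisson.
#' @param pcq_density_trees_ha Mean true tree density for the simulated
#'   point-centred-quarter records.
#' @param pcq_points PCQ points per site (default 10, the field design).
#' @param n_plant_species Plant species pool for the vegetation tables.
#' @return A validated list of class `scenario_truth`.
#' @export
scenario_truth <- function(seed,
                           n_sites = 30,
                           n_species = 392,
                           abundance_meanlog = log(0.21),
                           abundance_sdlog = 2.2,
                           effort = 1,
                           n_gradients = 1,
                           niche_sd = 1.5,
                           tolerance_range = c(0.5, 1.5),
                           fragment_effect = 4,
                           fragment_frac = 0.3,
                           env_loadings = c(0.9, 0.7, 0.5),
                           n_noise_vars = 3,
                           overdispersion = Inf,
                           pcq_density_trees_ha = 300,
                           pcq_points = 10,
                           n_plant_species = 80) {
  if (missing(seed) || !is.finite(seed)) abort("`seed` is mandatory.")
  truth <- list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                n_species = as.integer(n_species),
                abundance_meanlog = abundance_meanlog,
                abundance_sdlog = abundance_sdlog,
                effort = effort, n_gradients = as.integer(n_gradients),
                niche_sd = niche_sd, tolerance_range = tolerance_range,
                fragment_effect = fragment_effect,
                fragment_frac = fragment_frac,
                env_loadings = env_loadings, n_noise_vars = as.integer(n_noise_vars),
                overdispersion = overdispersion,
                pcq_density_trees_ha = pcq_density_trees_ha,
                pcq_points = as.integer(pcq_points),
                n_plant_species = as.integer(n_plant_species))
  with(truth, {
    if (n_sites < 2 || n_species < 2) abort("Need >= 2 sites and species.")
    if (abundance_sdlog <= 0 || niche_sd <= 0) abort("Variance parameters must be positive.")
    if (any(tolerance_range <= 0) || tolerance_range[2] < tolerance_range[1])
      abort("`tolerance_range` must be positive and increasing.")
    if (fragment_effect <= 0) abort("`fragment_effect` must be positive.")
    if (fragment_frac < 0 || fragment_frac > 1) abort("`fragment_frac` in [0, 1].")
    if (any(env_loadings <= 0 | env_loadings >= 1))
      abort("`env_loadings` must lie strictly in (0, 1).")
    if (overdispersion <= 0) abort("`overdispersion` must be positive.")
    if (any(effort <= 0)) abort("`effort` must be positive.")
  })
  structure(truth, class = "scenario_truth")
}

#' Serialise / restore scenario truth
#'
#' @param truth A `scenario_truth`.
#' @param path File path for the JSON representation.
#' @return `write_scenario_truth()` returns `path` invisibly;
#'   `read_scenario_truth()` returns the restored `scenario_truth`.
#' @export
write_scenario_truth <- function(truth, path) {
  stopifnot(inherits(truth, "scenario_truth"))
  x <- unclass(truth)
  x$overdispersion <- if (is.infinite(x$overdispersion)) "Inf" else x$overdispersion
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_truth
#' @export
read_scenario_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$overdispersion <- if (identical(x$overdispersion, "Inf")) Inf else x$overdispersion
  do.call(scenario_truth, x)
}

#' Generate a synthetic two-fragment community dataset
#'
#' Realises the scenario described by a [scenario_truth()]: the expected
#' count of species k at site i is
#' `effort_i * base_k * fragment_multiplier_k(g_i) *
#' prod_gradients exp(-(x_i - opt_k)^2 / (2 tol_k^2))`,
#' sampled with Poisson (or negative-binomial) noise. Observed environment
#' variables are linear in the latent gradients plus Gaussian noise;
#' vegetation (plant incidence, traits, Ellenberg values), landscape
#' composition and point-centred-quarter records are simulated consistently
#' with the same latent structure. Fully reproducible from the truth's seed.
#'
#' @param truth A [scenario_truth()].
#' @return A list of class `scenario_data`: `community`
#'   ([community_matrix()] with fragment group labels `A`/`B`), `env`
#'   (site covariates including the latent-gradient proxies), `plants`
#'   ([plant_data()]), `landscape` (landscape table), `pcq` (PCQ records),
#'   `gradients` (the latent site values), `truth`.
#' @export
generate_scenario <- function(truth) {
  stopifnot(inherits(truth, "scenario_truth"))
  set.seed(truth$seed)
  n <- 2 * truth$n_sites
  frag <- rep(c("A", "B"), each = truth$n_sites)
  site_id <- sprintf("%s%02d", frag, rep(seq_len(truth$n_sites), 2))
  effort <- rep_len(truth$effort, n)

  # latent gradients and species niches
  X <- matrix(rnorm(n * truth$n_gradients), n, truth$n_gradients)
  opt <- matrix(rnorm(truth$n_species * truth$n_gradients, sd = truth$niche_sd),
                truth$n_species, truth$n_gradients)
  tol <- matrix(runif(truth$n_species * truth$n_gradients,
                      truth$tolerance_range[1], truth$tolerance_range[2]),
                truth$n_species, truth$n_gradients)
  base <- rlnorm(truth$n_species, truth$abundance_meanlog, truth$abundance_sdlog)

  # between-fragment composition shift: half of the affected species up,
  # half down in fragment B, so fragment totals stay comparable
  n_aff <- round(truth$fragment_frac * truth$n_species)
  affected <- sample.int(truth$n_species, n_aff)
  mult <- rep(1, truth$n_species)
  if (n_aff > 0) {
    up <- affected[seq_len(ceiling(n_aff / 2))]
    down <- setdiff(affected, up)
    mult[up] <- truth$fragment_effect
    mult[down] <- 1 / truth$fragment_effect
  }

  mu <- matrix(0, n, truth$n_species)
  for (k in seq_len(truth$n_species)) {
    resp <- rep(1, n)
    for (g in seq_len(truth$n_gradients)) {
      resp <- resp * exp(-(X[, g] - opt[k, g])^2 / (2 * tol[k, g]^2))
    }
    mu[, k] <- effort * base[k] * resp * ifelse(frag == "B", mult[k], 1)
  }
  counts <- if (is.infinite(truth$overdispersion)) {
    matrix(rpois(length(mu), mu), n, truth$n_species)
  } else {
    matrix(stats::rnbinom(length(mu), size = truth$overdispersion, mu = mu),
           n, truth$n_species)
  }
  dimnames(counts) <- list(site_id, sprintf("sp%03d", seq_len(truth$n_species)))
  # a site that caught nothing is resampled as a minimal catch of the most
  # abundant species rather than dropped, to keep the design balanced
  dead <- rowSums(counts) == 0
  if (any(dead)) counts[dead, which.max(base)] <- 1
  cm <- suppressMessages(community_matrix(counts, group = frag))

  # observed environment: proxies per gradient with stated loadings,
  # plus pure-noise variables
  env <- tibble(site_id = site_id, group = frag)
  for (g in seq_len(truth$n_gradients)) {
    for (j in seq_along(truth$env_loadings)) {
      lam <- truth$env_loadings[j]
      env[[sprintf("grad%d_proxy%d", g, j)]] <-
        lam * X[, g] + rnorm(n, sd = sqrt(1 - lam^2))
    }
  }
  for (j in seq_len(truth$n_noise_vars)) {
    env[[sprintf("noise%d", j)]] <- rnorm(n)
  }

  plants <- simulate_plants(truth, X, site_id)
  landscape <- simulate_landscape(truth, site_id, frag)
  pcq <- simulate_pcq(truth, site_id)

  structure(list(community = cm, env = validate_env_table(env),
                 plants = plants, landscape = landscape, pcq = pcq,
                 gradients = X, truth = truth),
            class = "scenario_data")
}

# Plant incidence responds to the first latent gradient; Ellenberg humidity
# and nutrient values of a species track its gradient optimum (wetter,
# richer species sit at the high end), temperature is independent.
simulate_plants <- function(truth, X, site_id) {
  np <- truth$n_plant_species
  sp <- sprintf("plant%03d", seq_len(np))
  opt <- rnorm(np, sd = 1.2)
  prev <- stats::plogis(rnorm(np, 0.2, 0.8))
  n <- length(site_id)
  inc <- matrix(0L, n, np, dimnames = list(site_id, sp))
  for (k in seq_len(np)) {
    p <- prev[k] * exp(-(X[, 1] - opt[k])^2 / (2 * 1.5^2))
    inc[, k] <- rbinom(n, 1, pmin(1, p))
  }
  # guarantee at least one scorable species per site
  empty <- rowSums(inc) == 0
  if (any(empty)) inc[empty, which.max(prev)] <- 1L
  clamp <- function(x) pmin(9, pmax(1, round(x)))
  ellenberg <- tibble(
    plant_species_id = sp,
    humidity = clamp(5 + 1.5 * opt + rnorm(np, sd = 0.7)),
    nutrients = clamp(4.5 + 1.2 * opt + rnorm(np, sd = 0.8)),
    temperature = clamp(rnorm(np, 6.5, 0.8))
  )
  ellenberg$humidity[sample.int(np, round(0.05 * np))] <- NA
  traits <- tibble(
    plant_species_id = sp,
    height_cm = rlnorm(np, log(60), 0.7),
    sla = rlnorm(np, log(20), 0.4),
    growth_form = sample(c("herb", "shrub", "tree"), np, replace = TRUE,
                         prob = c(0.6, 0.25, 0.15))
  )
  plant_data(incidence = inc, traits = traits, ellenberg = ellenberg)
}

# Landscape composition with the between-fragment contrasts of the study
# system: fragment A has more reed/grassland in its buffers and lies close
# to industry; fragment B is embedded in farmland, far from industry.
simulate_landscape <- function(truth, site_id, frag) {
  n <- length(site_id)
  # point distances are properties of the site, shared across buffer radii
  dist_edge <- runif(n, 50, 900)
  dist_canal <- ifelse(frag == "A", rlnorm(n, log(190), 0.7),
                       rlnorm(n, log(590), 0.6))
  dist_industry <- pmax(100, ifelse(frag == "A", rnorm(n, 4000, 1100),
                                    rnorm(n, 13500, 1500)))
  one_radius <- function(r) {
    reed <- pmax(0, ifelse(frag == "A", rnorm(n, 0.09, 0.05), rnorm(n, 0.02, 0.02)))
    grass <- pmax(0, ifelse(frag == "A", rnorm(n, 0.04, 0.03), rnorm(n, 0.01, 0.01)))
    agri <- pmax(0, ifelse(frag == "A", rnorm(n, 0.05, 0.04), rnorm(n, 0.10, 0.05)))
    urban <- pmax(0, rnorm(n, 0.03, 0.02))
    water <- pmax(0, rnorm(n, 0.03, 0.02))
    forest <- pmax(0.05, 1 - reed - grass - agri - urban - water -
                     runif(n, 0, 0.05))
    tot <- reed + grass + agri + urban + water + forest
    scale_dn <- pmax(1, tot)  # renormalise only if fractions overflow
    tibble(site_id = site_id, radius_m = r,
           forest = forest / scale_dn, reed = reed / scale_dn,
           grassland = grass / scale_dn, water = water / scale_dn,
           agriculture = agri / scale_dn, urban_industrial = urban / scale_dn,
           edge_length_m = rlnorm(n, log(0.6 * pi * r), 0.4),
           dist_to_edge_m = dist_edge,
           dist_to_canal_m = dist_canal,
           dist_to_industry_m = dist_industry)
  }
  lt <- dplyr::bind_rows(one_radius(200), one_radius(500))
  validate_landscape_table(lt)
}

# PCQ quarter distances for a homogeneous Poisson forest: within one
# quarter the squared nearest-tree distance is exponential with rate
# lambda * pi / 4 (lambda in trees / m^2).
simulate_pcq <- function(truth, site_id) {
  dens_ha <- pmax(50, rnorm(length(site_id), truth$pcq_density_trees_ha,
                            truth$pcq_density_trees_ha / 6))
  rows <- lapply(seq_along(site_id), function(i) {
    lambda <- dens_ha[i] / 1e4
    m <- truth$pcq_points * 4L
    tibble(
      site_id = site_id[i],
      point_index = rep(seq_len(truth$pcq_points), each = 4L),
      quarter_index = rep(1:4, truth$pcq_points),
      distance_m = sqrt(rexp(m, rate = lambda * pi / 4)),
      tree_species_id = sample(sprintf("tree%02d", 1:6), m, replace = TRUE),
      dbh_cm = rlnorm(m, log(28), 0.45),
      is_conifer = runif(m) < 0.5,
      is_dead = runif(m) < 0.1
    )
  })
  validate_pcq_records(dplyr::bind_rows(rows))
}

#' Degrade sites by binomial thinning of part of the species pool
#'
#' Emulates structural impoverishment at a subset of sites: a randomly
#' chosen fraction of the species pool has its counts binomially thinned at
#' those sites (each individual independently retained with probability
#' `richness_penalty`). This produces the subtractive-heterogenisation
#' signature -- higher proportional beta-diversity at degraded sites --
#' while never increasing any count.
#'
#' @param cm A [community_matrix()].
#' @param sites Site labels (or index) to degrade; must be nonempty.
#' @param richness_penalty Retention probability in `(0, 1]`; `1` leaves
#'   the matrix unchanged.
#' @param species_frac Fraction of species subject to thinning (default 0.5).
#' @param seed Optional integer seed.
#' @return A `community_matrix` with thinned counts.
#' @export
degrade_sites <- function(cm, sites, richness_penalty, species_frac = 0.5,
                          seed = NULL) {
  stopifnot(inherits(cm, "community_matrix"))
  if (length(sites) == 0) abort("`sites` must be nonempty.")
  if (richness_penalty <= 0 || richness_penalty > 1)
    abort("`richness_penalty` must lie in (0, 1].")
  if (!is.null(seed)) set.seed(seed)
  idx <- if (is.character(sites)) match(sites, rownames(cm)) else
    seq_len(nrow(cm))[sites]
  if (anyNA(idx)) abort("Unknown site label(s) in `sites`.")
  m <- unclass(cm)
  target_sp <- sample.int(ncol(m), round(species_frac * ncol(m)))
  if (richness_penalty < 1) {
    for (j in target_sp) {
      m[idx, j] <- rbinom(length(idx), m[idx, j], richness_penalty)
    }
  }
  dead <- rowSums(m) == 0
  if (any(dead)) {
    warn(paste0("Thinning emptied site(s): ",
                paste(rownames(m)[dead], collapse = ", "),
                "; one individual of the commonest species retained."))
    m[dead, which.max(colSums(m))] <- 1
  }
  suppressMessages(community_matrix(m, group = site_groups(cm)))
}
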