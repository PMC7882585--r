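small_truth <- function(seed = 1, ...) {
  scenario_truth(seed = seed, n_sites = 8, n_species = 60,
                 n_plant_species = 25, pcq_points = 4, ...)
}

test_that("scenario generation is fully reproducible from the seed", {
  s1 <- generate_scenario(small_truth(seed = 5))
  s2 <- generate_scenario(small_truth(seed = 5))
  expect_identical(unclass(s1$community), unclass(s2$community))
  expect_identical(s1$env, s2$env)
  expect_identical(s1$pcq, s2$pcq)
  expect_identical(s1$landscape, s2$landscape)
  s3 <- generate_scenario(small_truth(seed = 6))
  expect_false(identical(unclass(s1$community), unclass(s3$community)))
})

test_that("generated data respect the declared structure", {
  sc <- generate_scenario(small_truth(seed = 9))
  cm <- sc$community
  expect_equal(nrow(cm), 16)
  expect_equal(ncol(cm), 60)
  expect_identical(sort(unique(site_groups(cm))), c("A", "B"))
  expect_true(all(unclass(cm) >= 0))
  # proxies carry the latent gradient with roughly their stated loadings
  expect_gt(cor(sc$env$grad1_proxy1, sc$gradients[, 1]), 0.6)
  # landscape table covers both radii for every site
  expect_equal(nrow(sc$landscape), 2 * nrow(cm))
  # PCQ records: 4 quarters x points per site
  expect_equal(nrow(sc$pcq), 16 * 4 * 4)
})

test_that("grand totals concentrate near the Poisson expectation", {
  tot <- vapply(1:6, function(s)
    sum(generate_scenario(small_truth(seed = 400 + s))$community),
    numeric(1))
  # coefficient of variation across replicates stays moderate
  expect_lt(sd(tot) / mean(tot), 0.4)
  expect_gt(mean(tot), 0)
})

test_that("truth serialises losslessly to JSON", {
  tr <- small_truth(seed = 3, fragment_effect = 2.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario_truth(tr, path)
  back <- read_scenario_truth(path)
  expect_equal(unclass(back), unclass(tr))
  # Inf overdispersion (Poisson) survives the round trip
  expect_true(is.infinite(back$overdispersion))
})

test_that("invalid truth parameters fail before any sampling", {
  expect_error(scenario_truth(seed = 1, fragment_effect = 0), "positive")
  expect_error(scenario_truth(seed = 1, abundance_sdlog = -1), "positive")
  expect_error(scenario_truth(seed = 1, tolerance_range = c(2, 1)), "increasing")
  expect_error(scenario_truth(seed = 1, env_loadings = c(0.5, 1.2)), "0, 1")
  expect_error(scenario_truth(), "mandatory")
})

test_that("degrade_sites thins counts without ever increasing them", {
  sc <- generate_scenario(small_truth(seed = 21))
  cm <- sc$community
  deg <- suppressWarnings(
    degrade_sites(cm, site_ids(cm)[1:4], richness_penalty = 0.3, seed = 2))
  expect_true(all(unclass(deg) <= unclass(cm) |
                    unclass(cm) == 0))  # rescue individuals only on emptied sites
  expect_identical(dim(deg), dim(cm))
  # penalty 1 leaves the matrix untouched
  same <- degrade_sites(cm, site_ids(cm)[1:4], richness_penalty = 1, seed = 2)
  expect_identical(unclass(same), unclass(cm))
  expect_error(degrade_sites(cm, character(), 0.5), "nonempty")
  expect_error(degrade_sites(cm, site_ids(cm)[1], 0), "0, 1")
})

test_that("degraded sites show elevated proportional beta-diversity", {
  higher <- 0
  n_rep <- 15
  for (s in seq_len(n_rep)) {
    sc <- generate_scenario(scenario_truth(seed = 600 + s, n_sites = 10,
                                           n_species = 120, fragment_effect = 1))
    cm <- sc$community
    g <- site_groups(cm)
    a_sites <- site_ids(cm)[g == "A"]
    deg <- suppressWarnings(degrade_sites(cm, a_sites[1:5],
                                          richness_penalty = 0.15,
                                          species_frac = 0.8, seed = 700 + s))
    sub <- subset_sites(deg, a_sites)
    m <- unclass(sub)
    alpha <- apply(m, 1, hill_shannon)
    gam <- hill_shannon(colSums(m))
    beta <- 1 - alpha / gam
    higher <- higher + (mean(beta[1:5]) > mean(beta[6:10]))
  }
  expect_gte(higher, n_rep - 3)
})
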