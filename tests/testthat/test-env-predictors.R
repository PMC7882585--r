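make_pcq <- function(site_id = "s1", n_points = 2, dist = 1:8, dbh = 20,
                     conifer = FALSE, dead = FALSE) {
  tibble::tibble(
    site_id = site_id,
    point_index = rep(seq_len(n_points), each = 4),
    quarter_index = rep(1:4, n_points),
    distance_m = rep_len(dist, 4 * n_points),
    tree_species_id = "oak",
    dbh_cm = rep_len(dbh, 4 * n_points),
    is_conifer = rep_len(conifer, 4 * n_points),
    is_dead = rep_len(dead, 4 * n_points)
  )
}

test_that("PCQ metrics follow Pollard's estimator and its scaling law", {
  r <- make_pcq(dist = c(1, 2, 1.5, 2.5, 1, 3, 2, 1))
  fs <- pcq_metrics(r)
  n <- 2
  expected <- 1e4 * 4 * (4 * n - 1) / (pi * sum(r$distance_m^2))
  expect_equal(fs$density_trees_ha, expected)
  # doubling every distance divides density by four
  r2 <- r; r2$distance_m <- 2 * r2$distance_m
  expect_equal(pcq_metrics(r2)$density_trees_ha, expected / 4)
  # identical dbh: zero basal-area spread, cover consistency
  expect_equal(fs$sd_basal_area, 0)
  expect_equal(fs$mean_basal_area_cm2, pi * 10^2)
  expect_equal(fs$deciduous_cover_m2_ha,
               fs$density_trees_ha * fs$mean_basal_area_cm2 * 1e-4)
  expect_equal(fs$conifer_cover_m2_ha, 0)
  expect_equal(fs$pct_dead_trees, 0)
})

test_that("PCQ density is consistent on a spatial Poisson forest", {
  # one genuinely spatial simulation: trees as a Poisson process, nearest
  # tree found per quadrant around interior sample points
  set.seed(101)
  lambda <- 0.03  # 300 trees/ha in trees per m^2
  L <- 260; buf <- 30
  n_tree <- rpois(1, lambda * L^2)
  tx <- runif(n_tree, 0, L); ty <- runif(n_tree, 0, L)
  pts <- 60
  px <- runif(pts, buf, L - buf); py <- runif(pts, buf, L - buf)
  rows <- list()
  for (i in seq_len(pts)) {
    dx <- tx - px[i]; dy <- ty - py[i]
    dd <- sqrt(dx^2 + dy^2)
    quad <- 1 + (dx < 0) + 2 * (dy < 0)
    for (q in 1:4) {
      sel <- which(quad == q)
      j <- sel[which.min(dd[sel])]
      rows[[length(rows) + 1]] <- tibble::tibble(
        site_id = "forest", point_index = i, quarter_index = q,
        distance_m = dd[j], tree_species_id = "t", dbh_cm = 30,
        is_conifer = FALSE, is_dead = FALSE)
    }
  }
  est <- pcq_metrics(dplyr::bind_rows(rows))$density_trees_ha
  expect_lt(abs(est - 300) / 300, 0.25)
})

test_that("incomplete PCQ points are excluded with a warning", {
  r <- make_pcq(n_points = 2)
  r <- r[-3, ]  # break point 1
  expect_warning(fs <- pcq_metrics(r), "4 quarters")
  expect_equal(fs$n_points, 1)
  expect_error(suppressWarnings(pcq_metrics(make_pcq(n_points = 1)[-2, ])),
               "incomplete")
})

test_that("Ellenberg means follow the missing-data contract", {
  inc <- rbind(s1 = c(1, 0, 0), s2 = c(1, 1, 0), s3 = c(0, 0, 1))
  colnames(inc) <- paste0("p", 1:3)
  ell <- tibble::tibble(plant_species_id = paste0("p", 1:3),
                        humidity = c(4, 6, 5),
                        nutrients = c(3, NA, 7),
                        temperature = c(6, 7, NA))
  tr <- tibble::tibble(plant_species_id = paste0("p", 1:3), h = 1:3)
  pd <- plant_data(inc, tr, ell)
  em <- suppressWarnings(ellenberg_means(pd))
  expect_equal(em$ellenberg_humidity, c(4, 5, 5))
  # p2 has no nutrient score: s2's nutrient mean uses p1 only
  expect_equal(em$ellenberg_nutrients, c(3, 3, 7))
  expect_warning(
    ellenberg_means(plant_data(
      inc, tr, tibble::tibble(plant_species_id = paste0("p", 1:3),
                              humidity = c(4, 6, NA), nutrients = c(3, 5, NA),
                              temperature = c(6, 7, NA)))),
    "scorable")
})

test_that("functional dispersion matches midpoint geometry and brute force", {
  inc <- rbind(s1 = c(1, 0, 0, 0), s2 = c(1, 1, 0, 0), s3 = c(1, 1, 1, 1))
  colnames(inc) <- paste0("p", 1:4)
  tr <- tibble::tibble(plant_species_id = paste0("p", 1:4),
                       t1 = c(0, 1, 0.5, 0.2), t2 = c(0, 0, 1, 0.8))
  ell <- tibble::tibble(plant_species_id = paste0("p", 1:4),
                        humidity = 5, nutrients = 5, temperature = 5)
  pd <- plant_data(inc, tr, ell)
  fd <- functional_dispersion(pd)
  expect_equal(fd$fdis[1], 0)  # single species
  g <- as.matrix(cluster::daisy(as.data.frame(tr[, c("t1", "t2")]),
                                metric = "gower"))
  expect_equal(fd$fdis[2], g[1, 2] / 2)  # two species: half their distance
  # brute force via explicit PCoA embedding (real and imaginary axes)
  d4 <- g
  G <- -0.5 * d4^2
  n <- 4
  J <- diag(n) - 1 / n
  e <- eigen(J %*% G %*% J, symmetric = TRUE)
  pos <- e$values > 1e-10; neg <- e$values < -1e-10
  Yp <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  d2 <- rowSums(sweep(Yp, 2, colMeans(Yp))^2)
  if (any(neg)) {
    Yn <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
    d2 <- d2 - rowSums(sweep(Yn, 2, colMeans(Yn))^2)
  }
  ref <- mean(sqrt(pmax(0, d2)))
  expect_equal(fd$fdis[3], ref, tolerance = 1e-10)
})

test_that("landscape metrics follow the defining arithmetic", {
  lt <- tibble::tibble(
    site_id = c("s1", "s1", "s2", "s2"),
    radius_m = c(200, 500, 200, 500),
    forest = c(1/3, 0.6, 0.5, 0.9), reed = c(1/3, 0, 0, 0),
    grassland = c(1/3, 0, 0, 0), water = c(0, 0.1, 0.2, 0),
    agriculture = c(0, 0.2, 0.2, 0.05), urban_industrial = c(0, 0.1, 0.1, 0.05),
    edge_length_m = c(1000, 4712, 500, 1000),
    dist_to_edge_m = 100, dist_to_canal_m = 200, dist_to_industry_m = 3000)
  lm_ <- landscape_metrics(lt)
  expect_equal(lm_$habitat_diversity[1], log(3))
  expect_equal(lm_$habitat_diversity[2], 0)     # single natural class
  # 500 m buffer is 78.54 ha; 4712 m of edge is 60 m/ha
  expect_equal(lm_$edge_density_m_ha[2], 4712 / (pi * 500^2 * 1e-4),
               tolerance = 1e-12)
  expect_equal(lm_$edge_density_m_ha[2], 60.0, tolerance = 1e-3)
  expect_equal(lm_$modified_fraction, c(0, 0.3, 0.3, 0.1))
  # all-zero natural habitat yields NA with a warning
  lt2 <- lt
  lt2$forest <- c(0, 0.6, 0.5, 0.9); lt2$reed <- 0; lt2$grassland <- 0
  expect_warning(lm2 <- landscape_metrics(lt2), "no natural habitat")
  expect_true(is.na(lm2$habitat_diversity[1]))
})
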