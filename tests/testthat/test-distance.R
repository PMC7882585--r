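test_that("Bray-Curtis matches hand arithmetic and boundary cases", {
  m <- rbind(s1 = c(4, 0), s2 = c(1, 1))
  cm <- suppressMessages(community_matrix(m, c("s1", "s2"), c("a", "b")))
  # sqrt rows: (2,0) vs (1,1): (1 + 1) / (3 + 1) = 0.5
  expect_equal(unclass(bray_curtis(cm, "sqrt"))["s1", "s2"], 0.5)
  ident <- suppressMessages(community_matrix(rbind(x = c(2, 3), y = c(2, 3))))
  expect_equal(unclass(bray_curtis(ident))["x", "y"], 0)
  disj <- suppressMessages(community_matrix(rbind(x = c(2, 0), y = c(0, 3))))
  expect_equal(unclass(bray_curtis(disj))["x", "y"], 1)
})

test_that("Bray-Curtis agrees with vegan and is a bounded semimetric", {
  skip_if_not_installed("vegan")
  cm <- random_cm(10, 25, seed = 17)
  d <- bray_curtis(cm, transform = "sqrt")
  ref <- as.matrix(vegan::vegdist(sqrt(unclass(cm)), method = "bray"))
  expect_equal(unclass(d), ref, ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1 + 1e-12))
  expect_equal(unclass(d), t(unclass(d)))
  # permuting species columns changes nothing
  perm <- unclass(cm)[, sample(ncol(cm))]
  d2 <- bray_curtis(suppressMessages(community_matrix(perm)), "sqrt")
  expect_equal(unclass(d), unclass(d2))
  # zero-total site is named in the error
  m <- unclass(cm); m[3, ] <- 0
  expect_error(bray_curtis(m), "s3")
})

test_that("PCoA recovers closed-form and embedding geometries", {
  # three equidistant sites: two equal positive eigenvalues, one zero
  d3 <- matrix(1, 3, 3) - diag(3)
  fit <- pcoa(comm_dist(d3))
  expect_equal(fit$eigenvalues, c(0.5, 0.5, 0), tolerance = 1e-12)
  # points on a line: a single positive eigenvalue reproduces the line
  x <- c(0, 1, 3, 7)
  dl <- as.matrix(dist(x))
  fl <- pcoa(comm_dist(dl))
  expect_equal(sum(fl$eigenvalues > 1e-9), 1)
  expect_equal(as.matrix(dist(fl$coordinates[, 1])), dl, ignore_attr = TRUE)
  # full-rank Euclidean configuration: distances round-trip exactly
  set.seed(4)
  pts <- matrix(rnorm(12), 4, 3)
  dp <- as.matrix(dist(pts))
  fp <- pcoa(comm_dist(dp))
  expect_equal(as.matrix(dist(fp$coordinates)), dp, ignore_attr = TRUE)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("multivariate dispersion matches geometry and vegan::betadisper", {
  ident <- matrix(rep(c(1, 0, 1), 3), 3, 3, byrow = TRUE)
  expect_equal(multivariate_dispersion(ident), 0)
  # two subplots sit at distance d; each is d/2 from the centroid
  two <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 1))
  d12 <- bray_curtis(suppressMessages(community_matrix(two + 0)),
                     transform = "none")[1, 2]
  expect_equal(multivariate_dispersion(two), d12 / 2)

  skip_if_not_installed("vegan")
  set.seed(23)
  inc <- matrix(rbinom(5 * 12, 1, 0.4), 5, 12)
  inc[rowSums(inc) == 0, 1] <- 1
  ours <- multivariate_dispersion(inc)
  dd <- vegan::vegdist(inc, method = "bray")
  bd <- vegan::betadisper(dd, group = rep("g", 5), type = "centroid")
  expect_equal(ours, mean(bd$distances), tolerance = 1e-10)
})

test_that("dispersion equals a direct embedding recomputation on small cases", {
  set.seed(29)
  for (i in 1:8) {
    inc <- matrix(rbinom(4 * 8, 1, 0.5), 4, 8)
    inc[rowSums(inc) == 0, 1] <- 1
    got <- multivariate_dispersion(inc)
    # independent recomputation: Sorensen distances, double-centring,
    # eigen-embedding with real/imaginary split
    d <- matrix(0, 4, 4)
    for (a in 1:3) for (b in (a + 1):4) {
      d[a, b] <- d[b, a] <- sum(abs(inc[a, ] - inc[b, ])) /
        sum(inc[a, ] + inc[b, ])
    }
    G <- -0.5 * d^2
    J <- diag(4) - 1 / 4
    e <- eigen(J %*% G %*% J, symmetric = TRUE)
    pos <- e$values > 1e-10; neg <- e$values < -1e-10
    Yp <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
    d2 <- rowSums(sweep(Yp, 2, colMeans(Yp))^2)
    if (any(neg)) {
      Yn <- e$vectors[, neg, drop = FALSE] %*%
        diag(sqrt(-e$values[neg]), sum(neg))
      d2 <- d2 - rowSums(sweep(Yn, 2, colMeans(Yn))^2)
    }
    expect_equal(got, mean(sqrt(pmax(0, d2))), tolerance = 1e-10)
    # replicating every subplot leaves the dispersion unchanged
    expect_equal(multivariate_dispersion(rbind(inc, inc)), got,
                 tolerance = 1e-10)
  }
})

test_that("empty subplots are excluded with a warning", {
  inc <- rbind(c(1, 1, 0), c(0, 0, 0), c(1, 0, 1))
  expect_warning(v <- multivariate_dispersion(inc), "no species")
  expect_gt(v, 0)
})
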