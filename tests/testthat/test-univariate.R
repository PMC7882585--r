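test_that("Mann-Whitney matches exact enumeration and symmetry properties", {
  x <- c(1, 2, 3, 4); y <- c(10, 11, 12, 13)
  res <- mann_whitney(x, y)
  expect_equal(res$U, 0)
  # exact two-sided p over all choose(8,4) = 70 arrangements is 2/70;
  # the tie-corrected normal approximation sits within 0.01 of it
  expect_lt(abs(res$p_value - 2 / 70), 0.01)
  # swapping the samples flips z, leaves p
  rev <- mann_whitney(y, x)
  expect_equal(rev$z, -res$z)
  expect_equal(rev$p_value, res$p_value)
  # identical multisets: z about zero, p about 1
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_lt(abs(same$z), 0.3)
  expect_gt(same$p_value, 0.7)
  expect_warning(tied <- mann_whitney(c(2, 2), c(2, 2, 2)), "tied")
  expect_equal(tied$p_value, 1)
})

test_that("the tie-corrected normal approximation tracks wilcox.test", {
  set.seed(103)
  for (i in 1:20) {
    x <- round(rnorm(10, 0, 2)); y <- round(rnorm(12, 0.5, 2))
    ours <- mann_whitney(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    # and the exact permutation distribution is close for these sizes
    if (!any(duplicated(c(x, y)))) {
      ex <- wilcox.test(x, y, exact = TRUE)
      expect_lt(abs(ours$p_value - ex$p.value), 0.02)
    }
  }
})

test_that("BH adjustment equals the textbook step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # oracle re-implementation on random vectors
  set.seed(107)
  for (i in 1:10) {
    p <- runif(15)^2
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    oracle <- pmin(1, q_sorted)[order(o)]
    expect_equal(bh_fdr(p), oracle)
    expect_true(all(bh_fdr(p) >= p - 1e-12))
  }
})

test_that("variable screening mirrors the two-group comparison layout", {
  set.seed(109)
  env <- tibble::tibble(site_id = paste0("s", 1:30),
                        group = rep(c("A", "B"), each = 15),
                        shifted = rnorm(30) + rep(c(0, 2), each = 15),
                        flat = rnorm(30))
  tab <- screen_variables(env)
  expect_identical(tab$variable, c("shifted", "flat"))
  expect_true(all(tab$q_value >= tab$p_value - 1e-12))
  expect_true(tab$significant[tab$variable == "shifted"])
  expect_equal(tab$mean_a[1], mean(env$shifted[1:15]))
  expect_error(screen_variables(env[, -2]), "group")
})

test_that("stepwise AIC honours the search contract and finds planted effects", {
  set.seed(113)
  n <- 40
  df <- tibble::tibble(axis1 = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                       n3 = rnorm(n), n4 = rnorm(n))
  df$y <- 0.5 * df$axis1 + rnorm(n, sd = 0.2)
  fit <- stepwise_aic(df, "y", c("axis1", paste0("n", 1:4)))
  expect_true("axis1" %in% fit$selected)
  expect_lte(fit$aic, fit$aic_full + 1e-9)
  # standardized coefficient has the analytic value beta * sd(x) / sd(y)
  b <- fit$coefficients
  expect_equal(b$std_beta[b$term == "axis1"],
               b$estimate[b$term == "axis1"] * sd(df$axis1) / sd(df$y))
  # pure-noise response: final AIC never exceeds the full model's
  df$y2 <- rnorm(n)
  fit2 <- stepwise_aic(df, "y2", c("axis1", paste0("n", 1:4)))
  expect_lte(fit2$aic, fit2$aic_full + 1e-9)
  expect_error(stepwise_aic(df[1:5, ], "y", c("axis1", paste0("n", 1:4))),
               "more sites")
  df$alias <- df$axis1 * 2
  expect_error(stepwise_aic(df, "y", c("axis1", "alias")), "aliased")
})

test_that("stepwise AIC never beats the exhaustive best subset", {
  set.seed(127)
  for (i in 1:5) {
    n <- 25
    df <- as.data.frame(matrix(rnorm(n * 4), n))
    names(df) <- paste0("x", 1:4)
    df$y <- 0.6 * df$x1 - 0.3 * df$x3 + rnorm(n, sd = 0.7)
    fit <- stepwise_aic(df, "y", paste0("x", 1:4))
    # enumerate all 16 subsets
    best <- Inf
    for (k in 0:4) for (s in utils::combn(4, k, simplify = FALSE)) {
      f <- if (k == 0) "y ~ 1" else
        paste("y ~", paste(paste0("x", s), collapse = "+"))
      best <- min(best, AIC(lm(as.formula(f), data = df)))
    }
    expect_gte(fit$aic + 1e-9, best)
  }
})
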