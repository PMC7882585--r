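# Small fixed communities and field tables, built in code.

tiny_cm <- function(group = NULL) {
  m <- rbind(s1 = c(4, 2, 1, 1, 0),
             s2 = c(0, 5, 3, 0, 2),
             s3 = c(1, 1, 1, 1, 1),
             s4 = c(6, 0, 0, 2, 0))
  colnames(m) <- paste0("sp", 1:5)
  suppressMessages(community_matrix(m, group = group))
}

random_cm <- function(n_sites, n_species, lambda = 3, seed = 1, group = NULL) {
  set.seed(seed)
  m <- matrix(rpois(n_sites * n_species, lambda), n_sites, n_species,
              dimnames = list(paste0("s", seq_len(n_sites)),
                              paste0("sp", seq_len(n_species))))
  m[rowSums(m) == 0, 1] <- 1
  suppressMessages(community_matrix(m, group = group))
}

write_cm_csv <- function(m, path, sep = ",") {
  df <- cbind(site_id = rownames(m), as.data.frame(m))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# Independent brute-force PERMANOVA over all relabelings that keep the
# group sizes: F from within-group sums of squared dissimilarities.
brute_permanova <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  lev <- unique(groups)
  ss_within <- function(g) {
    s <- 0
    for (l in lev) {
      idx <- which(g == l)
      s <- s + sum(d[idx, idx]^2) / (2 * length(idx))
    }
    s
  }
  ss_tot <- sum(d^2) / (2 * n)
  f_stat <- function(g) {
    ssw <- ss_within(g)
    ((ss_tot - ssw) / (length(lev) - 1)) / (ssw / (n - length(lev)))
  }
  f_obs <- f_stat(groups)
  labelings <- utils::combn(n, sum(groups == lev[1]), simplify = FALSE)
  fs <- vapply(labelings, function(idx) {
    g <- rep(lev[2], n); g[idx] <- lev[1]
    f_stat(g)
  }, numeric(1))
  list(F = f_obs, p = mean(fs >= f_obs - 1e-12))
}

# Independent brute-force IndVal p for every species: max-group A*B over
# all labelings preserving group sizes.
brute_indval <- function(m, groups) {
  lev <- sort(unique(groups))
  stat <- function(g) {
    iv <- sapply(lev, function(l) {
      sub <- m[g == l, , drop = FALSE]
      A_num <- colMeans(sub)
      B <- colMeans(sub > 0)
      A_num * B  # numerator; normalise across groups below
    })
    A_num <- sapply(lev, function(l) colMeans(m[g == l, , drop = FALSE]))
    A <- A_num / pmax(rowSums(A_num), .Machine$double.eps)
    B <- sapply(lev, function(l) colMeans(m[g == l, , drop = FALSE] > 0))
    apply(A * B, 1, max)
  }
  obs <- stat(groups)
  n <- nrow(m)
  labelings <- utils::combn(n, sum(groups == lev[1]), simplify = FALSE)
  counts <- rep(0, ncol(m))
  for (idx in labelings) {
    g <- rep(lev[2], n); g[idx] <- lev[1]
    counts <- counts + (stat(g) >= obs - 1e-12)
  }
  list(indval = obs, p = counts / length(labelings))
}
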