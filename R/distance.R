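#' Bray-Curtis dissimilarity between sites
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` on (optionally
#' square-root transformed) abundances. The square-root transform damps the
#' influence of highly abundant species before comparing communities. The
#' result is a dissimilarity (1 minus the familiar Bray-Curtis similarity),
#' bounded in `[0, 1]`.
#'
#' @param cm A [community_matrix()] (or bare non-negative matrix) with at
#'   least two sites, each with a positive total.
#' @param transform `"sqrt"` (default, as is conventional for abundance
#'   data) or `"none"`.
#' @return A `comm_dist` object: the symmetric dissimilarity matrix with a
#'   `transform` attribute and the sites' group labels carried along.
#' @export
bray_curtis <- function(cm, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  m <- unclass(cm)
  if (nrow(m) < 2) abort("Need at least 2 sites.")
  tot <- rowSums(m)
  if (any(tot == 0))
    abort(paste0("Site(s) with zero total abundance: ",
                 paste(rownames(m)[tot == 0], collapse = ", ")))
  if (transform == "sqrt") m <- sqrt(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(xi - m[j, ])) / sum(xi + m[j, ])
    }
  }
  comm_dist(d, transform = transform,
            group = if (inherits(cm, "community_matrix")) site_groups(cm))
}

#' Construct a community dissimilarity matrix object
#'
#' @param d Symmetric numeric matrix with zero diagonal, dissimilarities.
#' @param transform Tag recording the abundance transform applied upstream.
#' @param group Optional per-site group labels.
#' @return A `comm_dist` object.
#' @export
comm_dist <- function(d, transform = "none", group = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
    abort("Dissimilarity matrix must be symmetric.")
  if (any(abs(diag(d)) > 1e-12)) abort("Dissimilarity diagonal must be zero.")
  if (any(d < 0)) abort("Dissimilarities must be non-negative.")
  if (is.null(rownames(d))) dimnames(d) <- list(paste0("site", seq_len(nrow(d))),
                                                paste0("site", seq_len(nrow(d))))
  structure(d, class = c("comm_dist", "matrix"),
            transform = transform, group = group)
}

#' @export
print.comm_dist <- function(x, ...) {
  cat("<comm_dist> ", nrow(x), " sites, transform = ", attr(x, "transform"),
      ", range [", round(min(x[upper.tri(x)]), 3), ", ",
      round(max(x), 3), "]\n", sep = "")
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: the squared
#' dissimilarities are double-centred (Gower's matrix) and
#' eigen-decomposed. Eigenvalues are reported in descending order; negative
#' eigenvalues (possible for semimetric inputs such as Bray-Curtis) are
#' reported but their axes carry no coordinates.
#'
#' @param dm A `comm_dist` (or symmetric matrix of dissimilarities).
#' @return A list of class `pcoa_fit`: `eigenvalues` (all, descending),
#'   `coordinates` (sites x positive axes, scaled so the sum of squares of
#'   each axis equals its eigenvalue), `site_ids`, `group`.
#' @export
pcoa <- function(dm) {
  if (!inherits(dm, "comm_dist")) dm <- comm_dist(as.matrix(dm))
  G <- gower_center(unclass(dm))
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-9  # strictly positive axes
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  dimnames(coords) <- list(rownames(dm), paste0("axis", seq_len(ncol(coords))))
  structure(list(eigenvalues = e$values, coordinates = coords,
                 site_ids = rownames(dm), group = attr(dm, "group")),
            class = "pcoa_fit")
}

# Gower double-centring of squared dissimilarities.
gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% a %*% J
}

#' Multivariate dispersion of subplot communities
#'
#' Per-site heterogeneity of vegetation subplots: Sorensen dissimilarities
#' (Bray-Curtis on presence/absence) among a site's subplots are embedded by
#' principal coordinates, and the dispersion is the mean distance of the
#' subplots to their centroid. Negative-eigenvalue axes are handled by
#' subtracting the imaginary-axis contribution from the squared distances,
#' as in the standard multivariate-dispersion procedure.
#'
#' @param subplots A data frame or matrix of subplot x species incidence
#'   (0/1) for one site, or a named list of such matrices (one per site).
#' @param metric Dissimilarity among subplots; only `"sorensen"`.
#' @return For a single matrix, one dispersion value; for a list, a tibble
#'   with `site_id` and `dispersion`.
#' @export
multivariate_dispersion <- function(subplots, metric = c("sorensen")) {
  metric <- match.arg(metric)
  if (is.list(subplots) && !is.data.frame(subplots)) {
    vals <- vapply(subplots, multivariate_dispersion, numeric(1), metric = metric)
    return(tibble(site_id = names(subplots), dispersion = unname(vals)))
  }
  m <- as.matrix(subplots)
  if (!all(m %in% c(0, 1))) abort("Subplot incidence entries must be 0/1.")
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warn(paste0("Excluding ", sum(empty), " subplot(s) with no species."))
    m <- m[!empty, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("Need at least 2 non-empty subplots per site.")
  rownames(m) <- paste0("p", seq_len(nrow(m)))
  d <- bray_curtis(suppressMessages(community_matrix(m)), transform = "none")
  mean(dist_to_centroid(unclass(d)))
}

# Distances of points to their centroid in the PCoA embedding of a
# dissimilarity matrix, with the real/imaginary-axis correction of the
# multivariate-dispersion procedure (squared imaginary distances are
# subtracted; negative squared totals are truncated at zero).
dist_to_centroid <- function(d) {
  G <- gower_center(d)
  e <- eigen(G, symmetric = TRUE)
  tolv <- max(abs(e$values)) * 1e-9
  pos <- e$values > tolv
  neg <- e$values < -tolv
  n <- nrow(d)
  cp <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  cn <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
  d2 <- rowSums(sweep(cp, 2, colMeans(cp))^2)
  if (sum(neg) > 0) d2 <- d2 - rowSums(sweep(cn, 2, colMeans(cn))^2)
  sqrt(pmax(0, d2))
}
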