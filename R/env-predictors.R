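#' Forest structure from point-centred-quarter records
#'
#' Estimates per-site forest structure from plotless point-centred-quarter
#' sampling. Tree density uses Pollard's unbiased estimator over the pooled
#' quarters of a site's points, `lambda = 4 * (4n - 1) / (pi * sum(d^2))`
#' trees per square metre (n points, d in metres), scaled to trees/ha; the
#' classic Cottam-Curtis mean-distance form is available for comparison.
#' Basal area per tree is `pi * (dbh / 2)^2` (cm^2); cover of the deciduous
#' and conifer classes is class density times the class's mean basal area,
#' converted to m^2/ha.
#'
#' @param records PCQ records as validated by [validate_pcq_records()]
#'   (validation is applied here with `drop_incomplete = TRUE`, so points
#'   missing a quarter are excluded with a warning).
#' @param estimator `"pollard"` (unbiased, default) or `"cottam"`
#'   (`1 / mean(d)^2` form).
#' @return A tibble, one row per site: `site_id`, `density_trees_ha`,
#'   `mean_basal_area_cm2`, `sd_basal_area`, `deciduous_cover_m2_ha`,
#'   `conifer_cover_m2_ha`, `pct_dead_trees`, `n_points`.
#' @references Pollard, J.H. (1971) On distance estimators of density in
#'   randomly distributed forests. Biometrics 27, 991-1002.
#' @export
pcq_metrics <- function(records, estimator = c("pollard", "cottam")) {
  estimator <- match.arg(estimator)
  records <- validate_pcq_records(records, drop_incomplete = TRUE)
  split_recs <- split(as.data.frame(records), records$site_id)
  rows <- lapply(split_recs, function(r) {
    n_pts <- length(unique(r$point_index))
    d <- r$distance_m
    dens_m2 <- if (estimator == "pollard") {
      4 * (4 * n_pts - 1) / (pi * sum(d^2))
    } else {
      1 / mean(d)^2
    }
    dens_ha <- dens_m2 * 1e4
    ba <- pi * (r$dbh_cm / 2)^2
    class_cover <- function(sel) {
      if (!any(sel)) return(0)
      # class density = total density x class share of sampled trees
      dens_ha * mean(sel) * mean(ba[sel]) * 1e-4  # cm^2 -> m^2
    }
    tibble(
      site_id = r$site_id[1],
      density_trees_ha = dens_ha,
      mean_basal_area_cm2 = mean(ba),
      sd_basal_area = if (length(ba) > 1) sd(ba) else 0,
      deciduous_cover_m2_ha = class_cover(!r$is_conifer),
      conifer_cover_m2_ha = class_cover(r$is_conifer),
      pct_dead_trees = 100 * mean(r$is_dead),
      n_points = n_pts
    )
  })
  dplyr::bind_rows(rows)[order(names(split_recs)), , drop = FALSE]
}

#' Site-level Ellenberg indicator means
#'
#' Unweighted mean of the Ellenberg humidity, nutrient and temperature
#' indicator values over the plant species present at each site. Species
#' with a missing value for one index still contribute to the others; a
#' site with no scorable species for an index gets `NA` with a warning.
#'
#' @param pd A [plant_data()] object.
#' @return A tibble: `site_id`, `ellenberg_humidity`, `ellenberg_nutrients`,
#'   `ellenberg_temperature`.
#' @export
ellenberg_means <- function(pd) {
  stopifnot(inherits(pd, "plant_data"))
  inc <- pd$incidence
  ev <- pd$ellenberg[match(colnames(inc), pd$ellenberg$plant_species_id), ]
  one_index <- function(vals) {
    unname(apply(inc, 1, function(row) {
      v <- vals[row > 0]
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else mean(v)
    }))
  }
  out <- tibble(
    site_id = rownames(inc),
    ellenberg_humidity = one_index(ev$humidity),
    ellenberg_nutrients = one_index(ev$nutrients),
    ellenberg_temperature = one_index(ev$temperature)
  )
  n_miss <- sum(!complete.cases(out))
  if (n_miss > 0)
    warn(paste0(n_miss, " site(s) lack scorable species for some index."))
  out
}

#' Functional dispersion of site plant communities
#'
#' FDis per site: Gower distance over the mixed trait table for the species
#' present at a site, embedded by principal coordinates, and the mean
#' distance of those species to their trait-space centroid. Species weights
#' are equal because the vegetation data are incidences; abundance weights
#' can be supplied for other data.
#'
#' @param pd A [plant_data()] object. Species present at a site but absent
#'   from the trait table rows with only missing traits are excluded with a
#'   warning.
#' @param weights Optional sites x species abundance matrix (same dimnames
#'   as the incidence table) for abundance-weighted FDis.
#' @return A tibble: `site_id`, `fdis` (0 for single-species sites).
#' @references Laliberte, E. & Legendre, P. (2010) A distance-based
#'   framework for measuring functional diversity from multiple traits.
#'   Ecology 91, 299-305.
#' @export
functional_dispersion <- function(pd, weights = NULL) {
  stopifnot(inherits(pd, "plant_data"))
  inc <- pd$incidence
  tr <- as.data.frame(pd$traits)
  rownames(tr) <- tr$plant_species_id
  tr <- tr[setdiff(names(tr), "plant_species_id")]
  tr <- tr[colnames(inc), , drop = FALSE]
  tr[] <- lapply(tr, function(col) if (is.character(col)) factor(col) else col)
  untraited <- rownames(tr)[rowSums(!is.na(tr)) == 0]
  if (length(untraited) > 0)
    warn(paste0("Excluding species with no trait data: ",
                paste(head(untraited, 5), collapse = ", ")))
  gd <- as.matrix(cluster::daisy(tr, metric = "gower"))
  fdis_site <- function(site) {
    sp <- colnames(inc)[inc[site, ] > 0]
    sp <- setdiff(sp, untraited)
    if (length(sp) < 2) return(0)
    d <- gd[sp, sp]
    w <- if (is.null(weights)) rep(1, length(sp)) else weights[site, sp]
    weighted_dist_to_centroid(d, w)
  }
  tibble(site_id = rownames(inc),
         fdis = unname(vapply(rownames(inc), fdis_site, numeric(1))))
}

# Weighted mean distance to the weighted centroid in the PCoA embedding,
# with the real/imaginary correction (FDis definition).
weighted_dist_to_centroid <- function(d, w) {
  w <- w / sum(w)
  G <- gower_center(d)
  e <- eigen(G, symmetric = TRUE)
  tolv <- max(abs(e$values)) * 1e-9
  pos <- e$values > tolv
  neg <- e$values < -tolv
  cp <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  cn <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
  d2 <- rowSums(sweep(cp, 2, colSums(cp * w))^2)
  if (sum(neg) > 0) d2 <- d2 - rowSums(sweep(cn, 2, colSums(cn * w))^2)
  sum(w * sqrt(pmax(0, d2)))
}

#' Derived landscape metrics per site and buffer radius
#'
#' From a validated landscape composition table: habitat diversity is the
#' Shannon index (natural log) over the forest, reed and grassland
#' fractions renormalised to sum to one (the natural-habitat classes; water
#' and human-modified classes are excluded from the diversity); edge
#' density is the habitat boundary length divided by the buffer area in
#' hectares; the modified-areas fraction sums agriculture and
#' urban/industrial cover. Point distances are passed through.
#'
#' @param lt A table accepted by [validate_landscape_table()].
#' @return A tibble, one row per site x radius: `site_id`, `radius_m`,
#'   `habitat_diversity`, `edge_density_m_ha`, `modified_fraction`, the
#'   three distances, and the raw class fractions.
#' @export
landscape_metrics <- function(lt) {
  lt <- validate_landscape_table(lt, radii = unique(lt$radius_m))
  nat <- as.matrix(lt[c("forest", "reed", "grassland")])
  nat_tot <- rowSums(nat)
  hdiv <- vapply(seq_len(nrow(nat)), function(i) {
    if (nat_tot[i] == 0) return(NA_real_)
    p <- nat[i, ] / nat_tot[i]
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  if (anyNA(hdiv))
    warn("Site-radius row(s) with no natural habitat: diversity set to NA.")
  buffer_ha <- pi * lt$radius_m^2 * 1e-4
  tibble(
    site_id = lt$site_id,
    radius_m = lt$radius_m,
    habitat_diversity = hdiv,
    edge_density_m_ha = lt$edge_length_m / buffer_ha,
    modified_fraction = lt$agriculture + lt$urban_industrial,
    dist_to_edge_m = lt$dist_to_edge_m,
    dist_to_canal_m = lt$dist_to_canal_m,
    dist_to_industry_m = lt$dist_to_industry_m,
    forest = lt$forest, reed = lt$reed, grassland = lt$grassland,
    water = lt$water
  )
}
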