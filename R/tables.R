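#' Validate a site-level environment table
#'
#' Checks the contract for site-level covariate tables: one row per site,
#' a `site_id` column of unique labels, and numeric covariate columns free
#' of non-finite values.
#'
#' @param env A data frame with a `site_id` column and numeric covariates.
#' @param units Optional named character vector of per-variable unit strings;
#'   stored as an attribute.
#' @return The validated table as a tibble (invisible attributes preserved).
#' @export
validate_env_table <- function(env, units = NULL) {
  env <- as_tibble(env)
  if (!"site_id" %in% names(env)) abort("`env` must have a `site_id` column.")
  if (anyDuplicated(env$site_id)) abort("Duplicate `site_id` in environment table.")
  vars <- setdiff(names(env), c("site_id", "group"))
  for (v in vars) {
    if (!is.numeric(env[[v]]))
      abort(paste0("Environment variable `", v, "` is not numeric."))
    if (any(!is.finite(env[[v]])))
      abort(paste0("Environment variable `", v, "` contains non-finite values."))
  }
  if (!is.null(units)) attr(env, "units") <- units
  env
}

#' Validate plant incidence, trait and Ellenberg tables
#'
#' Bundles the vegetation inputs: a sites x plant-species 0/1 incidence
#' table (long or wide), a per-species trait table, and per-species Ellenberg
#' indicator values for humidity, nutrients and temperature (1-12 scale,
#' missing allowed per species).
#'
#' @param incidence Data frame: `site_id` column plus one 0/1 column per
#'   plant species, or a matrix with site rownames.
#' @param traits Data frame with `plant_species_id` plus numeric and/or
#'   categorical trait columns. Must cover exactly the incidence species.
#' @param ellenberg Data frame with `plant_species_id`, `humidity`,
#'   `nutrients`, `temperature` (NA allowed).
#' @return A list of class `plant_data` with elements `incidence` (matrix),
#'   `traits`, `ellenberg`.
#' @export
plant_data <- function(incidence, traits, ellenberg) {
  if (is.data.frame(incidence)) {
    if (!"site_id" %in% names(incidence))
      abort("`incidence` data frame needs a `site_id` column.")
    m <- as.matrix(incidence[setdiff(names(incidence), "site_id")])
    rownames(m) <- incidence$site_id
    incidence <- m
  }
  if (!all(incidence %in% c(0, 1)))
    abort("Incidence entries must be 0 or 1.")
  traits <- as_tibble(traits)
  if (!"plant_species_id" %in% names(traits))
    abort("`traits` needs a `plant_species_id` column.")
  if (!setequal(traits$plant_species_id, colnames(incidence)))
    abort("Trait table species set must equal the incidence species set.")
  ellenberg <- as_tibble(ellenberg)
  need <- c("plant_species_id", "humidity", "nutrients", "temperature")
  if (!all(need %in% names(ellenberg)))
    abort("`ellenberg` needs columns plant_species_id, humidity, nutrients, temperature.")
  ev <- as.matrix(ellenberg[c("humidity", "nutrients", "temperature")])
  if (any(ev < 1 | ev > 12, na.rm = TRUE))
    abort("Ellenberg indicator values must lie in the conventional 1-12 range.")
  structure(list(incidence = incidence, traits = traits, ellenberg = ellenberg),
            class = "plant_data")
}

#' Validate point-centred-quarter field records
#'
#' Each record is one tree: the nearest tree to a sampling point within one
#' of four quarters, with its distance, species, diameter at breast height,
#' and conifer / standing-dead flags. Every point must have exactly four
#' quarters; incomplete points are rejected here (downstream estimators may
#' exclude them with a warning instead via `drop_incomplete`).
#'
#' @param records Data frame with columns `site_id`, `point_index`,
#'   `quarter_index` (1-4), `distance_m` (> 0), `tree_species_id`,
#'   `dbh_cm` (> 0), `is_conifer`, `is_dead` (logical).
#' @param drop_incomplete If `TRUE`, points with fewer than 4 quarters are
#'   dropped with a warning instead of raising an error.
#' @return The validated records as a tibble.
#' @export
validate_pcq_records <- function(records, drop_incomplete = FALSE) {
  records <- as_tibble(records)
  need <- c("site_id", "point_index", "quarter_index", "distance_m",
            "tree_species_id", "dbh_cm", "is_conifer", "is_dead")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    abort(paste0("PCQ records missing column(s): ", paste(miss, collapse = ", ")))
  if (any(records$distance_m <= 0)) abort("`distance_m` must be positive.")
  if (any(records$dbh_cm <= 0)) abort("`dbh_cm` must be positive.")
  if (!all(records$quarter_index %in% 1:4))
    abort("`quarter_index` must be in 1..4.")
  key <- paste(records$site_id, records$point_index)
  nq <- tapply(records$quarter_index, key, function(q) length(unique(q)))
  bad <- names(nq)[nq != 4]
  if (length(bad) > 0) {
    if (drop_incomplete) {
      warn(paste0("Excluding ", length(bad), " point(s) without 4 quarters."))
      records <- records[!key %in% bad, , drop = FALSE]
      if (nrow(records) == 0) abort("All PCQ points were incomplete.")
    } else {
      abort(paste0("Point(s) without exactly 4 quarters: ",
                   paste(head(bad, 5), collapse = "; ")))
    }
  }
  records
}

#' Validate a landscape composition table
#'
#' One row per site and buffer radius, holding area fractions per land-cover
#' class, the total habitat edge length inside the buffer, and point
#' distances to the nearest reserve edge, water canal and industrial area.
#'
#' @param lt Data frame with columns `site_id`, `radius_m`, the class
#'   fractions `forest`, `reed`, `grassland`, `water`, `agriculture`,
#'   `urban_industrial` (each in `[0, 1]`, summing to at most 1),
#'   `edge_length_m`, and `dist_to_edge_m`, `dist_to_canal_m`,
#'   `dist_to_industry_m`.
#' @param radii Required buffer radii; every site must have one row per
#'   radius. Default `c(200, 500)` metres.
#' @return The validated table as a tibble.
#' @export
validate_landscape_table <- function(lt, radii = c(200, 500)) {
  lt <- as_tibble(lt)
  classes <- c("forest", "reed", "grassland", "water", "agriculture",
               "urban_industrial")
  need <- c("site_id", "radius_m", classes, "edge_length_m",
            "dist_to_edge_m", "dist_to_canal_m", "dist_to_industry_m")
  miss <- setdiff(need, names(lt))
  if (length(miss) > 0)
    abort(paste0("Landscape table missing column(s): ", paste(miss, collapse = ", ")))
  fr <- as.matrix(lt[classes])
  if (any(fr < 0 | fr > 1)) abort("Class fractions must lie in [0, 1].")
  if (any(rowSums(fr) > 1 + 1e-6))
    abort(paste0("Class fractions sum to > 1 at site(s): ",
                 paste(unique(lt$site_id[rowSums(fr) > 1 + 1e-6]), collapse = ", ")))
  dists <- as.matrix(lt[c("dist_to_edge_m", "dist_to_canal_m", "dist_to_industry_m")])
  if (any(dists < 0)) abort("Distances must be non-negative.")
  for (r in radii) {
    missing_sites <- setdiff(unique(lt$site_id), lt$site_id[lt$radius_m == r])
    if (length(missing_sites) > 0)
      abort(paste0("Site(s) lacking a ", r, " m buffer row: ",
                   paste(head(missing_sites, 5), collapse = ", ")))
  }
  lt
}
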