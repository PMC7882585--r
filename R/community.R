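#' Construct a community matrix
#'
#' A `community_matrix` is the central observable of the package: a sites x
#' species grid of non-negative integer abundances, with optional per-site
#' group labels (e.g. the reserve fragment each site belongs to). Species
#' whose column is all zero are retained (they matter for pooled-diversity
#' bookkeeping when sites are subset) but flagged in the `empty_species`
#' attribute.
#'
#' @param counts A numeric matrix or data frame of non-negative integers,
#'   sites as rows, species as columns. Row and column names are used as site
#'   and species labels when `site_ids` / `species_ids` are not given.
#' @param site_ids Character vector of unique site labels.
#' @param species_ids Character vector of unique species labels.
#' @param group Optional per-site categorical label (character or factor),
#'   recycled checks apply: length must equal the number of sites.
#'
#' @return An object of class `community_matrix`: the integer count matrix
#'   with `site_ids`, `species_ids`, `group` and `empty_species` attributes.
#' @export
#' @examples
#' cm <- community_matrix(rbind(a = c(3, 0), b = c(0, 5)),
#'                        species_ids = c("sp1", "sp2"))
#' site_totals(cm)
community_matrix <- function(counts, site_ids = NULL, species_ids = NULL,
                             group = NULL) {
  counts <- as.matrix(counts)
  site_ids <- site_ids %||% rownames(counts) %||% paste0("site", seq_len(nrow(counts)))
  species_ids <- species_ids %||% colnames(counts) %||% paste0("sp", seq_len(ncol(counts)))
  if (length(site_ids) != nrow(counts))
    abort("`site_ids` length must equal the number of rows of `counts`.")
  if (length(species_ids) != ncol(counts))
    abort("`species_ids` length must equal the number of columns of `counts`.")
  if (anyDuplicated(site_ids))
    abort(paste0("Duplicate site labels: ",
                 paste(unique(site_ids[duplicated(site_ids)]), collapse = ", ")))
  if (anyDuplicated(species_ids))
    abort(paste0("Duplicate species labels: ",
                 paste(unique(species_ids[duplicated(species_ids)]), collapse = ", ")))
  if (any(!is.finite(counts)))
    abort("Counts contain non-finite values.")
  if (any(counts < 0))
    abort("Counts must be non-negative.")
  if (any(abs(counts - round(counts)) > 1e-8))
    abort("Counts must be integers (individuals per species per site).")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  if (nrow(counts) > 0 && any(rowSums(counts) == 0))
    abort(paste0("Sites with no individuals: ",
                 paste(site_ids[rowSums(counts) == 0], collapse = ", ")))
  if (!is.null(group)) {
    if (length(group) != nrow(counts))
      abort("`group` length must equal the number of sites.")
    group <- as.character(group)
  }
  dimnames(counts) <- list(site_ids, species_ids)
  empty <- species_ids[colSums(counts) == 0]
  if (length(empty) > 0)
    inform(paste0("Retaining ", length(empty),
                  " all-zero species column(s): ",
                  paste(head(empty, 5), collapse = ", "),
                  if (length(empty) > 5) ", ..." else ""))
  structure(counts,
            class = c("community_matrix", "matrix"),
            group = group,
            empty_species = empty)
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("<community_matrix> ", nrow(x), " sites x ", ncol(x), " species, ",
      format(sum(x), big.mark = ","), " individuals\n", sep = "")
  if (!is.null(attr(x, "group")))
    cat("groups: ", paste(names(table(attr(x, "group"))), table(attr(x, "group")),
                          sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname community_matrix
#' @param cm A `community_matrix`.
#' @export
site_ids <- function(cm) rownames(cm)

#' @rdname community_matrix
#' @export
species_ids <- function(cm) colnames(cm)

#' @rdname community_matrix
#' @export
site_groups <- function(cm) attr(cm, "group")

#' @rdname community_matrix
#' @export
site_totals <- function(cm) rowSums(unclass(cm))

#' Subset a community matrix by site
#'
#' Keeps the full species set (columns) so that the gamma pool is unchanged;
#' newly emptied species columns are re-flagged, not dropped.
#'
#' @param cm A `community_matrix`.
#' @param sites Character vector of site labels or logical/integer index.
#' @return A `community_matrix` restricted to `sites`.
#' @export
subset_sites <- function(cm, sites) {
  idx <- if (is.character(sites)) match(sites, rownames(cm)) else
    seq_len(nrow(cm))[sites]
  if (anyNA(idx)) abort("Unknown site label(s) in `sites`.")
  g <- attr(cm, "group")
  suppressMessages(
    community_matrix(unclass(cm)[idx, , drop = FALSE],
                     group = if (!is.null(g)) g[idx])
  )
}

#' Read a community matrix from a delimited text file
#'
#' Reads a CSV or TSV abundance table (delimiter auto-detected, decimal point
#' only) into a validated [community_matrix()]. The first column must hold the
#' row labels. Orientation is canonicalised to sites-as-rows.
#'
#' @param path Path to a delimited text file with a header row.
#' @param orientation `"sites-rows"` (default) if rows are sites, or
#'   `"species-rows"` if rows are species (the table is transposed on read).
#' @param group Optional per-site group labels (applied after orientation is
#'   normalised).
#' @return A `community_matrix`.
#' @export
read_community_matrix <- function(path, orientation = c("sites-rows", "species-rows"),
                                  group = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- read_delim_auto(path)
  labels <- as.character(df[[1]])
  raw <- as.matrix(df[, -1, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                               dimnames = dimnames(raw)))
  ij <- which(is.na(m), arr.ind = TRUE)
  if (nrow(ij) > 0)
    abort(paste0("Cannot parse cell at row ", ij[1, 1] + 1L, ", column ",
                 ij[1, 2] + 1L, " of ", basename(path)))
  rownames(m) <- labels
  if (orientation == "species-rows") m <- t(m)
  cm <- community_matrix(m, group = group)
  inform(paste0("Read ", nrow(cm), " sites x ", ncol(cm), " species; ",
                sum(cm), " individuals."))
  cm
}

# Delimiter auto-detection between comma and tab; UTF-8; header mandatory.
read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  delim <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
               lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, name_repair = "minimal",
                    locale = readr::locale(decimal_mark = "."))
}

#' Align a community matrix with a site-level table
#'
#' Restricts both inputs to the (lexicographically ordered) intersection of
#' their site labels. Dropped sites are reported with a warning; an empty
#' intersection is an error.
#'
#' @param cm A `community_matrix`.
#' @param env A data frame with a `site_id` column (e.g. an environment
#'   table validated by [validate_env_table()]).
#' @return A list with elements `cm` and `env`, both in the same site order.
#' @export
align_tables <- function(cm, env) {
  stopifnot(inherits(cm, "community_matrix"))
  if (!"site_id" %in% names(env)) abort("`env` must have a `site_id` column.")
  common <- sort(intersect(rownames(cm), env$site_id))
  if (length(common) == 0) abort("No sites in common between the two tables.")
  dropped <- setdiff(union(rownames(cm), env$site_id), common)
  if (length(dropped) > 0)
    warn(paste0("Dropping sites absent from one table: ",
                paste(sort(dropped), collapse = ", ")))
  list(cm = subset_sites(cm, common),
       env = as_tibble(env)[match(common, env$site_id), , drop = FALSE])
}

#' Summarise species overlap between two groups of sites
#'
#' Counts species shared between, and exclusive to, each of two site groups,
#' together with per-group richness and the shared percentage of the pooled
#' species list. Singletons (species with exactly one individual in the
#' pooled data) are tallied among the exclusives.
#'
#' @param cm A `community_matrix` with a two-level `group` attribute, or
#'   supply `groups` explicitly.
#' @param groups Optional per-site group labels overriding the attribute.
#' @return A one-row tibble: `n_species`, `n_shared`, `shared_pct`, and for
#'   each group its label, richness and exclusive-species count.
#' @export
species_overlap <- function(cm, groups = NULL) {
  groups <- groups %||% site_groups(cm)
  if (is.null(groups)) abort("No group labels available.")
  lev <- sort(unique(groups))
  if (length(lev) != 2) abort("`species_overlap()` needs exactly two groups.")
  m <- unclass(cm)
  pres <- vapply(lev, function(g) colSums(m[groups == g, , drop = FALSE]) > 0,
                 logical(ncol(m)))
  observed <- rowSums(pres) > 0
  shared <- sum(pres[, 1] & pres[, 2])
  only1 <- sum(pres[, 1] & !pres[, 2])
  only2 <- sum(pres[, 2] & !pres[, 1])
  totals <- colSums(m)
  tibble(
    n_species = sum(observed),
    n_shared = shared,
    shared_pct = 100 * shared / sum(observed),
    group_a = lev[1], richness_a = sum(pres[, 1]), exclusive_a = only1,
    singletons_a = sum(pres[, 1] & !pres[, 2] & totals == 1),
    group_b = lev[2], richness_b = sum(pres[, 2]), exclusive_b = only2,
    singletons_b = sum(pres[, 2] & !pres[, 1] & totals == 1)
  )
}

#' Convert a community matrix to a long tibble
#'
#' @param x A `community_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `site_id`, `group` (if present), `species_id`
#'   and `count`.
#' @method as_tibble community_matrix
#' @export
as_tibble.community_matrix <- function(x, ...) {
  out <- tibble(
    site_id = rep(rownames(x), times = ncol(x)),
    species_id = rep(colnames(x), each = nrow(x)),
    count = as.vector(unclass(x))
  )
  g <- site_groups(x)
  if (!is.null(g)) out$group <- rep(g, times = ncol(x))
  out[order(out$site_id, out$species_id), c("site_id",
                                            if (!is.null(g)) "group",
                                            "species_id", "count")]
}
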