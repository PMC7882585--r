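#' Write a set of result tables with a manifest
#'
#' Writes each named table as a CSV file with stable column order and a
#' `manifest.json` recording the file names, row counts, and the run's seed
#' and configuration hash, so that a result bundle is self-describing and
#' re-runs can be compared byte for byte.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest (`NA` if the run had no
#'   stochastic stage).
#' @param config Optional list; a stable hash of its serialisation is stored.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, seed = NA_integer_, config = NULL) {
  if (length(tables) > 0 && (is.null(names(tables)) || any(names(tables) == "")))
    abort("`tables` must be a fully named list.")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste0("Cannot create directory: ", out_dir))
  files <- list()
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    tb <- as.data.frame(tables[[nm]])
    # fixed-format write: no scientific notation drift between runs
    readr::write_csv(tb, path, progress = FALSE)
    files[[nm]] <- list(file = paste0(nm, ".csv"), rows = nrow(tb))
  }
  manifest <- list(
    files = files,
    seed = if (is.na(seed)) NULL else as.integer(seed),
    config_hash = if (is.null(config)) NULL else config_hash(config),
    package = "fragbeta",
    version = as.character(utils::packageVersion("fragbeta"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Deterministic hash of a config list: serialize canonically, then sum a
# polynomial rolling hash over the bytes (no external digest dependency).
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  bytes <- as.integer(charToRaw(as.character(txt)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
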