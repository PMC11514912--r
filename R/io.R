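## Feature-table I/O, run configuration, and manifests.

canonical_columns <- c("id", "diameter_um", "te_count", "te_density",
                       "te_size_variance", "icm_area_um2", "ploidy")

#' Read a morphological feature table
#'
#' CSV with the canonical header `id, diameter_um, te_count, te_density,
#' te_size_variance, icm_area_um2, ploidy`; a `column_mapping` block absorbs
#' other header names. Ploidy strings are normalized case-insensitively to
#' euploid / mosaic / aneuploid and the binary outcome (euploid = 1,
#' mosaic and aneuploid = 0) is derived into `ploidy_binary`.
#'
#' @param path CSV file path.
#' @param column_mapping optional named character vector mapping canonical
#'   names to the file's column names, e.g.
#'   `c(te_count = "TE cell number")`.
#' @return data.frame with the canonical columns plus `ploidy_binary`.
#' @export
read_feature_table <- function(path, column_mapping = NULL) {
  if (!file.exists(path)) {
    stop("read_feature_table: no such file: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (canon in names(column_mapping)) {
    src <- column_mapping[[canon]]
    if (!src %in% names(raw)) {
      stop("read_feature_table: mapped column not found: ", src, call. = FALSE)
    }
    names(raw)[names(raw) == src] <- canon
  }
  missing <- setdiff(setdiff(canonical_columns, "id"), names(raw))
  if (length(missing)) {
    stop("read_feature_table: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"id" %in% names(raw)) raw$id <- sprintf("blastocyst_%04d", seq_len(nrow(raw)))
  tab <- raw[, c(canonical_columns,
                 intersect("maternal_age", names(raw))), drop = FALSE]
  pl <- tolower(trimws(tab$ploidy))
  known <- c("euploid", "mosaic", "aneuploid")
  bad <- setdiff(unique(pl), known)
  if (length(bad)) {
    stop("read_feature_table: unknown ploidy value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab$ploidy <- pl
  tab$ploidy_binary <- as.integer(pl == "euploid")
  num <- setdiff(canonical_columns, c("id", "ploidy"))
  for (cc in num) {
    tab[[cc]] <- as.numeric(tab[[cc]])
    if (anyNA(tab[[cc]])) {
      stop("read_feature_table: missing/non-numeric values in ", cc,
           call. = FALSE)
    }
  }
  if (any(tab$te_count < 0) || any(tab$te_count != round(tab$te_count))) {
    stop("read_feature_table: te_count must be a non-negative integer",
         call. = FALSE)
  }
  tab
}

#' Write a feature table with the canonical header
#' @param table data.frame (extra columns beyond the canonical set dropped).
#' @param path output CSV path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table[, intersect(canonical_columns, names(table))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All stage parameters with their documented defaults; serialized with the
#' run manifest so a run is reproducible byte-for-byte.
#'
#' @return nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    pixel_scale = 1,
    map_shape = c(256L, 512L),
    registration = list(ratio = 0.75, ransac_threshold_deg = 2,
                        ransac_max_iter = 1000, ransac_min_inliers = 6,
                        seed = 1L, refine = TRUE),
    segmentation = list(smoothing_sigma = 1, ridge_scale = 3,
                        icm_min_area_frac = 0.03),
    morphometry = list(min_cell_area_um2 = 10, sd_denominator = "n-1"),
    stats = list(welch = TRUE, alpha_enter = 0.05, alpha_remove = 0.10),
    predict = list(k = 5L, test_frac = 0.2, seeds = 1:5,
                   threshold_criterion = "topleft"),
    rules = list(te_count_threshold = 94, variance_threshold = 478,
                 icm_threshold = 8007)
  ), class = "run_config")
}

#' Read / write a run configuration (YAML)
#' @param path YAML file.
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(unclass(default_config()), yaml::read_yaml(path))
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a JSON run manifest (config hash, seeds, versions)
#' @param config the `run_config` used.
#' @param path output JSON path.
#' @param extra named list of extra fields (seeds, inputs, counts).
#' @export
write_manifest <- function(config, path, extra = list()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  jsonlite::write_json(c(list(
    package = "blastometry",
    version = as.character(utils::packageVersion("blastometry")),
    r_version = as.character(getRversion()),
    config_hash = unname(tools::md5sum(tmp)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
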