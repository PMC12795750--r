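#' Write the synthetic tables of one generated world to disk
#'
#' Writes `tracts.csv`, `blocks.csv`, `jem.csv`, `holc.csv`,
#' `mortgage.csv` and `ground_truth.json` (UTF-8, comma-separated,
#' header row) to `dir`. Coordinates are decimal degrees and all
#' proportions are decimals in `[0, 1]`.
#'
#' @param geo Output of [generate_geography()].
#' @param structural Output of [generate_structural()].
#' @param jem Output of [generate_jem()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_tables <- function(geo, structural, jem, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(geo$tracts, "tracts.csv")
  wr(geo$blocks, "blocks.csv")
  wr(jem, "jem.csv")
  wr(structural$holc, "holc.csv")
  wr(structural$mortgage, "mortgage.csv")
  write_ground_truth(geo$ground_truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' @rdname write_synthetic_tables
#' @param path Path of the ground-truth JSON file.
#' @param gt Ground-truth list as produced by [generate_geography()].
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_synthetic_tables
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$tracts <- as.data.frame(gt$tracts, stringsAsFactors = FALSE)
  gt
}

# Readers for the delimited tables. These double as the ingestion stubs
# for real inputs sharing the same column schema.

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")))
  df
}

#' Read pipeline input tables
#'
#' Column-checked readers for the tract, block, JEM, HOLC-overlap and
#' mortgage tables (CSV with header row). Real extracts with the same
#' schema can be read with the same functions.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_tracts <- function(path) {
  read_table_checked(path, c("tract_id", "metro_id", "ruca_code",
                             "population", "workers", race_columns(),
                             "pct_unemployed", "pct_low_income",
                             "pct_no_diploma", "pop_density",
                             "centroid_lat", "centroid_lon"))
}

#' @rdname read_tracts
#' @export
read_blocks <- function(path) {
  read_table_checked(path, c("block_id", "tract_id", "population", "laeq_24h"))
}

#' @rdname read_tracts
#' @export
read_jem <- function(path) {
  read_table_checked(path, c("group_id", "mean_twa", "sd_twa"))
}

#' @rdname read_tracts
#' @export
read_holc <- function(path) {
  read_table_checked(path, c("tract_id", "overlap_a", "overlap_b",
                             "overlap_c", "overlap_d", "total_graded"))
}

#' @rdname read_tracts
#' @export
read_mortgage <- function(path) {
  read_table_checked(path, c("tract_id", "loans_minority", "loans_total",
                             "households_minority", "households_total"))
}
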