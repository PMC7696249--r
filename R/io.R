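#' Screen table writers and readers
#'
#' Plain-text dialects shared by the simulator and the normalization
#' stage: UTF-8 CSV/TSV with a header row. The plate map carries the
#' layout (plate, well, role, compound, replicate, cell line, species);
#' the measurement file carries only (plate, well, luminescence); they
#' join on (plate_id, well).
#'
#' @param measurements combined well table from
#'   \code{\link{generate_screen}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return (invisibly) the paths written.
#' @name screen_io
NULL

#' @rdname screen_io
#' @export
write_screen_csv <- function(measurements, dir, prefix = "screen") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  map_path <- file.path(dir, paste0(prefix, "_plate_map.csv"))
  meas_path <- file.path(dir, paste0(prefix, "_measurements.csv"))
  map <- measurements[, c("plate_id", "well", "role", "compound_id",
                          "replicate", "cell_line", "species")]
  write.csv(map, map_path, row.names = FALSE, na = "")
  meas <- measurements[, c("plate_id", "well", "luminescence_rlu")]
  write.csv(meas, meas_path, row.names = FALSE)
  invisible(c(plate_map = map_path, measurements = meas_path))
}

#' @rdname screen_io
#' @param map_path,meas_path paths written by \code{write_screen_csv}.
#' @export
read_screen_csv <- function(map_path, meas_path) {
  map <- read.csv(map_path, stringsAsFactors = FALSE,
                  colClasses = c(compound_id = "character"))
  meas <- read.csv(meas_path, stringsAsFactors = FALSE)
  out <- merge(map, meas, by = c("plate_id", "well"), sort = FALSE)
  out$compound_id[out$compound_id == ""] <- NA_character_
  out
}

#' Write a compound annotation table
#'
#' @param annotation data frame (compound_id, name, targets, pathway).
#' @param path CSV path.
#' @export
write_annotation_csv <- function(annotation, path) {
  write.csv(annotation, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(compound_id = "character"))
}

#' Write a killing matrix (wide CSV + long TSV with QC flags)
#'
#' @param km a \code{\link{killing_matrix}}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return (invisibly) the paths written.
#' @export
write_killing_matrix <- function(km, dir, prefix = "killing") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide_path <- file.path(dir, paste0(prefix, "_matrix.csv"))
  long_path <- file.path(dir, paste0(prefix, "_long.tsv"))
  wide <- data.frame(cell_line = rownames(km$values),
                     species = unname(km$species),
                     km$values, check.names = FALSE)
  write.csv(wide, wide_path, row.names = FALSE)
  long <- data.frame(
    cell_line = rep(rownames(km$values), ncol(km$values)),
    species = rep(unname(km$species), ncol(km$values)),
    compound_id = rep(colnames(km$values), each = nrow(km$values)),
    percent_killing = as.vector(km$values),
    n_reps = as.vector(km$n_reps),
    qc_flag = as.vector(km$qc_flags), stringsAsFactors = FALSE)
  write.table(long, long_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(wide = wide_path, long = long_path))
}

#' @rdname write_killing_matrix
#' @param path wide-CSV path written by \code{write_killing_matrix}.
#' @export
read_killing_matrix <- function(path) {
  wide <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  v <- as.matrix(wide[, setdiff(names(wide), c("cell_line", "species"))])
  rownames(v) <- wide$cell_line
  killing_matrix(v, setNames(wide$species, wide$cell_line))
}
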