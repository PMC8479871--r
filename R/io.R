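#' Write a mesh in OFF format
#' @param mesh a [cell_mesh()].
#' @param path output path.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$nodes), nrow(mesh$triangles)), con)
  utils::write.table(format(mesh$nodes, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3, mesh$triangles - 1), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a mesh in ASCII PLY format
#'
#' Node attributes (`theta`, `phi`, adherence flag) are stored as extra
#' vertex properties.
#' @inheritParams write_mesh_off
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$nodes)),
               "property float x", "property float y", "property float z",
               "property float theta", "property float phi",
               "property uchar adherent",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  vdat <- cbind(mesh$nodes, mesh$theta, mesh$phi, as.integer(mesh$adherent))
  utils::write.table(format(vdat, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3, mesh$triangles - 1), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a signal field as CSV (one row per node, one column per time point)
#' @param signal a [signal_field()].
#' @param path output path.
#' @export
write_signal_csv <- function(signal, path) {
  df <- as.data.frame(signal$values)
  names(df) <- sprintf("t%g", signal_times(signal))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a signal field written by [write_signal_csv()]
#' @param path CSV path.
#' @param dt sampling interval in seconds.
#' @export
read_signal_csv <- function(path, dt) {
  df <- utils::read.csv(path, check.names = FALSE)
  t0 <- as.numeric(sub("^t", "", names(df)[1]))
  signal_field(as.matrix(df), dt = dt, t0 = t0)
}

#' Write scene ground truth as JSON
#' @param ground_truth the `ground_truth` element of [make_signal()].
#' @param path output path.
#' @param keep_activity store the full noiseless activity matrix (default
#'   `FALSE`; it can be large).
#' @export
write_ground_truth_json <- function(ground_truth, path,
                                    keep_activity = FALSE) {
  gt <- ground_truth
  if (!keep_activity) gt$activity <- NULL
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
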