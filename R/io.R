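#' Write a recording as a delimited matrix with a metadata sidecar
#'
#' The data file is a comma-delimited samples x channels matrix with a
#' header row of channel labels (plus an `ECG` column when a reference
#' channel is supplied). The sidecar is YAML carrying the sampling rate,
#' labels, seed and, when a planted ground truth is attached, its edge list.
#'
#' @param rec an `af_recording`.
#' @param path output file for the data matrix.
#' @param ecg optional reference ECG vector, written as column `ECG`.
#' @param meta_path sidecar path; default `<path>.meta.yaml`.
#' @param seed seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, ecg = NULL,
                            meta_path = paste0(path, ".meta.yaml"),
                            seed = NULL) {
  stopifnot(inherits(rec, "af_recording"))
  df <- as.data.frame(rec$data)
  if (!is.null(ecg)) df$ECG <- ecg
  data.table::fwrite(df, path)
  meta <- list(fs_hz = rec$fs_hz, labels = rec$labels, seed = seed)
  truth <- attr(rec, "truth")
  if (!is.null(truth)) {
    ut <- which(upper.tri(truth$adjacency) & truth$adjacency == 1,
                arr.ind = TRUE)
    meta$truth_edges <- apply(ut, 1, function(e)
      paste(e[1], e[2], truth$coupling[e[1], e[2]], sep = "\t"))
  }
  yaml::write_yaml(meta, meta_path)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path data file with a header row of channel labels.
#' @param fs_hz sampling rate; taken from the sidecar when present.
#' @param ecg_column name of the reference ECG column (dropped from the
#'   channel matrix and returned separately), or `NULL`.
#' @return List with `recording` (an `af_recording`) and `ecg` (vector or
#'   `NULL`).
#' @export
read_recording <- function(path, fs_hz = NULL, ecg_column = "ECG") {
  meta_path <- paste0(path, ".meta.yaml")
  if (is.null(fs_hz) && file.exists(meta_path))
    fs_hz <- yaml::read_yaml(meta_path)$fs_hz
  if (is.null(fs_hz)) stop_invalid("fs_hz not given and no metadata sidecar")
  df <- data.table::fread(path, data.table = FALSE)
  if (anyNA(df)) stop_invalid("recording contains missing values")
  ecg <- NULL
  if (!is.null(ecg_column) && ecg_column %in% names(df)) {
    ecg <- df[[ecg_column]]
    df[[ecg_column]] <- NULL
  }
  list(recording = af_recording(as.matrix(df), fs_hz), ecg = ecg)
}

#' Write an MI matrix as a square delimited matrix
#'
#' @param mi an `mi_matrix` (values in nats).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mi_matrix <- function(mi, path) {
  stopifnot(inherits(mi, "mi_matrix"))
  df <- as.data.frame(mi$values)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read an MI matrix written by [write_mi_matrix()]
#' @param path input path.
#' @return An `mi_matrix`.
#' @export
read_mi_matrix <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  v <- as.matrix(df)
  dimnames(v) <- list(names(df), names(df))
  structure(list(values = v, n_channels = ncol(v), labels = names(df),
                 window_index = NA_integer_),
            class = "mi_matrix")
}

#' Write a communication network as a tab-separated edge list
#'
#' Columns: `node_a`, `node_b`, `mi_nats` (the MI backing the edge when the
#' source matrix is supplied).
#'
#' @param net a `communication_network`.
#' @param path output path.
#' @param mi optional `mi_matrix` supplying edge weights.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, mi = NULL) {
  ut <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
  df <- data.frame(node_a = net$labels[ut[, 1]],
                   node_b = net$labels[ut[, 2]],
                   mi_nats = if (!is.null(mi)) mi$values[ut] else NA_real_)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
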