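#' Write / read a sensor stream as CSV with a JSON sidecar
#'
#' The CSV dialect has a header `t,ch1,...,chM` and one row per sample at
#' `1/sampling_rate` spacing; metadata (subject, activity, seed, rate, ADC
#' bits) goes to `<path>.json`.
#'
#' @param stream A `sensor_stream`.
#' @param path CSV path.
#' @return `read_stream_csv` returns a `sensor_stream`.
#' @export
write_stream_csv <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  M <- nrow(stream$values)
  df <- data.frame(t = (seq_len(ncol(stream$values)) - 1) /
                     stream$sampling_rate,
                   t(stream$values))
  names(df) <- c("t", paste0("ch", seq_len(M)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(stream$metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  rate <- meta$sampling_rate
  if (is.null(rate)) {
    dt <- diff(df$t)
    rate <- 1 / stats::median(dt)
  }
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  rownames(vals) <- NULL
  structure(list(values = vals, sampling_rate = rate, metadata = meta),
            class = "sensor_stream")
}

#' Write / read a labeled square matrix as TSV
#'
#' Used for likelihood and distance matrices: first column holds row ids,
#' header holds column ids.
#'
#' @param m Matrix.
#' @param path TSV path.
#' @return `read_matrix_tsv` returns a matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}

#' Write a dataset of streams plus a manifest
#'
#' @param streams List of `sensor_stream`s.
#' @param dir Output directory (created if missing).
#' @return Path of the manifest JSON (list of stream/sidecar paths).
#' @export
write_dataset <- function(streams, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(streams), function(i) {
    f <- file.path(dir, sprintf("stream_%04d.csv", i))
    write_stream_csv(streams[[i]], f)
    list(stream = basename(f), sidecar = paste0(basename(f), ".json"))
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE)
  manifest
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  lapply(manifest, function(e) read_stream_csv(file.path(dir, e$stream)))
}
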