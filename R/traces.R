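#' Calcium fluorescence trace set
#'
#' Container for a single imaging trial: a neurons x frames matrix of raw
#' fluorescence (arbitrary units) together with the acquisition metadata
#' needed by every downstream metric. Multi-neuron light-sheet trials are
#' typically 120 neurons sampled at 2 Hz for 10 min (1200 frames); AVA
#' single-neuron confocal trials are 1 neuron at 4 Hz.
#'
#' @param values numeric matrix, neurons x frames; finite and non-negative.
#' @param sampling_rate acquisition rate in Hz (volumes or images per second).
#' @param trial_id character scalar identifying the trial.
#' @param condition character scalar, e.g. genotype or day of adulthood.
#' @return An object of class `calcium_traces` with fields `values`,
#'   `sampling_rate`, `trial_id`, `condition`, `duration` (seconds).
#' @export
calcium_traces <- function(values, sampling_rate, trial_id = "trial",
                           condition = "unknown") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("trace matrix must have at least one neuron and one frame", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("fluorescence values must all be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("fluorescence values must be non-negative", call. = FALSE)
  }
  structure(
    list(
      values = values,
      sampling_rate = as.numeric(sampling_rate),
      trial_id = as.character(trial_id),
      condition = as.character(condition),
      duration = ncol(values) / as.numeric(sampling_rate)
    ),
    class = "calcium_traces"
  )
}

#' @export
print.calcium_traces <- function(x, ...) {
  cat(sprintf(
    "<calcium_traces> %s (%s): %d neurons x %d frames @ %g Hz (%.1f s)\n",
    x$trial_id, x$condition, nrow(x$values), ncol(x$values),
    x$sampling_rate, x$duration
  ))
  invisible(x)
}

#' Number of neurons / frames in a trace set
#' @param traces a `calcium_traces` object.
#' @return integer count.
#' @export
n_neurons <- function(traces) nrow(traces$values)

#' @rdname n_neurons
#' @export
n_frames <- function(traces) ncol(traces$values)

#' Read a trace matrix from disk
#'
#' Two dialects are supported. CSV: one neuron per row, first column a neuron
#' id, remaining columns frames; metadata (`sampling_rate_hz`, `condition`,
#' `trial_id`) lives in a JSON sidecar `<path>.json` (or is passed via
#' `metadata`). HDF5: dataset `traces` (neurons x frames) with the same keys
#' as HDF5 attributes.
#'
#' @param path file path.
#' @param format `"csv"` or `"hdf5"`; default guessed from the extension.
#' @param metadata optional named list overriding/supplying metadata.
#' @return A [calcium_traces()] object; row order as stored.
#' @export
load_traces <- function(path, format = c("auto", "csv", "hdf5"),
                        metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "csv"
  }
  if (format == "csv") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty trace file: ", path, call. = FALSE)
    parts <- strsplit(lines, ",", fixed = TRUE)
    lens <- lengths(parts)
    if (length(unique(lens)) != 1L) {
      stop("ragged CSV: rows have differing numbers of fields", call. = FALSE)
    }
    ids <- vapply(parts, `[[`, "", 1L)
    vals <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                     numeric(lens[[1L]] - 1L)))
    if (any(is.na(vals))) stop("non-numeric fluorescence entries in ", path, call. = FALSE)
    rownames(vals) <- ids
    meta <- list()
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta <- utils::modifyList(meta, as.list(metadata %||% list()))
    if (is.null(meta$sampling_rate_hz)) {
      stop("missing metadata: sampling_rate_hz (sidecar JSON or `metadata`)", call. = FALSE)
    }
    calcium_traces(vals, meta$sampling_rate_hz,
                   trial_id = meta$trial_id %||% basename(path),
                   condition = meta$condition %||% "unknown")
  } else {
    vals <- rhdf5::h5read(path, "traces")
    attrs <- rhdf5::h5readAttributes(path, "traces")
    meta <- utils::modifyList(attrs, as.list(metadata %||% list()))
    if (is.null(meta$sampling_rate_hz)) {
      stop("missing HDF5 attribute: sampling_rate_hz", call. = FALSE)
    }
    calcium_traces(vals, as.numeric(meta$sampling_rate_hz),
                   trial_id = as.character(meta$trial_id %||% basename(path)),
                   condition = as.character(meta$condition %||% "unknown"))
  }
}

#' Write a trace set to disk
#'
#' Inverse of [load_traces()]; CSV gets a JSON metadata sidecar, HDF5 stores
#' metadata as attributes of the `traces` dataset.
#'
#' @param traces a `calcium_traces` object.
#' @param path destination path.
#' @param format `"csv"` or `"hdf5"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, format = c("auto", "csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "csv"
  }
  meta <- list(sampling_rate_hz = traces$sampling_rate,
               trial_id = traces$trial_id, condition = traces$condition)
  if (format == "csv") {
    ids <- rownames(traces$values) %||% paste0("n", seq_len(nrow(traces$values)))
    lines <- vapply(seq_len(nrow(traces$values)), function(i) {
      paste(c(ids[i], format(traces$values[i, ], digits = 17)), collapse = ",")
    }, "")
    writeLines(lines, path)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(traces$values, path, "traces")
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, "traces")
    for (k in names(meta)) rhdf5::h5writeAttribute(meta[[k]], did, k)
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Downsample a trace set by an integer factor
#'
#' Keeps every `factor`-th frame starting from the first, and divides the
#' sampling rate accordingly. Used for acquisition-rate robustness checks
#' (e.g. 2 Hz recordings reduced to 1 and 0.5 Hz).
#'
#' @param traces a `calcium_traces` object.
#' @param factor positive integer decimation factor (1 = identity).
#' @return A new `calcium_traces` object.
#' @export
downsample <- function(traces, factor) {
  stopifnot(inherits(traces, "calcium_traces"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(traces)
  keep <- seq(1L, n_frames(traces), by = factor)
  if (length(keep) < 2L) stop("too few frames after downsampling", call. = FALSE)
  calcium_traces(traces$values[, keep, drop = FALSE],
                 traces$sampling_rate / factor,
                 trial_id = traces$trial_id, condition = traces$condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
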