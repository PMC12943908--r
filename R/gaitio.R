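#' Construct an IMU acceleration sequence
#'
#' Container for a uniformly sampled tri-axial accelerometer record, the raw
#' material of the stride-length pipeline. All three channels must have the
#' same length; if timestamps are supplied they must step by `dt` (within
#' 1e-6 s), otherwise they are synthesized as `(0:(n-1)) * dt`.
#'
#' @param ax,ay,az Numeric vectors of acceleration in m/s^2 (one per axis).
#' @param dt Sampling interval in seconds (default 0.02, i.e. 50 Hz).
#' @param timestamps Optional numeric vector of sample times in seconds.
#' @param channel_meta Optional free-text annotations (units, axis notes).
#' @return An object of class `imu_sequence`.
#' @export
imu_sequence <- function(ax, ay, az, dt = 0.02, timestamps = NULL,
                         channel_meta = NULL) {
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(ax)
  if (n < 1L) stop("empty sequence: need at least 1 sample")
  if (length(ay) != n || length(az) != n)
    stop("channel length mismatch: ax/ay/az must have identical length")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  if (is.null(timestamps)) {
    timestamps <- (seq_len(n) - 1) * dt
  } else {
    timestamps <- as.numeric(timestamps)
    if (length(timestamps) != n)
      stop("timestamps length does not match channel length")
    if (n > 1L && max(abs(diff(timestamps) - dt)) >= 1e-6)
      stop("sampling-interval mismatch: timestamps do not step by dt")
  }
  structure(list(timestamps = timestamps, ax = ax, ay = ay, az = az,
                 dt = dt, channel_meta = channel_meta),
            class = "imu_sequence")
}

#' @export
length.imu_sequence <- function(x) length(x$ax)

#' @export
print.imu_sequence <- function(x, ...) {
  cat(sprintf("<imu_sequence> %d samples @ %g s (%.1f Hz), %.2f s total\n",
              length(x), x$dt, 1 / x$dt, length(x) * x$dt))
  invisible(x)
}

#' Read an IMU log from delimited text
#'
#' Parses a CSV with a header into an [imu_sequence]. Unparseable cells are an
#' error (with the offending row reported), never silently dropped. An
#' optional scale factor converts recorded units to m/s^2 (e.g. 9.81 for
#' logs recorded in g).
#'
#' @param path Path to the CSV file.
#' @param dt Expected sampling interval in seconds.
#' @param column_map Named character vector mapping the internal channel names
#'   `time`, `ax`, `ay`, `az` to the file's column names. The `time` entry is
#'   optional; when absent, timestamps are synthesized.
#' @param scale Multiplier applied to the acceleration channels (default 1).
#' @return An [imu_sequence].
#' @export
read_imu_csv <- function(path, dt = 0.02,
                         column_map = c(time = "time", ax = "ax",
                                        ay = "ay", az = "az"),
                         scale = 1.0) {
  if (!file.exists(path)) stop("missing file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) < 1L) stop("empty sequence: file ", path, " has no data rows")
  need <- c("ax", "ay", "az")
  for (ch in need) {
    col <- column_map[[ch]]
    if (is.null(col) || !col %in% names(raw))
      stop("missing column '", col, "' (mapped to ", ch, ") in ", path)
  }
  parse_col <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad))
      stop("non-numeric cell in column '", col, "' at data row ", bad[1L])
    v
  }
  ts <- NULL
  tcol <- column_map[["time"]]
  if (!is.null(tcol) && !is.na(tcol) && tcol %in% names(raw))
    ts <- parse_col(tcol)
  imu_sequence(ax = parse_col(column_map[["ax"]]) * scale,
               ay = parse_col(column_map[["ay"]]) * scale,
               az = parse_col(column_map[["az"]]) * scale,
               dt = dt, timestamps = ts)
}

#' Write an IMU sequence as CSV
#'
#' @param seq An [imu_sequence].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(seq, path) {
  stopifnot(inherits(seq, "imu_sequence"))
  df <- data.frame(time = seq$timestamps, ax = seq$ax, ay = seq$ay,
                   az = seq$az)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a validated stride-event index
#'
#' Gait-event sample indices delimiting stride cycles: two consecutive
#' indices define the start and end of one stride. Indices are 0-based (the
#' convention of the event files) and strictly increasing; at least two are
#' required to define one stride.
#'
#' @param indices Integer vector of 0-based sample indices.
#' @param n_samples Length of the sequence the events refer to.
#' @return An object of class `stride_events`.
#' @export
stride_events <- function(indices, n_samples) {
  indices <- as.integer(round(as.numeric(indices)))
  if (length(indices) < 2L)
    stop("fewer than 2 indices: need at least 2 events to define a stride")
  if (any(diff(indices) <= 0L))
    stop("non-monotone event list: indices must be strictly increasing")
  if (indices[1L] < 0L || indices[length(indices)] > n_samples - 1L)
    stop("index out of range: events must lie in [0, ", n_samples - 1L, "]")
  structure(list(indices = indices, n_samples = as.integer(n_samples)),
            class = "stride_events")
}

#' Read a stride-event file
#'
#' One integer per line (or a single CSV column). Files may be 0-based
#' (default) or 1-based (`one_based = TRUE`, converted on read).
#'
#' @param path Path to the event file.
#' @param n_samples Length of the associated [imu_sequence].
#' @param one_based Set `TRUE` for files using 1-based indexing.
#' @return A [stride_events] object (0-based internally).
#' @export
read_stride_events <- function(path, n_samples, one_based = FALSE) {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("fewer than 2 indices: empty event file")
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals))
    stop("non-numeric event index at line ", which(is.na(vals))[1L])
  if (one_based) vals <- vals - 1
  stride_events(vals, n_samples)
}

#' Write stride events to a plain-text file (one 0-based index per line)
#' @param events A [stride_events] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stride_events <- function(events, path) {
  stopifnot(inherits(events, "stride_events"))
  writeLines(as.character(events$indices), path)
  invisible(path)
}

#' Cut a sequence channel into stride segments
#'
#' Segment i spans the half-open interval `[indices[i], indices[i+1])`, so
#' strides tile the record without overlap and segment lengths sum to
#' `indices[last] - indices[first]`.
#'
#' @param seq An [imu_sequence] (or a bare numeric vector).
#' @param events A [stride_events] object.
#' @param channel Which axis carries the measurement: `"ax"`, `"ay"` or
#'   `"az"` (default `"az"`). Ignored when `seq` is a bare vector.
#' @return A list of `stride_segment` objects with fields `stride_id`,
#'   `start`, `end` (0-based, half-open) and `samples`.
#' @export
segment_strides <- function(seq, events, channel = c("az", "ay", "ax")) {
  stopifnot(inherits(events, "stride_events"))
  if (inherits(seq, "imu_sequence")) {
    channel <- match.arg(channel)
    x <- seq[[channel]]
  } else {
    x <- as.numeric(seq)
  }
  idx <- events$indices
  if (idx[length(idx)] > length(x) - 1L)
    stop("index out of range: events exceed sequence length")
  lens <- diff(idx)
  if (any(lens < 3L))
    stop("segment shorter than 3 samples (stride ", which(lens < 3L)[1L], ")")
  lapply(seq_len(length(idx) - 1L), function(i) {
    structure(list(stride_id = i, start = idx[i], end = idx[i + 1L],
                   samples = x[(idx[i] + 1L):idx[i + 1L]]),
              class = "stride_segment")
  })
}

#' Build a per-stride estimate table
#'
#' Pairs estimated stride lengths with optional reference lengths and the
#' resulting absolute relative error in percent. `error_percent` is present
#' exactly when a nonzero reference is present.
#'
#' @param estimated_length Numeric vector of estimates (m), all >= 0.
#' @param reference_length Optional numeric vector of ground-truth lengths (m).
#' @param stride_id Optional integer ids (default `1:n`).
#' @return A `data.frame` with columns `stride_id`, `estimated_length`,
#'   `reference_length`, `error_percent`.
#' @export
stride_estimates <- function(estimated_length, reference_length = NULL,
                             stride_id = seq_along(estimated_length)) {
  estimated_length <- as.numeric(estimated_length)
  if (any(estimated_length < 0))
    stop("estimated_length must be non-negative")
  n <- length(estimated_length)
  if (is.null(reference_length)) reference_length <- rep(NA_real_, n)
  if (length(reference_length) != n)
    stop("reference_length length mismatch")
  ep <- ifelse(!is.na(reference_length) & reference_length != 0,
               abs(reference_length - estimated_length) /
                 abs(reference_length) * 100, NA_real_)
  data.frame(stride_id = as.integer(stride_id),
             estimated_length = estimated_length,
             reference_length = as.numeric(reference_length),
             error_percent = ep)
}

#' Write / read stride-estimate tables
#'
#' CSV with header `stride_id,estimated_length,reference_length,error_percent`.
#' Floats round-trip at full precision.
#'
#' @param estimates A data.frame as produced by [stride_estimates()].
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, the data.frame.
#' @export
write_estimates <- function(estimates, path) {
  need <- c("stride_id", "estimated_length", "reference_length",
            "error_percent")
  stopifnot(all(need %in% names(estimates)))
  df <- estimates[, need]
  for (cl in need[-1L]) df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stride_id", "estimated_length", "reference_length",
            "error_percent")
  if (!all(need %in% names(df)))
    stop("estimate file lacks required columns")
  df$stride_id <- as.integer(df$stride_id)
  for (cl in need[-1L]) df[[cl]] <- as.numeric(df[[cl]])
  df[, need]
}
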