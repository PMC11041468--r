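#' Device profile for a numeric-logging monitor
#'
#' Describes how one bedside device's interleaved numeric packets map onto
#' CRM data types: which packet field carries which data type, the native
#' packet rate (0.5 Hz for the study monitors), and the symbolic artifact
#' tokens the device may interlace per data type.
#'
#' @param device_id opaque device identifier.
#' @param mapping named character vector `c(field = data_type)` covering every
#'   data type the device emits.
#' @param native_rate packet rate in Hz; must be positive.
#' @param tokens character vector (or named list per data type) of artifact
#'   tokens the device emits.
#' @return A list of class `device_profile`.
#' @examples
#' device_profile("oximeter", c(spo2 = "SpO2", pr = "PR", alarm = "SpO2Alarm"))
#' @export
device_profile <- function(device_id, mapping, native_rate = 0.5,
                           tokens = c("NaN", "^^", "5")) {
  stopifnot(native_rate > 0, length(mapping) > 0, !is.null(names(mapping)))
  structure(list(device_id = device_id, mapping = mapping,
                 native_rate = native_rate, tokens = tokens),
            class = "device_profile")
}

#' Read a device profile from YAML
#'
#' Expects keys `device_id`, `mapping` (field: data_type), `native_rate`,
#' `tokens`.
#'
#' @param path YAML file path.
#' @return A [device_profile()].
#' @export
read_device_profile <- function(path) {
  y <- yaml::read_yaml(path)
  device_profile(y$device_id, unlist(y$mapping),
                 native_rate = if (is.null(y$native_rate)) 0.5 else y$native_rate,
                 tokens = if (is.null(y$tokens)) c("NaN", "^^", "5")
                          else as.character(unlist(y$tokens)))
}

#' Parse an interleaved monitor log into per-type streams
#'
#' Each row of `records` is one packet produced by the monitor at its native
#' rate; columns are a `time` stamp (seconds) plus one column per packet
#' field. Fields are routed to data types via the profile mapping; a missing
#' entry (`NA`) becomes the `"NaN"` token. Unmapped columns are skipped with
#' a warning; non-monotone packet times are an error.
#'
#' @param records data.frame of raw packets with a `time` column.
#' @param profile a [device_profile()].
#' @param patient_id patient identifier attached to every stream.
#' @return Named list of [vs_stream()], one per mapped data type, at the
#'   native rate with `sq_type = "null"`.
#' @export
parse_monitor_log <- function(records, profile, patient_id = "P00") {
  stopifnot(is.data.frame(records), "time" %in% names(records))
  tm <- as.numeric(records$time)
  if (nrow(records) > 1 && any(diff(tm) <= 0)) {
    stop("non-monotone packet times in monitor log", call. = FALSE)
  }
  fields <- setdiff(names(records), "time")
  unknown <- setdiff(fields, names(profile$mapping))
  if (length(unknown)) {
    warning("skipping unmapped packet field(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (f in intersect(names(profile$mapping), fields)) {
    v <- as.character(records[[f]])
    v[is.na(v) | v == ""] <- "NaN"
    dt <- profile$mapping[[f]]
    out[[dt]] <- vs_stream(v, data_type = dt, timestamp = tm,
                           sampling_rate = profile$native_rate,
                           patient_id = patient_id,
                           device_id = profile$device_id)
  }
  out
}

#' Upsample a native 0.5 Hz stream to 1 Hz
#'
#' Synchronization resamples every stream onto the common 1-second grid by
#' zero-order hold: each native sample is duplicated. Categorical alarm codes
#' and symbolic artifact tokens must never be averaged, so the hold rule is
#' the default for all types; linear interpolation for purely numeric streams
#' is available behind `method = "linear"` (symbolic samples still hold).
#' Output length is exactly twice the input length.
#'
#' @param stream a [vs_stream()] at 0.5 Hz.
#' @param method `"hold"` (default) or `"linear"`.
#' @return A [vs_stream()] at 1 Hz on an integer-second grid.
#' @export
upsample_to_1hz <- function(stream, method = c("hold", "linear")) {
  method <- match.arg(method)
  if (abs(stream$sampling_rate - 0.5) > 1e-9) {
    stop("upsample_to_1hz expects a 0.5 Hz input stream", call. = FALSE)
  }
  n <- length(stream$value)
  value <- rep(stream$value, each = 2)
  if (method == "linear" && n > 1) {
    num <- stream_values(stream)
    # midpoint between consecutive numeric samples; tokens keep the hold
    mid <- (num[-n] + num[-1]) / 2
    pos <- seq(2, 2 * n - 2, by = 2)
    ok <- !is.na(mid)
    value[pos][ok] <- as.character(mid[ok])
  }
  ts <- if (n == 0) numeric(0) else stream$timestamp[1] + seq.int(0, 2 * n - 1)
  out <- stream
  out$value <- value
  out$timestamp <- as.numeric(ts)
  out$sampling_rate <- 1
  if (!identical(stream$sq_type, "null")) {
    out$sq_value <- rep(stream$sq_value, each = 2)
  }
  out
}

#' Attach the default signal-quality annotation
#'
#' Monitors in this setting emit no explicit SQ stream, so acquisition
#' assigns every sample a default binary SQ value of 1 (trusted). Streams
#' that already carry a derived (non-null) SQ annotation must not be
#' overwritten and raise an error.
#'
#' @param stream a [vs_stream()] with `sq_type = "null"`.
#' @return The stream with `sq_type = "binary"` and all `sq_value = 1`.
#' @export
attach_default_sqi <- function(stream) {
  if (!identical(stream$sq_type, "null")) {
    stop("stream already carries a derived SQ annotation; refusing to overwrite",
         call. = FALSE)
  }
  set_sqi(stream, "binary", rep(1, length(stream$value)))
}

#' Acquire a session: parse, synchronize, annotate
#'
#' Full acquisition for one patient session across one or more devices:
#' parse each device's packet log, align devices at their first packets,
#' truncate to the common time span (with a warning when lengths differ),
#' upsample everything to the shared 1 Hz grid, and attach the default
#' binary SQ annotation.
#'
#' @param sessions either a named list of raw-packet data.frames (one per
#'   device, names matching `profiles`), or a named list of native-rate
#'   [vs_stream()] lists as produced by [parse_monitor_log()]/the simulator.
#' @param profiles named list of [device_profile()] (required when `sessions`
#'   holds raw packet data.frames).
#' @param patient_id patient identifier.
#' @return Named list of 1 Hz [vs_stream()] keyed by data type, all on one
#'   timestamp grid.
#' @export
acquire <- function(sessions, profiles = NULL, patient_id = "P00") {
  streams <- list()
  for (dev in names(sessions)) {
    el <- sessions[[dev]]
    if (is.data.frame(el)) {
      stopifnot(!is.null(profiles[[dev]]))
      streams <- c(streams, parse_monitor_log(el, profiles[[dev]], patient_id))
    } else {
      streams <- c(streams, el)
    }
  }
  lens <- vapply(streams, function(s) length(s$value), integer(1))
  n <- min(lens)
  if (any(lens != n)) {
    warning("session streams differ in length; truncating to common span of ",
            n, " native samples", call. = FALSE)
    streams <- lapply(streams, function(s) {
      keep <- seq_len(n)
      s$value <- s$value[keep]
      s$timestamp <- s$timestamp[1] + (keep - 1) / s$sampling_rate
      if (!identical(s$sq_type, "null")) s$sq_value <- s$sq_value[keep]
      s
    })
  }
  streams <- lapply(streams, function(s) {
    s$timestamp <- s$timestamp - s$timestamp[1]  # align first packets
    attach_default_sqi(upsample_to_1hz(s))
  })
  streams
}
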