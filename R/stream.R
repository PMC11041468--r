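#' Controlled-vocabulary registry for streams
#'
#' The common reference model (CRM) constrains every stream to a controlled
#' vocabulary: a set of known data types, a set of symbolic artifact tokens
#' that monitors interlace into numeric streams, and a set of signal-quality
#' (SQ) types, each with a value domain. `"binary"` is the rank set `{0, 1}`.
#' The registry is an ordinary list so new vocabularies (for other monitors)
#' can be added without touching the validators.
#'
#' @param data_types character vector of admissible `data_type` strings.
#' @param tokens character vector of symbolic artifact tokens that may appear
#'   verbatim in stream values (e.g. `"NaN"`, `"^^"`, `"5"`).
#' @param sq_types named list of SQ-type validators. Each element is a
#'   function of one numeric vector returning a logical vector (`TRUE` where
#'   the value is inside the domain), or `NULL` for the "null" type which
#'   carries no values.
#' @return A list of class `crm_registry`.
#' @examples
#' reg <- crm_registry()
#' names(reg$sq_types)
#' @export
crm_registry <- function(data_types = c("SpO2", "HR", "PR", "SpO2Alarm",
                                        "SpO2Med"),
                         tokens = c("NaN", "^^", "5"),
                         sq_types = NULL) {
  base_sq <- list(
    binary      = function(v) v %in% c(0, 1),
    rank        = function(v) is.finite(v) & v >= 0 & v == floor(v),
    categorical = function(v) !is.na(v),
    null        = NULL
  )
  if (!is.null(sq_types)) {
    for (nm in names(sq_types)) base_sq[[nm]] <- sq_types[[nm]]
  }
  structure(list(data_types = data_types, tokens = tokens,
                 sq_types = base_sq),
            class = "crm_registry")
}

#' Read a controlled-vocabulary registry from YAML or JSON
#'
#' The file may define `data_types`, `tokens`, and `sq_types`. Each entry of
#' `sq_types` is either the string `"null"` (no values) or a list with a
#' `domain` of explicit admissible values; unlisted SQ types keep their
#' built-in validators.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A `crm_registry`.
#' @export
read_registry <- function(path) {
  cfgy <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  sq <- NULL
  if (!is.null(cfgy$sq_types)) {
    sq <- lapply(cfgy$sq_types, function(d) {
      if (is.null(d) || identical(d, "null")) return(NULL)
      dom <- unlist(d$domain)
      function(v) v %in% dom
    })
  }
  crm_registry(
    data_types = if (is.null(cfgy$data_types)) c("SpO2", "HR", "PR", "SpO2Alarm", "SpO2Med")
                 else as.character(unlist(cfgy$data_types)),
    tokens = if (is.null(cfgy$tokens)) c("NaN", "^^", "5")
             else as.character(unlist(cfgy$tokens)),
    sq_types = sq
  )
}

#' Construct a vital-sign numeric stream
#'
#' A `vs_stream` is the CRM container for one uniformly sampled numeric
#' channel from one device: SpO2 (%), heart or pulse rate (bpm), or an alarm
#' status code. Values are stored verbatim as character so that symbolic
#' artifact tokens interlaced by the monitor (`"NaN"`, `"^^"`, `"5"`) survive
#' every transform untouched; [stream_values()] gives the numeric view. The
#' whole stream carries a single SQ type; per-sample SQ values live in
#' `sq_value`.
#'
#' @param value numeric or character vector of sample values; symbolic tokens
#'   are kept verbatim.
#' @param data_type controlled data-type string, e.g. `"SpO2"`.
#' @param timestamp numeric vector of sample times in seconds since session
#'   start; defaults to a 0-based grid at `sampling_rate`.
#' @param sampling_rate sampling rate in Hz (0.5 for the study monitors'
#'   native numerics, 1 after acquisition).
#' @param patient_id,device_id opaque identifier strings.
#' @param sq_type SQ type of the whole stream: `"binary"`, `"rank"`,
#'   `"categorical"` or `"null"` (no quality annotation yet).
#' @param sq_value numeric vector of per-sample SQ values, or `NULL` when
#'   `sq_type = "null"`.
#' @return An object of class `vs_stream`.
#' @examples
#' s <- vs_stream(c(96, "^^", 95), "SpO2", sampling_rate = 1)
#' stream_values(s)
#' @export
vs_stream <- function(value, data_type,
                      timestamp = NULL, sampling_rate = 1,
                      patient_id = "P00", device_id = "D00",
                      sq_type = "null", sq_value = NULL) {
  value <- as.character(value)
  if (is.null(timestamp)) {
    timestamp <- (seq_along(value) - 1) / sampling_rate
  }
  stopifnot(length(timestamp) == length(value))
  if (identical(sq_type, "null")) {
    sq_value <- NULL
  } else {
    stopifnot(length(sq_value) == length(value))
    sq_value <- as.numeric(sq_value)
  }
  structure(list(patient_id = patient_id, device_id = device_id,
                 data_type = data_type, sampling_rate = sampling_rate,
                 timestamp = as.numeric(timestamp), value = value,
                 sq_type = sq_type, sq_value = sq_value),
            class = "vs_stream")
}

#' Numeric view of a stream's values
#'
#' Symbolic artifact tokens (and the `"NaN"` missing marker) map to `NA`;
#' genuinely numeric samples are returned as numbers. Values are never
#' rewritten in place: this is a view.
#'
#' @param stream a [vs_stream()].
#' @return numeric vector, `NA` where the sample is symbolic.
#' @export
stream_values <- function(stream) {
  v <- suppressWarnings(as.numeric(stream$value))
  v[!is.finite(v)] <- NA_real_
  v
}

#' @export
length.vs_stream <- function(x) length(x$value)

#' @export
print.vs_stream <- function(x, ...) {
  cat(sprintf("<vs_stream> %s  patient=%s device=%s  %d samples @ %g Hz  SQ=%s\n",
              x$data_type, x$patient_id, x$device_id, length(x$value),
              x$sampling_rate, x$sq_type))
  n <- min(6L, length(x$value))
  if (n > 0) {
    head_df <- data.frame(timestamp = x$timestamp[seq_len(n)],
                          value = x$value[seq_len(n)])
    if (!identical(x$sq_type, "null")) head_df$sq_value <- x$sq_value[seq_len(n)]
    print(head_df, row.names = FALSE)
    if (length(x$value) > n) cat("  ...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.vs_stream <- function(x, ...) {
  df <- data.frame(patient_id = x$patient_id, device_id = x$device_id,
                   data_type = x$data_type, timestamp = x$timestamp,
                   value = x$value, stringsAsFactors = FALSE)
  if (!identical(x$sq_type, "null")) {
    df$sq_type <- x$sq_type
    df$sq_value <- x$sq_value
  }
  df
}

# internal: replace the SQ annotation, leaving values untouched
set_sqi <- function(stream, sq_type, sq_value) {
  stream$sq_type <- sq_type
  stream$sq_value <- as.numeric(sq_value)
  stream
}

# internal: TRUE where a sample is usable for arithmetic (numeric value and
# non-zero SQ; null SQ counts as usable)
valid_mask <- function(stream) {
  ok <- !is.na(stream_values(stream))
  if (!identical(stream$sq_type, "null")) ok <- ok & stream$sq_value != 0
  ok
}

#' Validate a stream against the CRM invariants
#'
#' Checks the container invariants of the common reference model and returns
#' violations instead of raising: timestamps non-negative, strictly
#' increasing, on a constant grid of `1/sampling_rate`; every value numeric
#' or a registered token; the SQ type registered and every SQ value inside
#' its domain. Each violation names the offending sample index (1-based) and
#' the rule.
#'
#' @param stream a [vs_stream()].
#' @param registry a [crm_registry()].
#' @return character vector of violation descriptions; empty when valid.
#' @examples
#' s <- vs_stream(c(96, 95), "SpO2", sq_type = "binary", sq_value = c(1, 2))
#' validate_stream(s)
#' @export
validate_stream <- function(stream, registry = crm_registry()) {
  out <- character(0)
  n <- length(stream$value)
  if (!stream$data_type %in% registry$data_types) {
    out <- c(out, sprintf("data_type '%s' not in registry", stream$data_type))
  }
  if (n == 0) return(out)
  bad_ts <- which(stream$timestamp < 0)
  for (i in bad_ts) out <- c(out, sprintf("sample %d: negative timestamp", i))
  if (n > 1) {
    d <- diff(stream$timestamp)
    step <- 1 / stream$sampling_rate
    bad <- which(abs(d - step) > 1e-9)
    for (i in bad) {
      rule <- if (d[i] <= 0) "timestamps not strictly increasing"
              else "timestamp spacing != 1/sampling_rate"
      out <- c(out, sprintf("sample %d: %s", i + 1L, rule))
    }
  }
  num <- suppressWarnings(as.numeric(stream$value))
  symbolic <- !is.finite(num)
  bad_val <- which(symbolic & !(stream$value %in% registry$tokens))
  for (i in bad_val) {
    out <- c(out, sprintf("sample %d: value '%s' neither numeric nor a registered token",
                          i, stream$value[i]))
  }
  if (!stream$sq_type %in% names(registry$sq_types)) {
    out <- c(out, sprintf("sq_type '%s' not in registry", stream$sq_type))
    return(out)
  }
  dom <- registry$sq_types[[stream$sq_type]]
  if (identical(stream$sq_type, "null")) {
    if (!is.null(stream$sq_value)) {
      out <- c(out, "sq_type 'null' must not carry sq_value")
    }
  } else if (is.null(stream$sq_value)) {
    out <- c(out, sprintf("sq_type '%s' requires per-sample sq_value", stream$sq_type))
  } else if (!is.null(dom)) {
    bad_sq <- which(!dom(stream$sq_value))
    for (i in bad_sq) {
      out <- c(out, sprintf("sample %d: sq_value %s outside '%s' domain",
                            i, format(stream$sq_value[i]), stream$sq_type))
    }
  }
  out
}

#' Read a stream from delimited text
#'
#' Canonical on-disk formats are CSV (columns `patient_id`, `device_id`,
#' `data_type`, `timestamp`, `value`, and, unless the stream carries no SQ
#' annotation, `sq_type`, `sq_value`) and JSON-lines with one record per
#' sample using the same field names.
#'
#' @param path file path or connection.
#' @param dialect `"csv"` or `"jsonl"`.
#' @param registry a [crm_registry()] used for validation.
#' @return A validated [vs_stream()].
#' @export
read_stream <- function(path, dialect = c("csv", "jsonl"),
                        registry = crm_registry()) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- tryCatch(
      utils::read.csv(path, colClasses = "character", check.names = FALSE),
      error = function(e) stop("format error reading '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) stop("empty stream file: ", path, call. = FALSE)
    recs <- lapply(seq_along(lines), function(i) {
      tryCatch(jsonlite::fromJSON(lines[i]),
               error = function(e) stop("format error at line ", i, " of '",
                                        path, "'", call. = FALSE))
    })
    df <- do.call(rbind, lapply(recs, function(r)
      as.data.frame(lapply(r, as.character), stringsAsFactors = FALSE)))
  }
  if (nrow(df) == 0) stop("empty stream file: ", path, call. = FALSE)
  need <- c("patient_id", "device_id", "data_type", "timestamp", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema mismatch: missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  has_sqi <- all(c("sq_type", "sq_value") %in% names(df)) &&
    !all(df$sq_type == "null")
  ts <- as.numeric(df$timestamp)
  rate <- if (nrow(df) > 1) 1 / (ts[2] - ts[1]) else 1
  s <- vs_stream(df$value, data_type = df$data_type[1], timestamp = ts,
                 sampling_rate = rate,
                 patient_id = df$patient_id[1], device_id = df$device_id[1],
                 sq_type = if (has_sqi) df$sq_type[1] else "null",
                 sq_value = if (has_sqi) as.numeric(df$sq_value) else NULL)
  viol <- validate_stream(s, registry)
  if (length(viol)) stop("invalid stream in '", path, "': ",
                         paste(viol, collapse = "; "), call. = FALSE)
  s
}

#' Write a stream to delimited text
#'
#' Inverse of [read_stream()]: `read_stream(write_stream(s, f), f)` is the
#' identity on valid streams. Streams with `sq_type = "null"` are written
#' without SQ columns/fields.
#'
#' @param stream a valid [vs_stream()].
#' @param path file path.
#' @param dialect `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(stream)
  if (dialect == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      rec <- as.list(df[i, , drop = FALSE])
      rec$timestamp <- as.numeric(rec$timestamp)
      if (!is.null(rec$sq_value)) rec$sq_value <- as.numeric(rec$sq_value)
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}
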