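#' De-interlace symbolic artifact markers into a signal-quality stream
#'
#' Monitors interlace artifact indicators directly into the numeric stream
#' (e.g. `"NaN"` for a dropped sample, `"^^"` for a flagged artifact, the
#' alarm code `5` for a sensor-off state). This operator maps each such
#' symbol to a configured SQ value at the samples where it occurs and leaves
#' every other sample's SQ value untouched. Data values are never rewritten.
#'
#' @param stream a [vs_stream()] carrying an SQ annotation (the acquisition
#'   default is acceptable).
#' @param art_syms character vector of artifact symbols/values to match
#'   (matched against the verbatim stored value).
#' @param sqi_match numeric vector of SQ values, one per entry of `art_syms`
#'   (recycled if scalar). A binary output uses `sqi_match = 0`.
#' @return The stream with its SQ values replaced at matched samples.
#' @examples
#' s <- attach_default_sqi(vs_stream(c(96, "^^", 95), "SpO2"))
#' ad_dil(s, c("NaN", "^^", "5"), 0)$sq_value
#' @export
ad_dil <- function(stream, art_syms, sqi_match = 0) {
  if (identical(stream$sq_type, "null")) {
    stop("ad_dil requires an incoming SQ stream (run attach_default_sqi first)",
         call. = FALSE)
  }
  if (length(art_syms) == 0) return(stream)
  if (length(sqi_match) == 1) sqi_match <- rep(sqi_match, length(art_syms))
  if (length(sqi_match) != length(art_syms) || anyNA(sqi_match)) {
    stop("every artifact symbol needs a matching SQ value", call. = FALSE)
  }
  hit <- match(stream$value, as.character(art_syms))
  idx <- which(!is.na(hit))
  stream$sq_value[idx] <- sqi_match[hit[idx]]
  stream
}

#' Fuse the signal-quality streams of several inputs
#'
#' Combines the per-sample SQ values of `N >= 1` input streams with a single
#' operator (`min`, `max`, or `avg`) and attaches the fused SQ stream to the
#' forwarded data streams. All inputs must share one SQ type, which is also
#' the output type; `avg` is refused for binary inputs since the mean leaves
#' the `{0, 1}` domain.
#'
#' @param streams list of equal-length [vs_stream()] with a common non-null
#'   SQ type.
#' @param operator `"min"`, `"max"`, or `"avg"`.
#' @param forward character vector of data types to forward with the fused
#'   SQ annotation; defaults to all inputs.
#' @return A named list of forwarded streams (by data type) carrying the
#'   fused SQ values; a single stream is returned bare.
#' @export
ad_fuse_sqi <- function(streams, operator = c("min", "max", "avg"),
                        forward = NULL) {
  operator <- match.arg(operator)
  stopifnot(length(streams) >= 1)
  lens <- vapply(streams, function(s) length(s$value), integer(1))
  if (length(unique(lens)) != 1) {
    stop("ad_fuse_sqi inputs must have equal length", call. = FALSE)
  }
  types <- vapply(streams, function(s) s$sq_type, character(1))
  if (length(unique(types)) != 1 || types[1] == "null") {
    stop("ad_fuse_sqi inputs must share one non-null sq_type", call. = FALSE)
  }
  if (operator == "avg" && types[1] == "binary") {
    stop("avg fusion is not defined for binary SQ streams", call. = FALSE)
  }
  m <- do.call(cbind, lapply(streams, function(s) s$sq_value))
  fused <- switch(operator,
                  min = do.call(pmin, lapply(streams, function(s) s$sq_value)),
                  max = do.call(pmax, lapply(streams, function(s) s$sq_value)),
                  avg = rowMeans(m))
  if (operator == "avg" && types[1] == "rank" && any(fused != floor(fused))) {
    warning("avg fusion left the rank domain; fractional SQ values kept",
            call. = FALSE)
  }
  if (is.null(forward)) {
    fwd <- streams
  } else {
    dts <- vapply(streams, function(s) s$data_type, character(1))
    miss <- setdiff(forward, dts)
    if (length(miss)) stop("cannot forward data type(s) not among inputs: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    fwd <- streams[match(forward, dts)]
  }
  out <- lapply(fwd, set_sqi, sq_type = types[1], sq_value = fused)
  names(out) <- vapply(out, function(s) s$data_type, character(1))
  if (length(out) == 1) out[[1]] else out
}

#' Derive signal quality from the disagreement of two redundant sensors
#'
#' When two devices measure the same physiology (here heart rate from ECG
#' and pulse rate from the oximeter's optical sensor), their absolute
#' per-sample difference is a proxy for the optical signal's quality. The
#' difference is binned against an ordered set of thresholds: the SQ value
#' for a sample is the one attached to the smallest threshold that the
#' difference does not exceed, or the default when all thresholds are
#' exceeded. If either input already has SQ value 0 (or a symbolic value
#' where a number is required), the default is emitted without arithmetic.
#'
#' @param stream1,stream2 equal-length numeric [vs_stream()] with
#'   binary-interpretable SQ annotations.
#' @param thresholds strictly increasing numeric vector (same units as the
#'   inputs; bpm here).
#' @param sq_values numeric vector of SQ values, one per threshold.
#' @param sqi_default SQ value when no threshold is met or an input is
#'   untrusted (default 0).
#' @param forward list of streams to which the derived SQ annotation is
#'   attached; defaults to `list(stream2)` (e.g. PR, which shares the SpO2
#'   sensor).
#' @param sq_type_out output SQ type; inferred (`"binary"` for a single 0/1
#'   configuration, else `"rank"`) when `NULL`.
#' @return Forwarded stream(s) carrying the derived SQ values; a single
#'   stream is returned bare.
#' @examples
#' hr <- attach_default_sqi(vs_stream(140, "HR"))
#' pr <- attach_default_sqi(vs_stream(145, "PR"))
#' ad_diff(hr, pr, thresholds = c(6, 12, 18), sq_values = c(3, 2, 1))$sq_value
#' @export
ad_diff <- function(stream1, stream2, thresholds, sq_values,
                    sqi_default = 0, forward = NULL, sq_type_out = NULL) {
  n <- length(stream1$value)
  stopifnot(length(stream2$value) == n)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  if (length(sq_values) != length(thresholds)) {
    stop("need one SQ value per threshold", call. = FALSE)
  }
  v1 <- stream_values(stream1)
  v2 <- stream_values(stream2)
  bad <- is.na(v1) | is.na(v2)
  if (!identical(stream1$sq_type, "null")) bad <- bad | stream1$sq_value == 0
  if (!identical(stream2$sq_type, "null")) bad <- bad | stream2$sq_value == 0
  d <- abs(v1 - v2)
  d[bad] <- NA_real_
  pos <- findInterval(d, thresholds, left.open = TRUE) + 1L
  sq <- c(sq_values, sqi_default)[pos]
  sq[bad] <- sqi_default
  if (is.null(sq_type_out)) {
    sq_type_out <- if (length(thresholds) == 1 &&
                       all(c(sq_values, sqi_default) %in% c(0, 1))) "binary"
                   else "rank"
  }
  if (is.null(forward)) forward <- list(stream2)
  out <- lapply(forward, set_sqi, sq_type = sq_type_out, sq_value = sq)
  names(out) <- vapply(out, function(s) s$data_type, character(1))
  if (length(out) == 1) out[[1]] else out
}

#' Quality-masked trailing median filter
#'
#' Smooths abrupt transient artifacts out of a numeric stream. Each output
#' sample is the median of the numeric samples inside the trailing window of
#' `med_ww` samples (current sample included) whose SQ value is acceptable
#' (non-zero); symbolic samples never enter the median. During warm-up the
#' window holds fewer than `med_ww` samples and all available ones are used.
#' A window with no acceptable sample holds the previous output (the first
#' such output is the `"NaN"` missing marker). An even count of candidates
#' yields the mean of the two middle values. The SQ stream passes through
#' unchanged and the output keeps the input's causality: sample `i` depends
#' only on samples `<= i`.
#'
#' @param stream a numeric [vs_stream()] with an SQ annotation.
#' @param med_ww positive integer window length in samples.
#' @param rename if `TRUE` (default) the output data type gains a `"Med"`
#'   suffix (e.g. `"SpO2"` to `"SpO2Med"`).
#' @return The filtered [vs_stream()], same length as the input.
#' @export
ad_medfilt <- function(stream, med_ww, rename = TRUE) {
  med_ww <- as.integer(med_ww)
  if (is.na(med_ww) || med_ww < 1) {
    stop("med_ww must be a positive integer", call. = FALSE)
  }
  v <- stream_values(stream)
  ok <- !is.na(v)
  if (!identical(stream$sq_type, "null")) ok <- ok & stream$sq_value != 0
  v[is.na(v)] <- NA_real_
  med <- masked_running_median(v, ok, med_ww)
  out <- stream
  out$value <- ifelse(is.na(med), "NaN", as.character(med))
  if (rename && !grepl("Med$", out$data_type)) {
    out$data_type <- paste0(out$data_type, "Med")
  }
  out
}
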