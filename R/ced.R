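#' Derive adjusted alarm thresholds from the monitor's limits
#'
#' The detection thresholds widen the bedside monitor's alarm limits by a
#' margin equal to the oximeter's specified reading accuracy (3 percentage
#' points by default): the low threshold is breached only when SpO2 falls at
#' least `margin` below the monitor's low limit, and symmetrically above the
#' high limit. A high threshold above 100% is clamped with a warning.
#'
#' @param oem_lo,oem_hi the monitor's low/high SpO2 alarm limits (%).
#' @param margin adjustment in percentage points (default 3).
#' @return Named numeric vector `c(lo, hi)`.
#' @examples
#' derive_thresholds(85, 95)   # c(lo = 82, hi = 98)
#' @export
derive_thresholds <- function(oem_lo, oem_hi, margin = 3) {
  stopifnot(oem_lo > 0, oem_lo < oem_hi, oem_hi <= 100, margin >= 0)
  hi <- oem_hi + margin
  if (hi > 100) {
    warning("high threshold clamped to 100%", call. = FALSE)
    hi <- 100
  }
  c(lo = oem_lo - margin, hi = hi)
}

#' Configuration of the SpO2 alarm generator
#'
#' The clinical event detector (CED) asserts an SpO2 alarm on any of three
#' conditions: the incoming value is at or below an absolute `floor` with
#' non-zero signal quality; the integrated low-threshold error exceeds
#' `dt_lo`; or the integrated high-threshold error exceeds `dt_hi`. Breach
#' magnitudes (percentage points below/above the adjusted thresholds) are
#' summed over a trailing circular buffer of `err_window` seconds, so the
#' integrated error grows with both the magnitude and the duration of a
#' breach and is measured in percentage-point-seconds. The decision
#' thresholds are proportional to the annunciation delay `ced_dt`:
#' `dt_lo = ced_dt` and `dt_hi = 2 * ced_dt`, so a sustained 1-pp low breach
#' annunciates after `ced_dt` seconds and the detector waits twice as long
#' for (clinically less dangerous) high-saturation alarms.
#'
#' @param oem_lo,oem_hi monitor alarm limits (% SpO2).
#' @param margin threshold adjustment in percentage points (default 3).
#' @param floor absolute minimum SpO2 (%); at or below it the detector
#'   alarms immediately. Clinically chosen in the 50-75% range; default 60.
#' @param ced_dt alarm annunciation delay in seconds, tunable in `[5, 60]`.
#' @param err_window length of the integration buffer in seconds (default
#'   240; must be at least `ced_dt`).
#' @param integrate `"magnitude"` (default) integrates the breach depth;
#'   `"binary"` integrates a 0/1 breach indicator instead.
#' @return A list of class `ced_config` with derived fields `thresh_lo`,
#'   `thresh_hi`, `dt_lo`, `dt_hi`.
#' @export
ced_config <- function(oem_lo = 85, oem_hi = 95, margin = 3, floor = 60,
                       ced_dt = 10, err_window = 240,
                       integrate = c("magnitude", "binary")) {
  integrate <- match.arg(integrate)
  th <- derive_thresholds(oem_lo, oem_hi, margin)
  if (!(floor < th[["lo"]])) stop("floor must lie below the low threshold",
                                  call. = FALSE)
  if (ced_dt < 5 || ced_dt > 60) stop("ced_dt must be in [5, 60] seconds",
                                      call. = FALSE)
  if (err_window < ced_dt) stop("err_window must be at least ced_dt",
                                call. = FALSE)
  structure(list(oem_lo = oem_lo, oem_hi = oem_hi, margin = margin,
                 thresh_lo = th[["lo"]], thresh_hi = th[["hi"]],
                 floor = floor, ced_dt = ced_dt,
                 dt_lo = ced_dt, dt_hi = 2 * ced_dt,
                 err_window = as.integer(err_window), integrate = integrate),
            class = "ced_config")
}

#' @export
print.ced_config <- function(x, ...) {
  cat(sprintf(paste0("<ced_config> thresholds %g/%g%% (limits %g/%g%%, margin %g pp)\n",
                     "  floor %g%%  ced_dt %g s (dt_lo %g, dt_hi %g)  err_window %d s  %s\n"),
              x$thresh_lo, x$thresh_hi, x$oem_lo, x$oem_hi, x$margin,
              x$floor, x$ced_dt, x$dt_lo, x$dt_hi, x$err_window, x$integrate))
  invisible(x)
}

#' Integrated threshold-breach error series
#'
#' For each sample of a 1 Hz SpO2 stream the per-sample breach magnitudes
#' below the low threshold and above the high threshold are computed
#' (samples with zero SQ value or symbolic values contribute nothing) and
#' summed over the trailing `err_window` samples.
#'
#' @param stream a 1 Hz numeric [vs_stream()] with SQ annotation.
#' @param cfg a [ced_config()].
#' @return List with numeric vectors `error_lo` and `error_hi` (pp-seconds),
#'   same length as the stream.
#' @export
breach_series <- function(stream, cfg) {
  v <- stream_values(stream)
  ok <- valid_mask(stream)
  b_lo <- ifelse(ok, pmax(0, cfg$thresh_lo - v), 0)
  b_hi <- ifelse(ok, pmax(0, v - cfg$thresh_hi), 0)
  b_lo[is.na(b_lo)] <- 0
  b_hi[is.na(b_hi)] <- 0
  if (identical(cfg$integrate, "binary")) {
    b_lo <- as.numeric(b_lo > 0)
    b_hi <- as.numeric(b_hi > 0)
  }
  list(error_lo = trailing_sum(b_lo, cfg$err_window),
       error_hi = trailing_sum(b_hi, cfg$err_window))
}

# internal: sum of the trailing w samples (fewer during warm-up)
trailing_sum <- function(x, w) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  cs <- cumsum(x)
  if (n <= w) return(cs)
  cs - c(rep(0, w), cs[seq_len(n - w)])
}

#' Generate SpO2 alarms from a quality-annotated stream
#'
#' Applies the three-condition alarm rule per sample and aggregates maximal
#' runs of asserted samples into episodes. The per-sample mask is
#' `(spo2 <= floor and SQ != 0) or (error_lo > dt_lo) or (error_hi > dt_hi)`.
#' An episode's kind is the highest-precedence condition that held during it
#' (`floor` over `low` over `high`); episodes separated by at least one
#' clear sample are distinct, and an episode persists while any condition
#' holds. Intervals are half-open `[start, end)` in seconds.
#'
#' @param stream a 1 Hz numeric [vs_stream()] with SQ annotation.
#' @param cfg a [ced_config()].
#' @return List of class `ced_alarms` with `mask` (logical per sample) and
#'   `episodes` (data.frame with `start`, `end`, `kind`, `source`).
#' @export
generate_alarms <- function(stream, cfg) {
  err <- breach_series(stream, cfg)
  v <- stream_values(stream)
  ok <- valid_mask(stream)
  cond_floor <- ok & !is.na(v) & v <= cfg$floor
  cond_lo <- err$error_lo > cfg$dt_lo
  cond_hi <- err$error_hi > cfg$dt_hi
  mask <- cond_floor | cond_lo | cond_hi
  episodes <- mask_to_episodes(mask, stream$timestamp, stream$sampling_rate,
                               cond_floor, cond_lo)
  structure(list(mask = mask, episodes = episodes,
                 error_lo = err$error_lo, error_hi = err$error_hi),
            class = "ced_alarms")
}

# internal: maximal runs of TRUE -> half-open episodes with kind precedence
mask_to_episodes <- function(mask, timestamp, rate, cond_floor = NULL,
                             cond_lo = NULL, source = "ced") {
  ep <- data.frame(start = numeric(0), end = numeric(0),
                   kind = character(0), source = character(0),
                   stringsAsFactors = FALSE)
  if (!any(mask)) return(ep)
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  step <- 1 / rate
  for (k in on) {
    i1 <- starts[k]; i2 <- ends[k]
    kind <- if (!is.null(cond_floor) && any(cond_floor[i1:i2])) "floor"
            else if (!is.null(cond_lo) && any(cond_lo[i1:i2])) "low"
            else if (!is.null(cond_floor)) "high"
            else "status"
    ep <- rbind(ep, data.frame(start = timestamp[i1],
                               end = timestamp[i2] + step,
                               kind = kind, source = source,
                               stringsAsFactors = FALSE))
  }
  ep
}

#' @export
print.ced_alarms <- function(x, ...) {
  cat(sprintf("<ced_alarms> %d asserted samples, %d episode(s)\n",
              sum(x$mask), nrow(x$episodes)))
  if (nrow(x$episodes)) print(x$episodes, row.names = FALSE)
  invisible(x)
}
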