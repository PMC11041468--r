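#' Configuration of the synthetic neonatal monitor simulator
#'
#' Describes the statistical structure of a simulated NICU monitoring
#' session: a stable SpO2 baseline with slow AR(1) wander, an ECG-derived
#' heart rate and an optically derived pulse rate that agree except during
#' motion artifacts, true desaturation events (the clinical events alarms
#' should capture), transient motion artifacts that corrupt the optical
#' channel and decouple PR from HR, sensor-off intervals, and a
#' threshold-only emulated bedside alarm channel. Event counts per session
#' are Poisson with the configured hourly rates; event intervals are
#' mutually disjoint. All randomness derives from `seed`, so a fixed seed
#' gives byte-identical cohorts.
#'
#' @param n_patients number of sessions (default 11).
#' @param duration session length in seconds (default 14,400, i.e. 7,200
#'   native samples).
#' @param native_rate monitor numeric rate in Hz (default 0.5).
#' @param spo2_mean,spo2_sd,spo2_ar SpO2 baseline mean (%), innovation sd,
#'   and AR(1) coefficient.
#' @param hr_baseline,hr_sd heart-rate baseline (bpm) and innovation sd.
#' @param pr_noise bound on |PR - HR| (bpm) outside artifacts.
#' @param desat_rate true desaturation events per hour.
#' @param desat_depth depth range in percentage points.
#' @param desat_duration duration range in seconds.
#' @param artifact_rate motion artifacts per hour.
#' @param artifact_duration artifact duration range in seconds.
#' @param artifact_pr_dev range of |PR - HR| deviation during artifacts
#'   (bpm).
#' @param artifact_spo2_range range of corrupted SpO2 values during
#'   artifacts (%).
#' @param token_prob per-sample probability that an artifact sample is
#'   logged as the `"^^"` token instead of a corrupted number.
#' @param sensoroff_rate sensor-off events per hour.
#' @param sensoroff_duration sensor-off duration range in seconds.
#' @param oem_lo,oem_hi the emulated monitor's alarm limits (% SpO2). The
#'   default high limit of 100 disables high-saturation alarms, as is common
#'   neonatal practice for infants not on supplemental oxygen.
#' @param seed integer seed driving the whole cohort.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 11, duration = 14400, native_rate = 0.5,
                       spo2_mean = 96, spo2_sd = 0.5, spo2_ar = 0.95,
                       hr_baseline = 150, hr_sd = 2, pr_noise = 5,
                       desat_rate = 2, desat_depth = c(15, 35),
                       desat_duration = c(60, 180),
                       artifact_rate = 6, artifact_duration = c(5, 30),
                       artifact_pr_dev = c(20, 60),
                       artifact_spo2_range = c(65, 100),
                       token_prob = 0.5,
                       sensoroff_rate = 1, sensoroff_duration = c(10, 40),
                       oem_lo = 85, oem_hi = 100, seed = 1) {
  stopifnot(n_patients >= 1, duration > 0, native_rate > 0,
            desat_rate >= 0, artifact_rate >= 0, sensoroff_rate >= 0,
            token_prob >= 0, token_prob <= 1,
            diff(desat_duration) >= 0, diff(artifact_duration) >= 0)
  if (max(desat_duration, artifact_duration, sensoroff_duration) > duration) {
    stop("configured event durations exceed the session length", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

# internal: place k disjoint intervals of the given durations in [0, total),
# also avoiding `avoid` (a 2-column matrix of existing intervals)
place_intervals <- function(k, dur_range, total, avoid = NULL, step = 2) {
  out <- avoid
  placed <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(k)) {
    d <- round(stats::runif(1, dur_range[1], dur_range[2]) / step) * step
    d <- max(step, d)
    for (try in 1:200) {
      a <- floor(stats::runif(1, 0, max(1, total - d)) / step) * step
      b <- a + d
      clash <- !is.null(out) && nrow(out) > 0 &&
        any(a < out[, 2] & b > out[, 1])
      if (!clash) {
        out <- rbind(out, c(a, b))
        placed <- rbind(placed, c(a, b))
        break
      }
      if (try == 200) stop("could not place disjoint events; config infeasible",
                           call. = FALSE)
    }
  }
  list(placed = placed, all = out)
}

# internal: AR(1) series around a mean
ar1 <- function(n, mean, sd, coef) {
  mean + as.numeric(stats::filter(stats::rnorm(n, 0, sd), coef,
                                  method = "recursive"))
}

#' Simulate one patient session
#'
#' Generates the four native-rate streams of one monitored infant: SpO2,
#' pulse rate and the emulated alarm-status channel at the oximeter device,
#' and heart rate at the ECG device, together with the ground truth (true
#' desaturation, artifact and sensor-off intervals, all half-open seconds).
#' Streams are integer-valued with symbolic tokens interlaced exactly as the
#' study monitors log them: `"^^"` during flagged artifacts, `"NaN"` for the
#' dropped optical channel during sensor-off, alarm code `5` while the
#' sensor is off.
#'
#' @param cfg a [sim_config()].
#' @param patient patient index (seeds this session).
#' @return List with `streams` (named native-rate [vs_stream()] list:
#'   `SpO2`, `PR`, `SpO2Alarm`, `HR`) and `truth` (list of interval
#'   data.frames `desat`, `artifact`, `sensor_off`).
#' @export
simulate_patient <- function(cfg, patient = 1) {
  set.seed((cfg$seed + 7919L * patient) %% .Machine$integer.max)
  step <- 1 / cfg$native_rate
  n <- round(cfg$duration * cfg$native_rate)
  ts <- (seq_len(n) - 1) * step
  pid <- sprintf("P%02d", patient)

  # event placement (desats first, then artifacts, then sensor-off)
  k_desat <- stats::rpois(1, cfg$desat_rate * cfg$duration / 3600)
  k_art <- stats::rpois(1, cfg$artifact_rate * cfg$duration / 3600)
  k_off <- stats::rpois(1, cfg$sensoroff_rate * cfg$duration / 3600)
  pl <- place_intervals(k_desat, cfg$desat_duration, cfg$duration, step = step)
  desat <- pl$placed
  pl <- place_intervals(k_art, cfg$artifact_duration, cfg$duration, pl$all,
                        step = step)
  artifact <- pl$placed
  pl <- place_intervals(k_off, cfg$sensoroff_duration, cfg$duration, pl$all,
                        step = step)
  sensor_off <- pl$placed

  spo2 <- ar1(n, cfg$spo2_mean, cfg$spo2_sd, cfg$spo2_ar)
  hr <- ar1(n, cfg$hr_baseline, cfg$hr_sd, 0.9)
  pr <- hr + pmin(pmax(stats::rnorm(n, 0, cfg$pr_noise / 3),
                       -cfg$pr_noise), cfg$pr_noise)

  in_iv <- function(iv) {
    m <- logical(n)
    for (r in seq_len(nrow(iv))) m <- m | (ts >= iv[r, 1] & ts < iv[r, 2])
    m
  }
  # true desaturations: trapezoidal dip of the drawn depth
  for (r in seq_len(nrow(desat))) {
    idx <- which(ts >= desat[r, 1] & ts < desat[r, 2])
    m <- length(idx)
    depth <- stats::runif(1, cfg$desat_depth[1], cfg$desat_depth[2])
    ramp <- max(1L, round(m / 4))
    prof <- c(seq(0, 1, length.out = ramp),
              rep(1, max(0L, m - 2 * ramp)),
              seq(1, 0, length.out = ramp))[seq_len(m)]
    spo2[idx] <- spo2[idx] - depth * prof
  }
  spo2 <- pmin(100, pmax(0, round(spo2)))
  hr <- round(hr)
  pr <- round(pr)
  pr <- pmin(pmax(pr, hr - cfg$pr_noise), hr + cfg$pr_noise)

  spo2_chr <- as.character(spo2)
  pr_chr <- as.character(pr)

  # motion artifacts: PR decouples from HR; SpO2 corrupted or tokenized
  for (r in seq_len(nrow(artifact))) {
    idx <- which(ts >= artifact[r, 1] & ts < artifact[r, 2])
    dev <- stats::runif(1, cfg$artifact_pr_dev[1], cfg$artifact_pr_dev[2]) *
      sample(c(-1, 1), 1)
    pr_chr[idx] <- as.character(round(hr[idx] + dev))
    spike <- round(stats::runif(length(idx), cfg$artifact_spo2_range[1],
                                cfg$artifact_spo2_range[2]))
    tok <- stats::runif(length(idx)) < cfg$token_prob
    spo2_chr[idx] <- ifelse(tok, "^^", as.character(spike))
  }
  off_mask <- in_iv(sensor_off)
  spo2_chr[off_mask] <- "NaN"
  pr_chr[off_mask] <- "NaN"

  mk <- function(v, dt, dev) vs_stream(v, dt, timestamp = ts,
                                       sampling_rate = cfg$native_rate,
                                       patient_id = pid, device_id = dev)
  spo2_stream <- mk(spo2_chr, "SpO2", "oximeter")
  streams <- list(
    SpO2 = spo2_stream,
    PR = mk(pr_chr, "PR", "oximeter"),
    SpO2Alarm = emulate_oem_alarms(spo2_stream, cfg$oem_lo, cfg$oem_hi,
                                   sensor_off = off_mask),
    HR = mk(as.character(hr), "HR", "ecg")
  )
  iv_df <- function(m) data.frame(start = m[, 1], end = m[, 2])
  list(streams = streams,
       truth = list(desat = iv_df(desat), artifact = iv_df(artifact),
                    sensor_off = iv_df(sensor_off)))
}

#' Emulate the bedside monitor's threshold-only alarm channel
#'
#' The emulated monitor asserts its alarm (code 1) at exactly the samples
#' where the numeric SpO2 value crosses a limit -- no annunciation delay, no
#' signal-quality reasoning. Samples in a sensor-off state carry code 5;
#' all other samples (including symbolic artifact samples) are clear
#' (code 0). This is the comparison baseline whose transient-artifact false
#' alarms the pipelines are built to suppress.
#'
#' @param spo2_stream a native-rate SpO2 [vs_stream()].
#' @param oem_lo,oem_hi the monitor's alarm limits (%).
#' @param sensor_off logical mask of sensor-off samples (optional).
#' @return An alarm-status [vs_stream()] (`data_type = "SpO2Alarm"`).
#' @export
emulate_oem_alarms <- function(spo2_stream, oem_lo = 85, oem_hi = 95,
                               sensor_off = NULL) {
  v <- stream_values(spo2_stream)
  code <- rep("0", length(v))
  breach <- !is.na(v) & (v < oem_lo | v > oem_hi)
  code[breach] <- "1"
  if (!is.null(sensor_off)) code[sensor_off] <- "5"
  out <- spo2_stream
  out$data_type <- "SpO2Alarm"
  out$value <- code
  out$sq_type <- "null"
  out$sq_value <- NULL
  out
}

#' Simulate a cohort of patient sessions
#'
#' Draws `n_patients` independent sessions from the seed sequence. When
#' `out_dir` is given, each stream is written as a CRM CSV
#' (`P01_SpO2.csv`, ...), ground truth as `P01_truth.csv` (columns `event`,
#' `start`, `end`), and a `manifest.json` listing the files and the
#' configuration.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory.
#' @return List of patients as returned by [simulate_patient()], invisibly
#'   when writing to disk.
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  cohort <- lapply(seq_len(cfg$n_patients), function(p)
    simulate_patient(cfg, p))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    for (p in seq_along(cohort)) {
      pid <- sprintf("P%02d", p)
      for (dt in names(cohort[[p]]$streams)) {
        f <- file.path(out_dir, sprintf("%s_%s.csv", pid, dt))
        write_stream(cohort[[p]]$streams[[dt]], f)
        files[[length(files) + 1]] <- basename(f)
      }
      tr <- cohort[[p]]$truth
      tdf <- do.call(rbind, lapply(names(tr), function(ev)
        if (nrow(tr[[ev]])) cbind(event = ev, tr[[ev]]) else NULL))
      if (is.null(tdf)) tdf <- data.frame(event = character(0),
                                          start = numeric(0), end = numeric(0))
      tf <- file.path(out_dir, sprintf("%s_truth.csv", pid))
      utils::write.csv(tdf, tf, row.names = FALSE)
      files[[length(files) + 1]] <- basename(tf)
    }
    manifest <- list(n_patients = cfg$n_patients, duration = cfg$duration,
                     native_rate = cfg$native_rate, seed = cfg$seed,
                     files = unlist(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(cohort))
  }
  cohort
}

#' Acquire a simulated cohort onto the 1 Hz grid
#'
#' Convenience wrapper: runs [acquire()] on every simulated patient and
#' pairs the synchronized streams with the true desaturation intervals, in
#' the shape [loocv()] expects.
#'
#' @param cohort output of [simulate_cohort()].
#' @return List of `list(streams, truth)` per patient; `truth` is the
#'   desaturation interval data.frame.
#' @export
prepare_cohort <- function(cohort) {
  lapply(cohort, function(p) {
    list(streams = acquire(list(all = p$streams)),
         truth = p$truth$desat)
  })
}
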