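# shared fixtures and independent oracles for the suite

# 1 Hz stream with the acquisition-default binary SQ annotation
mk_stream <- function(values, data_type = "SpO2", sq = NULL, rate = 1) {
  s <- vs_stream(values, data_type, sampling_rate = rate)
  if (is.null(sq)) attach_default_sqi(s) else set_sqi_test(s, sq)
}

set_sqi_test <- function(s, sq, type = "binary") {
  s$sq_type <- type
  s$sq_value <- as.numeric(sq)
  s
}

# sort-based trailing-median oracle with quality masking, independent of the
# compiled implementation
median_oracle <- function(values, ok, w) {
  n <- length(values)
  out <- rep(NA_real_, n)
  prev <- NA_real_
  for (i in seq_len(n)) {
    win <- max(1, i - w + 1):i
    v <- values[win][ok[win] & !is.na(values[win])]
    if (length(v) == 0) {
      out[i] <- prev
    } else {
      v <- sort(v)
      m <- length(v)
      out[i] <- if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
      prev <- out[i]
    }
  }
  out
}

# brute-force per-sample re-evaluation of the three alarm conditions:
# floor crossing with trusted quality, integrated low error above dt_lo,
# integrated high error above dt_hi. Per-sample breaches are derived one
# sample at a time and the trailing-window sums recomputed from scratch at
# every sample -- no shared code or rolling-sum trick with the implementation.
ced_oracle_mask <- function(values, sq, cfg) {
  n <- length(values)
  v <- suppressWarnings(as.numeric(values))
  v[!is.finite(v)] <- NA
  b_lo <- b_hi <- numeric(n)
  for (k in seq_len(n)) {
    if (!is.na(v[k]) && sq[k] != 0) {
      b_lo[k] <- max(0, cfg$thresh_lo - v[k])
      b_hi[k] <- max(0, v[k] - cfg$thresh_hi)
      if (identical(cfg$integrate, "binary")) {
        b_lo[k] <- as.numeric(b_lo[k] > 0)
        b_hi[k] <- as.numeric(b_hi[k] > 0)
      }
    }
  }
  mask <- logical(n)
  for (i in seq_len(n)) {
    win <- max(1, i - cfg$err_window + 1):i
    c1 <- !is.na(v[i]) && sq[i] != 0 && v[i] <= cfg$floor
    c2 <- sum(b_lo[win]) > cfg$dt_lo
    c3 <- sum(b_hi[win]) > cfg$dt_hi
    mask[i] <- c1 || c2 || c3
  }
  mask
}

# random quality-annotated SpO2 stream for property tests
random_spo2_stream <- function(n, p_token = 0.05, p_bad_sq = 0.05) {
  v <- as.character(sample(55:100, n, replace = TRUE))
  tok <- runif(n) < p_token
  v[tok] <- sample(c("NaN", "^^"), sum(tok), replace = TRUE)
  sq <- ifelse(runif(n) < p_bad_sq, 0, 1)
  mk_stream(v, sq = sq)
}

# minimal clean session (all four data types, native 0.5 Hz) for pipelines
mk_session <- function(spo2, hr = NULL, pr = NULL, alarm = NULL) {
  n <- length(spo2)
  if (is.null(hr)) hr <- rep(150, n)
  if (is.null(pr)) pr <- hr
  if (is.null(alarm)) alarm <- rep(0, n)
  list(
    SpO2 = vs_stream(spo2, "SpO2", sampling_rate = 0.5, device_id = "oximeter"),
    PR = vs_stream(pr, "PR", sampling_rate = 0.5, device_id = "oximeter"),
    SpO2Alarm = vs_stream(alarm, "SpO2Alarm", sampling_rate = 0.5,
                          device_id = "oximeter"),
    HR = vs_stream(hr, "HR", sampling_rate = 0.5, device_id = "ecg")
  )
}
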