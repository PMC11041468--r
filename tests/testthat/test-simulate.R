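small_cfg <- function(...) sim_config(n_patients = 2, duration = 1800,
                                      seed = 9, ...)

test_that("a fixed seed gives byte-identical sessions", {
  a <- simulate_patient(small_cfg(), 1)
  b <- simulate_patient(small_cfg(), 1)
  expect_identical(a, b)
  c <- simulate_patient(small_cfg(), 2)
  expect_false(identical(a$streams$SpO2$value, c$streams$SpO2$value))
})

test_that("session geometry follows the configuration", {
  p <- simulate_patient(sim_config(seed = 3), 1)
  expect_true(all(vapply(p$streams, length, 1L) == 7200))
  expect_equal(p$streams$SpO2$sampling_rate, 0.5)
  expect_equal(max(p$streams$SpO2$timestamp), 14398)
  expect_identical(p$streams$HR$device_id, "ecg")
  expect_identical(p$streams$SpO2$device_id, "oximeter")
})

test_that("zero event rates give a fully numeric, token-free cohort", {
  cfg <- small_cfg(artifact_rate = 0, sensoroff_rate = 0, desat_rate = 0)
  p <- simulate_patient(cfg, 1)
  for (s in p$streams) {
    expect_false(any(s$value %in% c("NaN", "^^", "5")), info = s$data_type)
    expect_false(anyNA(stream_values(s)), info = s$data_type)
  }
  expect_equal(nrow(p$truth$desat), 0)
  # outside events PR stays within the configured noise bound of HR
  gap <- abs(stream_values(p$streams$PR) - stream_values(p$streams$HR))
  expect_lte(max(gap), cfg$pr_noise)
})

test_that("every emitted token is in the device artifact registry", {
  p <- simulate_patient(sim_config(seed = 5, duration = 7200), 1)
  reg <- crm_registry()
  for (s in p$streams) {
    num <- suppressWarnings(as.numeric(s$value))
    toks <- unique(s$value[!is.finite(num)])
    expect_true(all(toks %in% reg$tokens), info = s$data_type)
    expect_identical(validate_stream(s, reg), character(0), info = s$data_type)
  }
})

test_that("ground-truth intervals are mutually disjoint and in range", {
  p <- simulate_patient(sim_config(seed = 11), 1)
  iv <- rbind(p$truth$desat, p$truth$artifact, p$truth$sensor_off)
  iv <- iv[order(iv$start), ]
  expect_true(all(iv$end > iv$start))
  expect_true(all(iv$start >= 0 & iv$end <= 14400))
  if (nrow(iv) > 1) expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
})

test_that("the emulated monitor alarms exactly on threshold crossings", {
  clean <- simulate_patient(small_cfg(artifact_rate = 0, sensoroff_rate = 0,
                                      desat_rate = 0), 1)
  expect_false(any(clean$streams$SpO2Alarm$value == "1"))

  s <- vs_stream(c(96, 60, 96, 98), "SpO2", sampling_rate = 0.5)
  al <- emulate_oem_alarms(s, 85, 97)
  expect_identical(al$value, c("0", "1", "0", "1"))
  expect_identical(al$data_type, "SpO2Alarm")

  # sensor-off samples carry code 5, never an assertion
  s2 <- vs_stream(c(96, "NaN", 96), "SpO2", sampling_rate = 0.5)
  al2 <- emulate_oem_alarms(s2, 85, 100, sensor_off = c(FALSE, TRUE, FALSE))
  expect_identical(al2$value, c("0", "5", "0"))
})

test_that("a spike is a false OEM alarm and a desaturation a true one", {
  n <- 600
  spo2 <- rep(96, n)
  spo2[150] <- 66                       # transient spike (one native sample)
  desat_idx <- 250:309                  # 120 s sustained desaturation
  spo2[desat_idx] <- 75
  s <- vs_stream(spo2, "SpO2", sampling_rate = 0.5)
  eps <- episodes_from_status(emulate_oem_alarms(s, 85, 100))
  truth <- data.frame(start = 498, end = 618)
  cnt <- categorize(eps, truth)
  expect_equal(c(cnt$tp, cnt$fp, cnt$fn), c(1, 1, 0))
})

test_that("cohort totals and on-disk layout match the configuration", {
  cfg <- sim_config(n_patients = 2, duration = 3600, seed = 21)
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cfg, out_dir = dir)
  expect_length(co, 2)
  files <- list.files(dir)
  expect_length(grep("_truth\\.csv$", files), 2)
  expect_length(grep("_SpO2\\.csv$", files), 2)
  expect_true("manifest.json" %in% files)
  # streams re-read identically from disk
  back <- read_stream(file.path(dir, "P01_SpO2.csv"))
  expect_identical(back, co[[1]]$streams$SpO2)
})

test_that("native and acquired totals scale as 2x across the cohort", {
  cfg <- sim_config(n_patients = 3, duration = 1200, seed = 13)
  co <- simulate_cohort(cfg)
  native <- sum(vapply(co, function(p) length(p$streams$SpO2$value), 1L))
  pc <- prepare_cohort(co)
  onehz <- sum(vapply(pc, function(p) length(p$streams$SpO2$value), 1L))
  expect_equal(native, 3 * 600)
  expect_equal(onehz, 2 * native)
})

test_that("event counts match the configured Poisson rates", {
  cfg <- sim_config(n_patients = 1, duration = 3600, desat_rate = 2,
                    artifact_rate = 6, seed = 77)
  k_desat <- k_art <- numeric(100)
  for (i in 1:100) {
    p <- simulate_patient(cfg, i)
    k_desat[i] <- nrow(p$truth$desat)
    k_art[i] <- nrow(p$truth$artifact)
  }
  # totals are Poisson(100 * rate); check within 3 standard errors
  expect_lt(abs(sum(k_desat) - 200), 3 * sqrt(200))
  expect_lt(abs(sum(k_art) - 600), 3 * sqrt(600))
})

test_that("an artifact-free cohort yields identical alarms across presets", {
  cfg <- small_cfg(artifact_rate = 0, sensoroff_rate = 0)
  p <- simulate_patient(cfg, 1)
  streams <- acquire(list(s = p$streams))
  eps <- lapply(list(preset(1, ced_dt = 10),
                     preset(2, ced_dt = 10, med_ww = 1),
                     preset(3, ced_dt = 10, sq_thresh = 18),
                     preset(4, ced_dt = 10, med_ww = 1, sq_thresh = 18)),
                function(g) run_graph(g, streams)$episodes)
  for (k in 2:4) expect_identical(eps[[k]], eps[[1]])
})
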