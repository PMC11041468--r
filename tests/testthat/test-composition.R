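# a clean 0.5 Hz session: baseline 96%, all channels agreeing
clean_session <- function(n = 600, spo2 = rep(96, n)) mk_session(spo2)

test_that("all four presets pass compatibility for every study tunable", {
  for (dt in c(5, 10, 12, 15, 20, 30, 60)) {
    expect_identical(check_compatibility(preset(1, ced_dt = dt)), character(0))
    for (w in c(5, 10, 20, 25, 30, 35, 60)) {
      expect_identical(check_compatibility(preset(2, ced_dt = dt, med_ww = w)),
                       character(0))
    }
    for (th in c(6, 12, 18)) {
      expect_identical(check_compatibility(preset(3, ced_dt = dt,
                                                  sq_thresh = th)),
                       character(0))
      expect_identical(check_compatibility(
        preset(4, ced_dt = dt, med_ww = 10, sq_thresh = th)), character(0))
    }
  }
})

test_that("preset structure follows the published formulations", {
  count_type <- function(g, ty)
    sum(vapply(g$nodes, function(n) n$type == ty, logical(1)))
  expect_equal(count_type(preset(1), "dil"), 2)
  expect_equal(count_type(preset(3), "dil"), 4)
  expect_equal(count_type(preset(2), "medfilt"), 1)
  expect_equal(count_type(preset(1), "medfilt"), 0)
  # the median filter sits between fusion and the alarm generator
  g2 <- preset(2, med_ww = 10)
  expect_identical(g2$nodes$medfilt$inputs$x, "fuse1.SpO2")
  expect_identical(g2$nodes$ced$inputs$spo2, "medfilt.SpO2Med")

  expect_error(preset(1, med_ww = 10), "med_ww")
  expect_error(preset(2, sq_thresh = 12), "sq_thresh")
  expect_error(preset(3, med_ww = 10), "med_ww")
})

test_that("compatibility checking flags bad wiring", {
  g <- preset(1)
  # cycle: make a de-interlacer depend on the fusion output
  g$nodes$dil_spo2$inputs$x <- "fuse1.SpO2"
  expect_true(any(grepl("cyclic", check_compatibility(g))))

  # rank SQ fed into a binary-requiring fusion
  g2 <- preset(1)
  g2$nodes$dil_spo2$sq_out <- "rank"
  expect_true(any(grepl("sq_type", check_compatibility(g2))))

  # unprovided requirement
  g3 <- preset(1)
  g3$nodes$ced$inputs$spo2 <- "ghost.SpO2"
  expect_true(any(grepl("unprovided", check_compatibility(g3))))
})

test_that("running a graph is deterministic and inspectable", {
  streams <- acquire(list(s = clean_session()))
  g <- preset(2, ced_dt = 10, med_ww = 10)
  r1 <- run_graph(g, streams)
  r2 <- run_graph(g, streams)
  expect_identical(r1, r2)
  expect_true("medfilt.SpO2Med" %in% names(r1$channels))
  expect_s3_class(r1$channels[["fuse1.SpO2"]], "vs_stream")

  expect_error(run_graph(preset(3), streams["SpO2"]), "missing")
})

test_that("a unit median window reproduces the filter-free pipeline", {
  set.seed(5)
  spo2 <- as.character(pmin(100, round(96 + cumsum(rnorm(600, 0, 0.3)))))
  spo2[sample(600, 20)] <- "^^"
  streams <- acquire(list(s = clean_session(spo2 = spo2)))
  r1 <- run_graph(preset(1, ced_dt = 10), streams)
  r2 <- run_graph(preset(2, ced_dt = 10, med_ww = 1), streams)
  expect_identical(r2$episodes, r1$episodes)
  expect_identical(r2$mask, r1$mask)
})

test_that("median filtering suppresses a transient spike but keeps true events", {
  n <- 600
  spo2 <- rep(96, n)
  # 5-second, 30-pp artifact spike (native 0.5 Hz: samples at 2 s)
  spike_idx <- which((0:(n - 1)) * 2 >= 300 & (0:(n - 1)) * 2 < 305)
  spo2[spike_idx] <- 66
  # 120-second true desaturation to 75%
  desat_idx <- which((0:(n - 1)) * 2 >= 700 & (0:(n - 1)) * 2 < 820)
  spo2[desat_idx] <- 75
  streams <- acquire(list(s = clean_session(n, spo2)))
  r1 <- run_graph(preset(1, ced_dt = 5), streams)
  r2 <- run_graph(preset(2, ced_dt = 5, med_ww = 20), streams)
  truth <- data.frame(start = 700, end = 820)
  overlaps <- function(eps) eps$start < 830 & eps$end > 690
  # the plain pipeline alarms on the artifact; the filtered one does not
  expect_true(any(!overlaps(r1$episodes)))
  expect_true(all(overlaps(r2$episodes)))
  expect_gte(nrow(r2$episodes), 1)
  # both detect the true desaturation
  expect_equal(categorize(r1$episodes, truth)$tp, 1)
  expect_equal(categorize(r2$episodes, truth)$tp, 1)
  expect_equal(categorize(r2$episodes, truth)$fp, 0)
})

test_that("HR-PR divergence masks breaches in the dual-sensor presets", {
  n <- 600
  spo2 <- rep(96, n)
  pr <- hr <- rep(150, n)
  # an optical artifact: SpO2 plunges while PR leaves HR by 40 bpm
  idx <- 100:130
  spo2[idx] <- 70
  pr[idx] <- 190
  streams <- acquire(list(s = mk_session(spo2, hr = hr, pr = pr)))
  r1 <- run_graph(preset(1, ced_dt = 10), streams)
  r3 <- run_graph(preset(3, ced_dt = 10, sq_thresh = 18), streams)
  expect_gte(nrow(r1$episodes), 1)   # quality-blind: false alarm
  expect_equal(nrow(r3$episodes), 0) # divergence masks the breach
  # derived SQ is zero exactly where the sensors disagree
  sq <- r3$channels[["fuse2.SpO2"]]$sq_value
  expect_true(all(sq[300:400] == 1))
  expect_true(all(sq[c(idx * 2 - 1, idx * 2)] == 0))
})
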