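test_that("de-interlacing maps artifact symbols to SQ values and nothing else", {
  s <- mk_stream(c("96", "^^", "95"))
  out <- ad_dil(s, c("NaN", "^^", "5"), 0)
  expect_equal(out$sq_value, c(1, 0, 1))
  expect_identical(out$value, s$value)  # values immutable

  # alarm-channel example: a lead-disconnect code in the alarms stream
  al <- mk_stream(c("0", "2", "0"), data_type = "SpO2Alarm")
  expect_equal(ad_dil(al, "2", 0)$sq_value, c(1, 0, 1))

  expect_identical(ad_dil(s, character(0)), s)  # empty symbol set: identity

  expect_error(ad_dil(s, c("^^", "NaN"), c(0, NA)), "matching SQ value")
  expect_error(ad_dil(vs_stream("96", "SpO2"), "^^", 0), "SQ stream")
})

test_that("de-interlacing leaves non-matched SQ values untouched", {
  s <- mk_stream(c("96", "^^", "95", "5"), sq = c(1, 1, 0, 1))
  out <- ad_dil(s, c("^^", "5"), 0)
  expect_equal(out$sq_value, c(1, 0, 0, 0))
})

test_that("SQ fusion applies min/max/avg pointwise", {
  a <- mk_stream(c(96, 95, 94), sq = c(1, 1, 0))
  b <- mk_stream(c(0, 0, 0), data_type = "SpO2Alarm", sq = c(1, 0, 1))
  fused <- ad_fuse_sqi(list(a, b), "min", forward = "SpO2")
  expect_equal(fused$sq_value, c(1, 0, 0))
  expect_identical(fused$data_type, "SpO2")

  expect_equal(ad_fuse_sqi(list(a), "min")$sq_value, a$sq_value)  # N = 1

  r1 <- set_sqi_test(vs_stream(1:2, "HR"), c(3, 1), "rank")
  r2 <- set_sqi_test(vs_stream(1:2, "PR"), c(1, 1), "rank")
  avg <- ad_fuse_sqi(list(r1, r2), "avg", forward = "HR")
  expect_equal(avg$sq_value, c(2, 1))

  expect_error(ad_fuse_sqi(list(a, b), "avg"), "binary")
  expect_error(ad_fuse_sqi(list(a, mk_stream(96)), "min"), "equal length")
  r3 <- set_sqi_test(vs_stream(1:3, "HR"), c(1, 1, 1), "rank")
  expect_error(ad_fuse_sqi(list(a, r3), "min"), "one non-null sq_type")
})

test_that("fusion is permutation-invariant and pointwise bounded", {
  set.seed(11)
  for (rep in 1:20) {
    qs <- replicate(3, sample(0:3, 10, replace = TRUE), simplify = FALSE)
    streams <- lapply(qs, function(q)
      set_sqi_test(vs_stream(rep(1, 10), "HR"), q, "rank"))
    mn <- ad_fuse_sqi(streams, "min", forward = "HR")$sq_value
    mx <- ad_fuse_sqi(streams, "max", forward = "HR")$sq_value
    perm <- sample(3)
    expect_equal(ad_fuse_sqi(streams[perm], "min", forward = "HR")$sq_value, mn)
    for (q in qs) {
      expect_true(all(mn <= q))
      expect_true(all(mx >= q))
    }
  }
})

test_that("dual-sensor differencing bins |HR - PR| against ordered thresholds", {
  hr <- mk_stream(140, data_type = "HR")
  pr <- mk_stream(145, data_type = "PR")
  cfgv <- list(thresholds = c(6, 12, 18), sq_values = c(3, 2, 1))
  expect_equal(ad_diff(hr, pr, c(6, 12, 18), c(3, 2, 1))$sq_value, 3)  # diff 5
  expect_equal(ad_diff(mk_stream(140, data_type = "HR"),
                       mk_stream(165, data_type = "PR"),
                       c(6, 12, 18), c(3, 2, 1))$sq_value, 0)  # diff 25
  # untrusted input short-circuits to the default even at zero difference
  pr0 <- mk_stream(140, data_type = "PR", sq = 0)
  expect_equal(ad_diff(hr, pr0, c(6, 12, 18), c(3, 2, 1))$sq_value, 0)
  # boundary: diff equal to a threshold belongs to that threshold's bin
  pr6 <- mk_stream(146, data_type = "PR")
  expect_equal(ad_diff(hr, pr6, c(6, 12, 18), c(3, 2, 1))$sq_value, 3)
  expect_error(ad_diff(hr, pr, c(6, 6, 18), c(3, 2, 1)), "strictly increasing")
})

test_that("differencing is symmetric, monotone in the gap, and token-safe", {
  set.seed(7)
  for (rep in 1:20) {
    h <- sample(120:180, 15, replace = TRUE)
    p <- sample(120:180, 15, replace = TRUE)
    hr <- mk_stream(h, data_type = "HR")
    pr <- mk_stream(p, data_type = "PR")
    a <- ad_diff(hr, pr, c(6, 12, 18), c(3, 2, 1), forward = list(pr))
    b <- ad_diff(pr, hr, c(6, 12, 18), c(3, 2, 1), forward = list(pr))
    expect_equal(a$sq_value, b$sq_value)
    # rank SQ is non-increasing as the gap grows
    o <- order(abs(h - p))
    expect_true(all(diff(a$sq_value[o]) <= 0 | diff(abs(h - p)[o]) == 0))
  }
  tok <- mk_stream(c("^^", "150"), data_type = "PR")
  hr2 <- mk_stream(c(150, 150), data_type = "HR")
  expect_equal(ad_diff(hr2, tok, 18, 1)$sq_value, c(0, 1))
})

test_that("single-threshold differencing yields a binary SQ stream", {
  hr <- mk_stream(c(140, 140), data_type = "HR")
  pr <- mk_stream(c(145, 170), data_type = "PR")
  out <- ad_diff(hr, pr, thresholds = 18, sq_values = 1)
  expect_identical(out$sq_type, "binary")
  expect_equal(out$sq_value, c(1, 0))
})

test_that("the masked median filter matches its examples", {
  s <- mk_stream(c(90, 40, 90, 90, 90))
  out <- ad_medfilt(s, 5)
  expect_equal(stream_values(out)[5], 90)
  expect_identical(out$data_type, "SpO2Med")
  expect_equal(out$sq_value, s$sq_value)  # SQ passes through

  # med_ww = 1 is the identity on valid samples
  expect_equal(stream_values(ad_medfilt(s, 1)), stream_values(s))

  # masked sample excluded; even count averages the middle pair
  m <- mk_stream(c(90, 40, 92), sq = c(1, 0, 1))
  expect_equal(stream_values(ad_medfilt(m, 3))[3], 91)

  expect_error(ad_medfilt(s, 0), "positive integer")
})

test_that("an all-masked window holds the previous output", {
  s <- mk_stream(c("^^", 90, "^^", "^^"), sq = c(0, 1, 0, 0))
  out <- stream_values(ad_medfilt(s, 2))
  expect_true(is.na(out[1]))     # nothing seen yet
  expect_equal(out[2:3], c(90, 90))
  expect_equal(out[4], 90)       # window empty, hold
})

test_that("the median filter agrees with a sort-based oracle on random windows", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    w <- sample(1:15, 1)
    s <- random_spo2_stream(n, p_token = 0.15, p_bad_sq = 0.2)
    got <- stream_values(ad_medfilt(s, w))
    v <- stream_values(s)
    want <- median_oracle(v, s$sq_value != 0, w)
    expect_equal(got, want, info = sprintf("n=%d w=%d rep=%d", n, w, rep))
    # in-range property: output within [min, max] of valid window samples
    ok <- s$sq_value != 0 & !is.na(v)
    for (i in which(!is.na(got))) {
      win <- max(1, i - w + 1):i
      vals <- v[win][ok[win]]
      if (length(vals)) {
        expect_gte(got[i], min(vals))
        expect_lte(got[i], max(vals))
      }
    }
  }
})
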