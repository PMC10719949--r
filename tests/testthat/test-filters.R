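fs <- 200
t <- seq(0, 60, by = 1 / fs)
mid <- function(x) x[(length(x) / 3):(2 * length(x) / 3)]

test_that("slow band passes 0.8 Hz, rejects DC and 12 Hz", {
  dc <- bandpassSlow(rep(10, fs * 30), fs)
  expect_lt(max(abs(mid(dc))), 0.1)

  y <- bandpassSlow(sin(2 * pi * 0.8 * t), fs)
  expect_gte(max(abs(mid(y))), 0.9)
  expect_lte(max(abs(mid(y))), 1.0 + 1e-2)

  y12 <- bandpassSlow(sin(2 * pi * 12 * t), fs)
  expect_lt(max(abs(mid(y12))), 0.1)

  expect_error(bandpassSlow(rnorm(10), fs), "short")
})

test_that("spindle envelope tracks in-band tone amplitude, rejects slow band", {
  expect_equal(spindleEnvelope(numeric(fs * 30), fs), numeric(fs * 30))

  A <- 7
  env <- spindleEnvelope(A * sin(2 * pi * 12 * t), fs)
  expect_gte(min(mid(env)), 0.9 * A)
  expect_lte(max(mid(env)), 1.05 * A)

  env4 <- spindleEnvelope(A * sin(2 * pi * 4 * t), fs)
  expect_lt(max(mid(env4)), 0.1 * A)
})

test_that("envelope works at the minimum sampling rate for spindles", {
  fs64 <- 64
  t64 <- seq(0, 30, by = 1 / fs64)
  env <- spindleEnvelope(sin(2 * pi * 12 * t64), fs64)
  m <- env[(length(env) / 3):(2 * length(env) / 3)]
  expect_gte(min(m), 0.85)
  expect_lte(max(m), 1.1)
})
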