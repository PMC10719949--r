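test_that("envelope thresholds use masked samples and the n-1 deviation", {
  th <- computeSpindleThresholds(c(0, 0, 0, 0, 10))
  expect_equal(th$mu, 2)
  expect_equal(th$sigma, sqrt(20), tolerance = 1e-6)   # 4.4721
  expect_equal(th$lower, 2 + 1.5 * sqrt(20), tolerance = 1e-6)  # 8.708
  expect_equal(th$upper, 2 + 2.5 * sqrt(20), tolerance = 1e-6)

  thc <- computeSpindleThresholds(rep(3, 100))
  expect_equal(thc$mu, 3); expect_equal(thc$sigma, 0)
  expect_equal(thc$upper, thc$lower)

  thm <- computeSpindleThresholds(c(0, 0, 0, 0, 10),
                                  mask = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(thm$mu, 0); expect_equal(thm$sigma, 0)

  expect_warning(expect_null(
    computeSpindleThresholds(1:5, mask = rep(FALSE, 5))), "aborted")
})

test_that("spindle runs respect duration, upper threshold and the mask", {
  fs <- 200
  burst <- function(dur, total, amp = 20) {
    x <- numeric(fs * total)
    n <- round(dur * fs)
    w <- amp * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))) *
      sin(2 * pi * 12 * seq_len(n) / fs)
    x[(5 * fs):(5 * fs + n - 1)] <- w
    x + rnorm(length(x), sd = 0.05)
  }
  set.seed(1)
  env1 <- spindleEnvelope(burst(1.0, 120), fs)
  th1 <- computeSpindleThresholds(env1)
  sp1 <- detectSpindles(env1, th1, fs)
  expect_equal(nrow(sp1), 1L)
  # the reported extent must equal the supra-lower run computed directly;
  # for a Hann burst that run is shorter than the nominal duration because
  # the tapers sit below any data-derived threshold
  r <- rle(env1 > th1$lower)
  oracleRun <- max(r$lengths[r$values]) / fs
  expect_equal(sp1$offset - sp1$onset, oracleRun)
  expect_gte(sp1$offset - sp1$onset, 0.7)
  expect_lte(sp1$offset - sp1$onset, 1.15)
  expect_equal(sp1$peak_time, 5.5, tolerance = 0.1)

  env03 <- spindleEnvelope(burst(0.3, 40), fs)
  expect_equal(nrow(detectSpindles(env03, computeSpindleThresholds(env03),
                                   fs)), 0L)

  # envelope that stays between lower and upper yields nothing
  thHi <- list(mu = 0, sigma = 0, lower = 1, upper = 1e6)
  expect_equal(nrow(detectSpindles(env1, thHi, fs)), 0L)

  # runs touching masked-out samples are discarded whole
  mask <- rep(TRUE, length(env1))
  mask[round(5.5 * fs)] <- FALSE
  expect_equal(nrow(detectSpindles(env1, th1, fs, mask)), 0L)
})
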