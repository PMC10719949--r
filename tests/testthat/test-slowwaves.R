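test_that("a single sine cycle yields one candidate at the analytic extrema", {
  fs <- 200
  x <- sin(2 * pi * seq(0, 1.05, by = 1 / fs))
  cands <- extractCandidates(x, fs)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$peak_time, 0.25, tolerance = 1.5 / fs)
  expect_equal(cands$trough_time, 0.75, tolerance = 1.5 / fs)
  expect_equal(cands$peak_amp, 1, tolerance = 1e-3)
  expect_equal(cands$trough_amp, -1, tolerance = 1e-3)

  # strictly positive signal: no crossings, no candidates
  expect_equal(nrow(extractCandidates(sin(2 * pi * seq(0, 2, by = 1 / fs)) + 2,
                                      fs)), 0L)

  # two full cycles: two candidates, ordered in time
  x2 <- sin(2 * pi * seq(0, 2.05, by = 1 / fs))
  c2 <- extractCandidates(x2, fs)
  expect_equal(nrow(c2), 2L)
  expect_true(all(diff(c2$peak_time) > 0))
})

test_that("candidate extraction matches the brute-force sign-change oracle", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(50:400, 1)
    x <- as.numeric(stats::filter(rnorm(n), rep(1, 5), circular = TRUE))
    expect_equal(extractCandidates(x, 100), bruteCandidates(x, 100),
                 ignore_attr = TRUE)
  }
})

test_that("candidates touching masked-out samples are discarded whole", {
  fs <- 100
  x <- sin(2 * pi * seq(0, 3.05, by = 1 / fs))   # 3 cycles
  mask <- rep(TRUE, length(x))
  full <- extractCandidates(x, fs, mask)
  expect_equal(nrow(full), 3L)
  mask[round(1.75 * fs) + 1L] <- FALSE            # second trough (t = (i-1)/fs)
  expect_equal(nrow(extractCandidates(x, fs, mask)), 2L)
})

test_that("percentile thresholds follow the linear-interpolation convention", {
  cands <- data.frame(peak_amp = c(1, 2, 3, 4, 5),
                      trough_amp = c(-5, -4, -3, -2, -1))
  th <- computeSlowThresholds(cands)
  expect_equal(th$negative, -3.4)
  expect_equal(th$positive, 4.4)

  # degenerate distribution
  cands$trough_amp <- rep(-2, 5)
  expect_equal(computeSlowThresholds(cands)$negative, -2)

  expect_warning(expect_null(computeSlowThresholds(cands[1:3, ])),
                 "fewer than 5")
})

test_that("thresholds match a sort-and-interpolate oracle on random data", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    cands <- data.frame(peak_amp = rnorm(n, 5, 3), trough_amp = rnorm(n, -5, 3))
    th <- computeSlowThresholds(cands)
    oracle <- function(v, p) {       # h = (n-1)p + 1 on sorted values
      s <- sort(v); h <- (length(s) - 1) * p + 1
      lo <- floor(h); hi <- ceiling(h)
      s[lo] + (h - lo) * (s[hi] - s[lo])
    }
    expect_equal(th$negative, oracle(cands$trough_amp, 0.40), tolerance = 1e-9)
    expect_equal(th$positive, oracle(cands$peak_amp, 0.85), tolerance = 1e-9)
  }
})

test_that("classification separates SO, delta and discarded candidates", {
  th <- list(negative = -3.4, positive = 4.4)
  cands <- data.frame(
    peak_time = c(1, 2, 3, 4, 5),
    peak_amp = c(6, 2, 6, 6, 2),
    trough_time = c(1.3, 2.3, 3.7, 4.3, 5.6),
    trough_amp = c(-5, -5, -5, -2, -5))
  ev <- classifySlowWaves(cands, th)
  # row 1: SO; row 2: delta; row 3: lag 700 ms discarded; row 4: shallow
  # trough discarded; row 5: delta with lag 600 ms discarded
  expect_equal(ev$kind, c("SO", "delta"))
  expect_equal(ev$up_state_time, c(1, 2))

  # delta has no lower duration bound by default, SO does
  fast <- data.frame(peak_time = 1, peak_amp = 6, trough_time = 1.1,
                     trough_amp = -5)
  expect_equal(nrow(classifySlowWaves(fast, th)), 0L)  # SO-amp but lag 100 ms
  fastDelta <- transform(fast, peak_amp = 2)
  expect_equal(classifySlowWaves(fastDelta, th)$kind, "delta")

  # a candidate is never both SO and delta
  set.seed(3)
  cands <- data.frame(peak_time = 1:50,
                      peak_amp = runif(50, 0, 10),
                      trough_time = 1:50 + runif(50, 0.1, 0.6),
                      trough_amp = runif(50, -10, 0))
  th2 <- computeSlowThresholds(cands)
  ev2 <- classifySlowWaves(cands, th2)
  key <- paste(ev2$peak_time, ev2$trough_time)
  expect_false(anyDuplicated(key) > 0)
  expect_lte(nrow(ev2), nrow(cands))
})
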