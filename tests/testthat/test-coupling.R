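slowRow <- function(ch, kind, up) {
  data.frame(channel = ch, kind = kind, up_state_time = up)
}
spRow <- function(ch, pk) data.frame(channel = ch, peak_time = pk)

test_that("nesting window is -0.5 to +1.0 s around the UP state", {
  nested <- nestSpindles(slowRow("C3", "SO", 10), spRow("C3", 10.8))
  expect_equal(nrow(nested), 1L)
  expect_equal(nested$lag, 0.8)

  expect_equal(nrow(nestSpindles(slowRow("C3", "SO", 10), spRow("C3", 11.2))),
               0L)
  expect_equal(nrow(nestSpindles(slowRow("C3", "SO", 10), spRow("C3", 9.6))),
               1L)
  expect_equal(nrow(nestSpindles(slowRow("C3", "SO", 10), spRow("C3"[0], numeric(0)))),
               0L)
})

test_that("nesting is one-to-one per kind, smallest |lag| first", {
  slow <- rbind(slowRow("C3", "SO", 10), slowRow("C3", "SO", 12))
  sp <- spRow("C3", c(10.3, 11.8))
  nested <- nestSpindles(slow, sp)
  expect_equal(nrow(nested), 2L)
  expect_equal(sort(nested$spindle_peak_time), c(10.3, 11.8))
  expect_equal(sort(nested$up_state_time), c(10, 12))

  # two spindles competing for one SO: only the closer one nests
  n1 <- nestSpindles(slowRow("C3", "SO", 10), spRow("C3", c(10.3, 10.9)))
  expect_equal(nrow(n1), 1L)
  expect_equal(n1$spindle_peak_time, 10.3)

  # one spindle, two candidate SOs: pairs with the smaller |lag|
  slow2 <- rbind(slowRow("C3", "SO", 10), slowRow("C3", "SO", 10.6))
  n2 <- nestSpindles(slow2, spRow("C3", 10.5))
  expect_equal(nrow(n2), 1L)
  expect_equal(n2$up_state_time, 10.6)

  # tie in |lag| goes to the earlier slow event
  slow3 <- rbind(slowRow("C3", "delta", 10), slowRow("C3", "delta", 10.4))
  n3 <- nestSpindles(slow3, spRow("C3", 10.2))
  expect_equal(n3$up_state_time, 10)

  # same window for SO and delta: one spindle may serve both kinds
  slow4 <- rbind(slowRow("C3", "SO", 10), slowRow("C3", "delta", 10.3))
  n4 <- nestSpindles(slow4, spRow("C3", 10.5))
  expect_equal(sort(n4$slow_kind), c("SO", "delta"))
})

test_that("nested counts are bounded and the window acts monotonically", {
  set.seed(5)
  for (i in 1:20) {
    nSlow <- sample(1:15, 1); nSp <- sample(1:15, 1)
    slow <- data.frame(channel = "C3",
                       kind = sample(c("SO", "delta"), nSlow, TRUE),
                       up_state_time = sort(runif(nSlow, 0, 120)))
    sp <- data.frame(channel = "C3", peak_time = sort(runif(nSp, 0, 120)))
    nested <- nestSpindles(slow, sp)
    for (k in c("SO", "delta")) {
      expect_lte(sum(nested$slow_kind == k),
                 min(sum(slow$kind == k), nSp))
    }
    wide <- nestSpindles(slow, sp, window = c(-1, 2))
    expect_gte(nrow(wide), nrow(nested))
    expect_equal(nrow(nestSpindles(slow, sp, window = c(0, 0))), 0L)
  }
})

test_that("nesting counts aggregate by channel and kind without cross-talk", {
  nested <- rbind(
    data.frame(channel = "C3", slow_kind = rep("SO", 3),
               up_state_time = 1:3, spindle_peak_time = 1:3 + 0.2,
               lag = 0.2),
    data.frame(channel = "C3", slow_kind = rep("delta", 2),
               up_state_time = 4:5, spindle_peak_time = 4:5 + 0.2, lag = 0.2),
    data.frame(channel = "C4", slow_kind = "SO", up_state_time = 9,
               spindle_peak_time = 9.1, lag = 0.1))
  counts <- nestingCounts(nested)
  expect_equal(counts$count[counts$channel == "C3" & counts$slow_kind == "SO"], 3L)
  expect_equal(counts$count[counts$channel == "C3" & counts$slow_kind == "delta"], 2L)
  expect_equal(counts$count[counts$channel == "C4" & counts$slow_kind == "SO"], 1L)
  expect_equal(nrow(nestingCounts(nested[0, ])), 0L)
})
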