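fakeDetection <- function(slowChannels = character(0),
                          slowKinds = character(0),
                          spindleChannels = character(0)) {
  list(slow = data.frame(channel = slowChannels, kind = slowKinds,
                         up_state_time = seq_along(slowChannels)),
       spindles = data.frame(channel = spindleChannels,
                             peak_time = seq_along(spindleChannels)))
}
noNest <- data.frame(channel = character(0), slow_kind = character(0),
                     up_state_time = numeric(0),
                     spindle_peak_time = numeric(0), lag = numeric(0))

# direct construction of a density table, bypassing detection
densityTable <- function(values, channels, type = "spindle",
                         subject = "s1") {
  data.frame(subject = subject, channel = channels, event_type = type,
             count = values, minutes = 1, density = values)
}

test_that("densities are counts per retained NREM minute on a full grid", {
  det <- fakeDetection(rep("C3", 9), rep("SO", 9),
                       spindleChannels = rep("C3", 120))
  den <- computeDensity(det, noNest, minutes = c(C3 = 4.5, C4 = 60))
  expect_equal(den$density[den$channel == "C3" & den$event_type == "SO"], 2)
  expect_equal(den$density[den$channel == "C3" & den$event_type == "spindle"],
               120 / 4.5)
  expect_equal(den$density[den$channel == "C4" & den$event_type == "spindle"], 0)
  expect_equal(nrow(den), 10L)  # 2 channels x 5 types

  den2 <- computeDensity(fakeDetection(spindleChannels = rep("C4", 120)),
                         noNest, minutes = c(C4 = 60))
  expect_equal(den2$density[den2$event_type == "spindle"], 2)

  expect_warning(d0 <- computeDensity(det, noNest, minutes = c(C3 = 4.5, C4 = 0)),
                 "excluded")
  expect_false("C4" %in% d0$channel)
})

test_that("laterality index is the ratio of group mean densities", {
  g <- resolveGroups(list(stroke = c("C4", "P4"),
                          contralateral_mirror = c("C3", "P3"),
                          contralateral_non_mirror = c("F3", "O1")),
                     c("C3", "C4", "P3", "P4", "F3", "O1"))
  den <- densityTable(c(2, 4, 1, 2, 1.5, 1.5),
                      c("C4", "P4", "C3", "P3", "F3", "O1"))
  expect_equal(lateralityIndex(den, g, "spindle", denominator = "mirror"),
               3 / 1.5)
  expect_equal(lateralityIndex(den, g, "spindle"), 3 / 1.5)  # CNM mean equal

  # identical densities on every channel: LI = 1 whatever the groups
  denEq <- densityTable(rep(2, 6), c("C4", "P4", "C3", "P3", "F3", "O1"))
  expect_equal(lateralityIndex(denEq, g, "spindle"), 1)

  # healthy subjects: left over right
  gh <- resolveGroups(list(), c("C3", "C4"))
  denH <- densityTable(c(1, 2), c("C3", "C4"))
  expect_equal(lateralityIndex(denH, gh, "spindle"), 0.5)

  # scale invariance and group swap
  den10 <- densityTable(10 * c(2, 4, 1, 2, 1.5, 1.5),
                        c("C4", "P4", "C3", "P3", "F3", "O1"))
  expect_equal(lateralityIndex(den10, g, "spindle"),
               lateralityIndex(den, g, "spindle"))
  gSwap <- resolveGroups(list(stroke = c("C3", "P3"),
                              contralateral_mirror = c("C4", "P4"),
                              contralateral_non_mirror = c("F3", "O1")),
                         c("C3", "C4", "P3", "P4", "F3", "O1"))
  denSym <- densityTable(c(2, 4, 1, 2, 3, 3),
                         c("C4", "P4", "C3", "P3", "F3", "O1"))
  expect_equal(lateralityIndex(denSym, gSwap, "spindle",
                               denominator = "mirror"),
               1 / lateralityIndex(denSym, g, "spindle",
                                   denominator = "mirror"))

  # zero denominator flagged as NA
  denZ <- densityTable(c(1, 1, 0, 0, 0, 0),
                       c("C4", "P4", "C3", "P3", "F3", "O1"))
  expect_warning(li <- lateralityIndex(denZ, g, "spindle"), "undefined")
  expect_true(is.na(li))
})

test_that("LI ratio divides SO-nested by delta-nested laterality", {
  expect_equal(liRatio(1.2, 1.5), 0.8)
  expect_equal(liRatio(1.3, 1.3), 1)
  expect_warning(r <- liRatio(1.2, 0), "undefined")
  expect_true(is.na(r))
  expect_warning(is.na(liRatio(NA_real_, 1)))
})

test_that("lateralityResult reports all five types and the ratio", {
  gh <- resolveGroups(list(), c("C3", "C4"))
  den <- do.call(rbind, lapply(
    c("SO", "delta", "spindle", "SO_spindle", "delta_spindle"),
    function(tt) densityTable(c(2, 2), c("C3", "C4"), type = tt)))
  res <- lateralityResult(den, gh)
  expect_equal(nrow(res), 6L)
  expect_true(all(res$value == 1))
})
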