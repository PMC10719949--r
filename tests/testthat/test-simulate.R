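test_that("background noise hits the target RMS and is seed-reproducible", {
  spec <- smallSpec(backgroundRms = 10, durationMin = 2)
  bg <- generateBackground(spec)
  rms <- apply(samples(bg), 2, function(x) sqrt(mean(x^2)))
  expect_true(all(rms >= 9 & rms <= 11))

  bg2 <- generateBackground(spec)
  expect_identical(samples(bg), samples(bg2))

  bg3 <- generateBackground(smallSpec(seed = 43, backgroundRms = 10,
                                      durationMin = 2))
  expect_false(identical(samples(bg), samples(bg3)))
})

test_that("alpha = 0 gives a flat spectrum by periodogram regression", {
  spec <- smallSpec(alpha = 0, durationMin = 2)
  x <- samples(generateBackground(spec))[, 1]
  p <- stats::spec.pgram(x, plot = FALSE, taper = 0)
  keep <- p$freq > 0.01
  slope <- stats::coef(stats::lm(log(p$spec[keep]) ~ log(p$freq[keep])))[2]
  expect_lt(abs(slope), 0.2)
})

test_that("zero rates leave the background untouched", {
  spec <- smallSpec(soRate = 0, deltaRate = 0, spindleRate = 0,
                    durationMin = 2)
  bg <- generateBackground(spec)
  out <- injectEvents(bg, spec)
  expect_identical(samples(out$recording), samples(bg))
  expect_equal(nrow(out$truth), 0L)
})

test_that("injected counts track rates and keep 2 s slow-event spacing", {
  spec <- smallSpec(soRate = 2, deltaRate = 3, durationMin = 10, seed = 8)
  sim <- simulateSubject(spec)
  perCh <- table(sim$truth$channel[sim$truth$type == "SO"])
  expect_true(all(abs(perCh - 20) <= 3 * sqrt(20)))
  perDe <- table(sim$truth$channel[sim$truth$type == "delta"])
  expect_true(all(abs(perDe - 30) <= 3 * sqrt(30)))

  for (ch in unique(sim$truth$channel)) {
    peaks <- sort(sim$truth$peak_time[sim$truth$channel == ch &
                                        sim$truth$type != "spindle"])
    if (length(peaks) > 1) expect_gte(min(diff(peaks)), 2 - 1e-9)
  }

  # every nested spindle references an existing slow event on its channel
  sp <- sim$truth[sim$truth$type == "spindle" & !is.na(sim$truth$nested_kind), ]
  for (i in seq_len(nrow(sp))) {
    host <- sim$truth[sim$truth$channel == sp$channel[i] &
                        sim$truth$type == sp$nested_kind[i] &
                        abs(sim$truth$peak_time - sp$host_up_time[i]) < 1e-9, ]
    expect_equal(nrow(host), 1L)
    lag <- sp$peak_time[i] - sp$host_up_time[i]
    expect_gte(lag, -0.5); expect_lte(lag, 1.0)
  }
})

test_that("hemispheric asymmetry scales injected rates on one side", {
  spec <- smallSpec(asymmetry = 2, asymmetryHemisphere = "right",
                    durationMin = 10, seed = 12)
  sim <- simulateSubject(spec)
  hemi <- hemisphereOf(sim$truth$channel)
  for (tt in c("SO", "delta", "spindle")) {
    ratio <- sum(hemi == "right" & sim$truth$type == tt) /
      sum(hemi == "left" & sim$truth$type == tt)
    expect_gt(ratio, 1.6); expect_lt(ratio, 2.4)
  }
})

test_that("emitted datasets round-trip through both formats", {
  spec <- smallSpec(durationMin = 2)
  sim <- simulateSubject(spec)
  for (fmt in c("delimited", "edf")) {
    outdir <- file.path(tempfile(), fmt)
    files <- emitDataset(sim$recording, sim$truth, outdir, format = fmt)
    expect_true(all(file.exists(files)))
    rec <- loadRecording(files["recording"])
    expect_identical(channelNames(rec), channelNames(sim$recording))
    tol <- if (fmt == "edf") 0.02 else 1e-5
    expect_lt(max(abs(samples(rec) - samples(sim$recording))), tol)
    hyp <- readHypnogram(files["hypnogram"])
    expect_equal(nEpochs(hyp), ceiling(2 * 60 / 30))
    expect_true(all(isNREM(hyp)))
    gt <- utils::read.table(files["ground_truth"], header = TRUE, sep = "\t")
    expect_equal(nrow(gt), nrow(sim$truth))
    cfg <- readGroupsConfig(files["config"])
    expect_setequal(unlist(cfg$left), c("F3", "C3", "P3", "O1"))
  }
})
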