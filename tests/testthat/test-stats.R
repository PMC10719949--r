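test_that("paired t-test matches the textbook statistic", {
  r <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0); expect_equal(r$p, 1)

  r2 <- pairedTTest(c(2, 3, 5, 6), c(1, 2, 3, 4))   # differences 1,1,2,2
  expect_equal(r2$t, 5.196152, tolerance = 1e-6)
  expect_equal(r2$p, 0.01385, tolerance = 1e-3)
  expect_equal(r2$df, 3)

  expect_error(pairedTTest(1:3, 1:4), "equal-length")
  expect_error(pairedTTest(c(2, 3, 4), c(1, 2, 3)), "zero variance")
})

test_that("one-way ANOVA matches the classic F and flags degeneracy", {
  r <- oneWayAnova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$F, 0); expect_equal(r$p, 1)
  expect_false(r$degenerate)

  expect_warning(d <- oneWayAnova(list(c(1, 1), c(5, 5))), "degenerate")
  expect_true(d$degenerate); expect_true(is.nan(d$F))

  expect_error(oneWayAnova(list(1:3)), "at least 2 groups")
  expect_error(oneWayAnova(list(1:3, 5)), "at least 2 values")

  # cross-check against stats::aov on a random case
  set.seed(2)
  g <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  r3 <- oneWayAnova(g)
  fit <- summary(stats::aov(y ~ grp, data = data.frame(
    y = unlist(g), grp = factor(rep(1:3, each = 8)))))[[1]]
  expect_equal(r3$F, fit$`F value`[1], tolerance = 1e-8)
  expect_equal(r3$p, fit$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("Cohen's d classes follow the 0.20/0.50/0.80 bands", {
  expect_equal(classifyEffectSize(0.1), "negligible")
  expect_equal(classifyEffectSize(0.20), "small")
  expect_equal(classifyEffectSize(-0.49), "small")
  expect_equal(classifyEffectSize(0.50), "medium")
  expect_equal(classifyEffectSize(0.79), "medium")
  expect_equal(classifyEffectSize(0.80), "large")
  expect_equal(classifyEffectSize(-2), "large")
})

simulateCohortTable <- function(effect, nPatients = 5, nElectrodes = 8,
                                sdPatient = 0.5, sdNoise = 1) {
  rows <- list()
  meds <- rep(c("group1_propofol", "group2_levetiracetam", "group3_other"),
              length.out = nPatients)
  for (p in seq_len(nPatients)) {
    b <- rnorm(1, sd = sdPatient)
    cls <- rep(c(1, 0), each = nElectrodes / 2)
    rows[[p]] <- data.frame(
      patient = paste0("P", p), medication_group = meds[p],
      electrode_class = cls, channel = paste0("E", seq_len(nElectrodes)),
      density = 5 + b + effect * cls + rnorm(nElectrodes, sd = sdNoise))
  }
  do.call(rbind, rows)
}

test_that("mixed model recovers a strong electrode effect", {
  set.seed(11)
  tab <- simulateCohortTable(effect = 2)
  fit <- suppressWarnings(fitMixedModel(tab))
  expect_gt(fit$estimate, 1)
  expect_lt(fit$p, 0.05)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)
  expect_equal(fit$magnitude, classifyEffectSize(fit$d))
  expect_gt(fit$d, 0.8)

  # residual-only standardizer never shrinks |d|
  fitR <- suppressWarnings(fitMixedModel(tab, standardizer = "residual"))
  expect_gte(abs(fitR$d), abs(fit$d))
})

test_that("mixed model needs two patients and both electrode classes", {
  tab <- simulateCohortTable(effect = 0, nPatients = 1)
  expect_error(fitMixedModel(tab), "2 patients")
})
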