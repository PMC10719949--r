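test_that("scalp map interpolation is exact at electrodes", {
  v <- c(FP1 = 1, FP2 = 0.5, C3 = 2, C4 = 0, O1 = 1.2, O2 = 0.3, CZ = 1.1)
  map <- scalpMap(v)
  pos <- electrodePositions(names(v))
  at <- evalScalpMap(map, pos$x, pos$y)
  expect_equal(at, unname(v), tolerance = 1e-6)

  # constant input gives a constant field
  vc <- c(FP1 = 2, FP2 = 2, C3 = 2, C4 = 2)
  mc <- scalpMap(vc)
  expect_equal(range(mc$z, na.rm = TRUE), c(2, 2), tolerance = 1e-6)

  # a lone bump at C3 peaks at C3
  vb <- c(C3 = 1, C4 = 0, F3 = 0, F4 = 0, P3 = 0, P4 = 0)
  mb <- scalpMap(vb)
  peak <- which(mb$z == max(mb$z, na.rm = TRUE), arr.ind = TRUE)
  c3 <- electrodePositions("C3")
  expect_lt(abs(mb$x[peak[1]] - c3$x), 0.12)
  expect_lt(abs(mb$y[peak[2]] - c3$y), 0.12)

  expect_error(scalpMap(c(C3 = 1, C4 = 2, CZ = 1)), "at least 4")
})

test_that("scalp maps render to PNG", {
  v <- c(F3 = 1, F4 = 0.4, C3 = 2, C4 = 0.2, P3 = 0.9, P4 = 0.6)
  tf <- tempfile(fileext = ".png")
  plotScalpMap(scalpMap(v), tf, main = "spindle density")
  expect_true(file.exists(tf) && file.size(tf) > 0)
})
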