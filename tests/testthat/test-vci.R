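test_that("the comparative index reproduces the worked table examples", {
  # opposite-direction changes still compare magnitudes
  expect_equal(round(vci(126.86, 125.17, 106.39, 114.63), 2), 0.21)
  expect_lt(vci(126.86, 125.17, 106.39, 114.63, absolute = FALSE), 0)
  # mean systemic arterial pressure at 8 METs
  expect_equal(round(vci(126.17, 92.26, 124.24, 102.52), 2), 1.56)
  # pulmonary venous pressure at 4 METs
  expect_equal(round(vci(10.97, 10.53, 10.90, 10.28), 2), 0.71)
  # equal variations in both arms
  expect_equal(vci(10, 5, 105, 100), 1)
})

test_that("zero variation in the reference arm yields a flagged undefined
          index", {
  expect_warning(out <- vci(2, 1, 5, 5), "undefined VCI")
  expect_true(is.nan(out))
})

test_that("the index is invariant to affine unit changes", {
  set.seed(31)
  for (i in 1:30) {
    q <- stats::rnorm(4, 50, 20)
    a <- stats::runif(1, 0.1, 10)
    b <- stats::rnorm(1, 0, 40)
    v0 <- vci(q[1], q[2], q[3], q[4])
    v1 <- vci(a * q[1] + b, a * q[2] + b, a * q[3] + b, a * q[4] + b)
    expect_equal(v1, v0, tolerance = 1e-10)
  }
})

test_that("relevance thresholds are inclusive and monotone", {
  expect_equal(classify_vci(1.15), "relevant-SHR")
  expect_equal(classify_vci(0.85), "relevant-HHR")
  expect_equal(classify_vci(1.0), "not-relevant")
  expect_equal(classify_vci(c(1.149, 0.851)), rep("not-relevant", 2))
  expect_true(is.na(classify_vci(NaN)))

  # monotone: increasing VCI never leaves relevant-SHR
  grid <- seq(0.5, 2, by = 0.01)
  cls <- classify_vci(grid)
  first_shr <- match("relevant-SHR", cls)
  expect_true(all(cls[first_shr:length(cls)] == "relevant-SHR"))
  last_hhr <- max(which(cls == "relevant-HHR"))
  expect_true(all(cls[1:last_hhr] == "relevant-HHR"))
})

test_that("the full VCI table recomputed from the published means matches
          the published indexes", {
  to_stats <- function(tab, met) {
    data.frame(variable = tab$variable,
               mean = tab[[paste0("met", met, "_mean")]])
  }
  shr_tab <- ref_af_stats("SHR")
  hhr_tab <- ref_af_stats("HHR")
  shr <- lapply(stats::setNames(c(1, 4, 6, 8),
                                paste0("met", c(1, 4, 6, 8))),
                to_stats, tab = shr_tab)
  hhr <- lapply(stats::setNames(c(1, 4, 6, 8),
                                paste0("met", c(1, 4, 6, 8))),
                to_stats, tab = hhr_tab)
  v <- vci_table(shr, hhr)
  ref <- ref_vci()
  for (col in c("VCI_4", "VCI_6", "VCI_8"))
    expect_lt(max(abs(v[[col]] - ref[[col]])), 0.02 + 1e-9)
  # bold rule: relevance flag means at least one index beyond a threshold
  m <- as.matrix(v[paste0("VCI_", c(4, 6, 8))])
  expect_equal(v$relevant, unname(apply(m, 1, function(x)
    any(x >= 1.15 | x <= 0.85))))
})
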