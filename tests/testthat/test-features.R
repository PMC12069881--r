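test_that("DB4 decomposition has the expected structure and coefficients", {
  ## zero in, zero out
  wc0 <- db4_decompose(rep(0, 200))
  expect_true(all(abs(unlist(coeff_sets(wc0))) == 0))
  expect_length(coeff_sets(wc0), 5)
  ## coefficient-set lengths for n = 200 under symmetric extension
  set.seed(1)
  wc <- db4_decompose(rnorm(200))
  expect_equal(length(wc$approx), 19)
  expect_equal(vapply(wc$details, length, integer(1)), c(19L, 31L, 55L, 103L))
  ## single-level coefficients frozen from an independent reference
  ## implementation of the same transform (x = 1..16, symmetric extension)
  ca_ref <- c(7.064531462580935, 4.230736111149599, 1.413607166075824,
              2.836054280342409, 5.664481405088599, 8.49290852983479,
              11.32133565458098, 14.14976277932717, 16.97709909776168,
              19.810894449193015, 22.62802339426679)
  cd_ref <- c(2.371313062622617e-02, 4.096208639586620e-02,
              -6.467521702209224e-02, 0, 0, 0, 0, 0,
              -2.371313062622554e-02, -4.096208639586560e-02,
              6.467521702209250e-02)
  wc1 <- db4_decompose(1:16, levels = 1)
  expect_equal(wc1$approx, ca_ref, tolerance = 1e-12)
  expect_equal(wc1$details[[1]], cd_ref, tolerance = 1e-12)
  expect_error(db4_decompose(rnorm(10), levels = 4), "short")
})

test_that("the inverse transform reconstructs the input (orthogonal wavelet)", {
  set.seed(2)
  for (n in c(200, 250, 97)) {
    x <- rnorm(n)
    lev <- if (n >= 64) 4 else 3
    wc <- db4_decompose(x, levels = lev)
    expect_lt(max(abs(db4_reconstruct(wc) - x)) / max(abs(x)), 1e-8)
  }
})

test_that("periodic-mode transform conserves energy (Parseval)", {
  set.seed(3)
  x <- rnorm(208)  # even length at all four levels
  wc <- db4_decompose(x, levels = 4, mode = "periodic")
  e <- sum(vapply(coeff_sets(wc), function(cs) sum(cs^2), numeric(1)))
  expect_equal(e, sum(x^2), tolerance = 1e-10)
  expect_lt(max(abs(db4_reconstruct(wc) - x)), 1e-10)
})

test_that("the 12 coefficient-set features follow their definitions", {
  f <- featurize_set(rep(4, 10))
  expect_equal(unname(f[c("mean", "sd", "var", "rms", "zero_cross",
                          "mean_cross")]),
               c(4, 0, 0, 4, 0, 0))
  f2 <- featurize_set(c(1, -1, 1, -1))
  expect_equal(unname(f2["zero_cross"]), 3)
  expect_equal(unname(f2["mean"]), 0)
  expect_equal(unname(f2["rms"]), 1)
  ## uniform energy over m coefficients: entropy log(m)
  expect_equal(unname(featurize_set(c(2, -2, 2, -2, 2))["entropy"]), log(5))
  expect_length(featurize_set(rnorm(30)), 12)
  expect_error(featurize_set(numeric(0)), "empty")
})

test_that("channel featurisation yields 60 named features", {
  f <- featurize_channel(rnorm(200))
  expect_length(f, 60)
  expect_true(all(grepl("^(a4|d[1-4])_", names(f))))
  w <- featurize_window(matrix(rnorm(8 * 250), 8, 250))
  expect_length(w, 480)
  expect_equal(sum(startsWith(names(w), "ch03_")), 60)
})

test_that("information gain matches hand arithmetic and behaves at the extremes", {
  ## perfect predictor with balanced classes: 1 bit
  y <- rep(c(TRUE, FALSE), 20)
  expect_equal(information_gain(as.numeric(y), y), 1, tolerance = 1e-12)
  ## hand-computed 2x2 contingency: x=0 -> (3,1), x=1 -> (1,3)
  x <- c(rep(0, 4), rep(1, 4))
  yy <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  hand <- h(c(0.5, 0.5)) - (0.5 * h(c(3, 1) / 4) + 0.5 * h(c(1, 3) / 4))
  expect_equal(information_gain(x, yy, bins = 2), hand, tolerance = 1e-12)
  expect_equal(information_gain(x, yy, method = "threshold"), hand,
               tolerance = 1e-12)
  ## independent feature: below the permutation-null 95th percentile
  set.seed(5)
  xr <- rnorm(300)
  yr <- rep(c(TRUE, FALSE), 150)
  obs <- information_gain(xr, yr)
  null <- vapply(1:200, function(i) information_gain(xr, sample(yr)),
                 numeric(1))
  expect_lte(obs, quantile(null, 0.95) + 1e-12)
  ## degenerate labels
  expect_equal(information_gain(xr, rep(TRUE, 300)), 0)
  expect_equal(information_gain(rep(1, 300), yr), 0)
  expect_error(information_gain(c(1, NA), c(TRUE, FALSE)), "finite")
})

test_that("the selector keeps exactly 4 features per channel and recovers planted ones", {
  set.seed(6)
  n <- 200
  y <- rep(c(TRUE, FALSE), n / 2)
  stats <- c("entropy", "p05", "p25", "p75", "p95", "median", "mean", "sd",
             "var", "rms", "zero_cross", "mean_cross")
  cn <- as.vector(outer(paste0("ch0", 1:8), as.vector(outer(
    c("a4", "d4", "d3", "d2", "d1"), stats, paste, sep = "_")),
    paste, sep = "_"))
  x <- matrix(rnorm(n * length(cn)), n, length(cn))
  colnames(x) <- cn
  planted <- lapply(1:8, function(ch) {
    cols <- sample(grep(sprintf("^ch0%d_", ch), cn), 4)
    for (j in cols) x[y, j] <<- x[y, j] + 3
    sort(cn[cols])
  })
  sel <- fit_selector(x, y)
  expect_length(unlist(sel$selected), 32)
  for (ch in 1:8)
    expect_setequal(sel$selected[[paste0("ch0", ch)]], planted[[ch]])
  out <- apply_selector(sel, x)
  expect_equal(ncol(out), 32)
  ## determinism
  sel2 <- fit_selector(x, y)
  expect_identical(sel$selected, sel2$selected)
})

test_that("a constant channel is flagged and filled by the tie-break", {
  set.seed(7)
  n <- 80
  y <- rep(c(TRUE, FALSE), n / 2)
  cn <- as.vector(t(outer(paste0("ch0", 1:2), paste0("f", 1:10),
                          paste, sep = "_")))
  x <- matrix(rnorm(n * 20), n, 20)
  colnames(x) <- cn
  x[, startsWith(cn, "ch02_")] <- 1  # degenerate channel
  sel <- fit_selector(x, y)
  expect_true("ch02" %in% sel$flags)
  ## tie-break: the first four columns of the degenerate channel
  expect_equal(sel$selected[["ch02"]], paste0("ch02_f", 1:4))
})

test_that("zero-noise risky and non-risky windows are linearly separable", {
  fx <- zn_windows()
  d <- as.data.frame(fx$x)
  d$y <- fx$win$labels
  fit <- suppressWarnings(glm(y ~ ., binomial(), d))
  pred <- predict(fit, type = "response") >= 0.5
  expect_gte(balanced_accuracy(d$y, pred), 0.9)
})
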