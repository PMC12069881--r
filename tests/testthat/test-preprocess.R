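test_that("baseline correction removes the resting-state offset", {
  ts <- seq(0, 30, by = 0.02)
  const <- matrix(3.7, 2, length(ts))
  expect_equal(baseline_correct(const, 20, ts),
               matrix(0, 2, length(ts)), ignore_attr = TRUE)
  ## offset plus spike: spike preserved, offset removed
  x <- matrix(5, 1, length(ts))
  x[1, 1300] <- 5 + 2
  out <- baseline_correct(x, 20, ts)
  base_idx <- ts <= 20
  expect_lt(abs(mean(out[1, base_idx])), 2 / sum(base_idx) + 1e-12)
  expect_equal(out[1, 1300] - out[1, 1299], 2)
  ## synthetic episode with drift: baseline-window mean ~ 0
  ep <- generate_episode(35, list(), seed = 1)
  bc <- baseline_correct(ep, 20)
  idx <- bc$timestamps <= 20
  expect_lt(max(abs(rowMeans(bc$hbo[, idx]))), 1e-12)
  expect_error(baseline_correct(matrix(1, 1, 10), 20, seq(0, 0.18, by = 0.02)),
               "shorter")
})

test_that("cubic-spline resampling reproduces polynomials and smooth signals", {
  ## already-uniform 50 Hz input is returned unchanged on the shared grid
  ts <- seq(0, 2, by = 0.02)
  v <- sin(ts)
  out <- resample_50hz(ts, v)
  expect_equal(out$time, ts)
  expect_equal(out$values, v, tolerance = 1e-12)
  ## cubic polynomial sampled irregularly: exact recovery
  set.seed(1)
  ti <- sort(runif(80, 0, 4))
  p <- function(t) 2 - t + 0.5 * t^2 - 0.1 * t^3
  outp <- resample_50hz(ti, p(ti))
  expect_equal(outp$values, p(outp$time), tolerance = 1e-9)
  ## jittered sine at 0.5 Hz: error below 1e-3 of amplitude
  tj <- seq(0, 10, by = 0.02) + runif(501, -0.004, 0.004)
  tj <- sort(tj)
  outs <- resample_50hz(tj, sin(2 * pi * 0.5 * tj))
  interior <- outs$time > 0.2 & outs$time < 9.8
  expect_lt(max(abs(outs$values - sin(2 * pi * 0.5 * outs$time))[interior]),
            1e-3)
  expect_error(resample_50hz(c(1, 2, 2, 3), 1:4), "increasing")
  expect_error(resample_50hz(c(1, 2, 3), 1:3), "4 samples")
})

test_that("DEMA recursion matches its closed-form behaviour", {
  ## constant input converges to the input (unit DC gain)
  st <- list(y1 = 0, y2 = 0)
  for (i in 1:5000) { r <- dema_step(7, 0.055, st); st <- r$state }
  expect_equal(r$y, 7, tolerance = 1e-9)
  ## impulse response equals a literal high-precision recursion
  lam <- 0.055
  n <- 200
  x <- c(1, rep(0, n - 1))
  st <- list(y1 = 0, y2 = 0)
  mine <- numeric(n)
  for (i in seq_len(n)) { r <- dema_step(x[i], lam, st); st <- r$state; mine[i] <- r$y }
  y1 <- 0; y2 <- 0; oracle <- numeric(n)
  for (i in seq_len(n)) {
    y1 <- (1 - lam) * y1 + lam * x[i]
    y2 <- (1 - lam) * y2 + lam * y1
    oracle[i] <- 2 * y1 - y2
  }
  expect_equal(mine, oracle, tolerance = 1e-14)
  expect_error(dema_step(1, 1, st), "lambda")
  expect_error(dema_step(1, 0, st), "lambda")
})

test_that("MACD band-pass blocks DC and matches the analytic transfer function", {
  p <- filter_params()
  x <- rep(2.5, 4000)
  y <- macd_bandpass(x, p)
  expect_lt(abs(y[4000]), 1e-6)  # DC rejected
  ## single-frequency gains match the closed-form response
  fs <- p$fs
  for (f0 in c(0.2, 5)) {
    t <- seq(0, 120, by = 1 / fs)
    s <- sin(2 * pi * f0 * t)
    out <- macd_bandpass(s, p)
    tail_amp <- max(abs(out[(length(out) - 10 * fs):length(out)]))
    expect_equal(tail_amp, freq_response(f0, p, include_sma = TRUE),
                 tolerance = 0.05)
  }
  ## passband gain far exceeds stopband gain
  expect_gt(freq_response(0.2, p, TRUE) / freq_response(5, p, TRUE), 50)
})

test_that("streaming and batch filtering agree to 1e-10", {
  set.seed(3)
  p <- filter_params()
  x <- matrix(rnorm(8 * 1500, 0, 0.5), 8, 1500)
  batch <- macd_bandpass(x, p)
  st <- filter_state(8, p)
  stream <- matrix(0, 8, 1500)
  for (i in seq_len(1500)) {
    r <- macd_step(x[, i], st)
    st <- r$state
    stream[, i] <- r$y
  }
  expect_lt(max(abs(stream - batch)), 1e-10)
  expect_error(macd_step(x[1:3, 1], st), "channel")
})

test_that("the filter chain is linear after baseline correction", {
  set.seed(4)
  p <- filter_params()
  x <- rnorm(1000)
  expect_equal(macd_bandpass(3 * x, p), 3 * macd_bandpass(x, p),
               tolerance = 1e-12)
  y <- rnorm(1000)
  expect_equal(macd_bandpass(x + y, p),
               macd_bandpass(x, p) + macd_bandpass(y, p), tolerance = 1e-12)
})

test_that("DEMA lags a ramp less than a single EMA at equal lambda", {
  lam <- 0.02
  n <- 3000
  x <- seq_len(n)  # unit-slope ramp
  ema <- as.numeric(stats::filter(lam * x, 1 - lam, method = "recursive"))
  st <- list(y1 = 0, y2 = 0)
  dema <- numeric(n)
  for (i in seq_len(n)) { r <- dema_step(x[i], lam, st); st <- r$state; dema[i] <- r$y }
  expect_lt(abs(x[n] - dema[n]), abs(x[n] - ema[n]))
})

test_that("oxygen-exchange index follows its definition", {
  expect_equal(compute_coe(0.2, 0.4), -0.1)
  expect_equal(compute_coe(matrix(1, 2, 2), matrix(1, 2, 2)),
               matrix(0, 2, 2))
  a1 <- matrix(rnorm(4), 2); a2 <- matrix(rnorm(4), 2)
  b1 <- matrix(rnorm(4), 2); b2 <- matrix(rnorm(4), 2)
  expect_equal(compute_coe(a1 + b1, a2 + b2),
               compute_coe(a1, a2) + compute_coe(b1, b2))
  expect_error(compute_coe(matrix(1, 2, 3), matrix(1, 3, 2)), "shape")
})

test_that("rolling buffers emit 8 x 250 slices at the configured stride", {
  ep <- generate_episode(30, list(c(22, 26)), seed = 5)
  slices <- slice_stream(ep, stride_s = 1)
  expect_gt(length(slices), 0)
  for (s in slices[c(1, length(slices))]) {
    expect_equal(dim(s$hbo), c(8, 250))
    expect_equal(dim(s$coe), c(8, 250))
    expect_equal(s$coe, (s$hbr - s$hbo) / 2)
  }
  ## first emission only after 5 s of data
  expect_gte(slices[[1]]$t_end, 5 - 0.03)
  ## consecutive slices overlap by 250 - stride * 50 samples
  s1 <- slices[[1]]; s2 <- slices[[2]]
  expect_equal(s1$coe[, 51:250], s2$coe[, 1:200], tolerance = 1e-12)
  ## a stream shorter than the buffer emits nothing
  short <- generate_episode(21.5, list(), baseline_s = 20, seed = 1)
  short$timestamps <- short$timestamps[1:200]
  short$hbo <- short$hbo[, 1:200]; short$hbr <- short$hbr[, 1:200]
  short$button <- short$button[1:200]
  short$baseline_s <- 2
  expect_length(slice_stream(short), 0)
})

test_that("band edges respond to the design parameters", {
  e <- band_edges(filter_params())
  ## faster lambda2 raises the upper edge; slower lambda1 lowers the lower edge
  e_fast <- band_edges(filter_params(lambda2 = 0.11))
  expect_gt(e_fast["upper"], e["upper"])
  e_slow <- band_edges(filter_params(lambda1 = 0.0005))
  expect_lt(e_slow["lower"], e["lower"])
  ## the SMA smoother dominates the upper edge of the full cascade
  e_sma <- band_edges(filter_params(), include_sma = TRUE)
  expect_lt(e_sma["upper"], e["upper"])
  tab <- freq_response_table(n = 50)
  expect_equal(names(tab), c("freq_hz", "gain"))
})
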