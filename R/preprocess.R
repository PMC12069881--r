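#' Band-pass filter parameters
#'
#' The real-time filter is the difference of two double-exponential moving
#' averages (DEMA), a moving-average-convergence-divergence (MACD) style
#' band-pass, followed by a causal simple moving average (SMA). With the
#' defaults (`lambda1 = 0.001`, `lambda2 = 0.055`, 100-point SMA, 50 Hz) the
#' band-pass stage passes roughly 0.01--0.90 Hz: see [band_edges()].
#'
#' @param lambda1 smoothing constant of the slow DEMA (sets the lower edge).
#' @param lambda2 smoothing constant of the fast DEMA (sets the upper edge);
#'   must satisfy `0 < lambda1 < lambda2 < 1`.
#' @param sma_len length of the causal simple moving average, in samples.
#' @param fs sampling rate in Hz.
#' @param init filter state initialisation: `"first"` seeds the recursions
#'   with the first sample (avoids a multi-second start-up transient),
#'   `"zero"` starts from rest.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(lambda1 = 0.001, lambda2 = 0.055, sma_len = 100,
                          fs = 50, init = c("first", "zero")) {
  init <- match.arg(init)
  if (!(lambda1 > 0 && lambda1 < lambda2 && lambda2 < 1))
    stop("need 0 < lambda1 < lambda2 < 1")
  if (sma_len < 1) stop("sma_len must be >= 1")
  if (fs <= 0) stop("fs must be positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, sma_len = sma_len,
                 fs = fs, init = init),
            class = "filter_params")
}

#' Initialise streaming filter state
#'
#' Holds the four recursive DEMA accumulators (two per smoothing constant)
#' and the SMA ring buffer, one set per channel.
#'
#' @param n_channels number of channels.
#' @param params a [filter_params()].
#' @return An object of class `filter_state`; all accumulators zero and the
#'   ring buffer empty (a reset state).
#' @export
filter_state <- function(n_channels, params = filter_params()) {
  structure(list(n_channels = n_channels, params = params,
                 y1a = rep(0, n_channels), y2a = rep(0, n_channels),
                 y1b = rep(0, n_channels), y2b = rep(0, n_channels),
                 ring = matrix(0, n_channels, params$sma_len),
                 count = 0L, seeded = FALSE),
            class = "filter_state")
}

#' Single DEMA recursion step
#'
#' One update of the double exponential moving average
#' `y1 <- (1-lambda) y1 + lambda x`, `y2 <- (1-lambda) y2 + lambda y1`,
#' output `2 y1 - y2`. The converged filter has unit DC gain.
#'
#' @param x_n current input (scalar or per-channel vector).
#' @param lambda smoothing constant in (0, 1).
#' @param state list with accumulators `y1`, `y2` (initialise at 0 or at the
#'   first sample).
#' @return List with `y` (filter output) and updated `state`.
#' @export
dema_step <- function(x_n, lambda, state) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  y1 <- (1 - lambda) * state$y1 + lambda * x_n
  y2 <- (1 - lambda) * state$y2 + lambda * y1
  list(y = 2 * y1 - y2, state = list(y1 = y1, y2 = y2))
}

## batch DEMA along a vector using two cascaded recursive filters
dema_filter_vec <- function(x, lambda, init_val = 0) {
  y1 <- stats::filter(lambda * x, 1 - lambda, method = "recursive",
                      init = init_val)
  y2 <- stats::filter(lambda * y1, 1 - lambda, method = "recursive",
                      init = init_val)
  as.numeric(2 * y1 - y2)
}

## causal SMA with partial windows during warm-up
sma_causal <- function(x, len) {
  if (len == 1L) return(x)
  n <- length(x)
  cs <- cumsum(x)
  lag <- c(rep(0, min(len, n)), if (n > len) cs[seq_len(n - len)])
  denom <- pmin(seq_len(n), len)
  (cs - lag[seq_len(n)]) / denom
}

#' MACD-style band-pass filter (batch)
#'
#' `y = DEMA_lambda1(x) - DEMA_lambda2(x)`, smoothed with a causal
#' `sma_len`-point simple moving average. The steady-state response to a
#' constant input is 0 (DC blocked) and the filter is causal. Rows are
#' channels when `x` is a matrix.
#'
#' @param x numeric vector, or channel x sample matrix.
#' @param params a [filter_params()].
#' @return Filtered signal, same shape as `x`.
#' @seealso [macd_step()] for the sample-by-sample version, which produces
#'   identical output given the same initialisation.
#' @export
macd_bandpass <- function(x, params = filter_params()) {
  f <- function(v) {
    init <- if (params$init == "first") v[1] else 0
    ## seeded recursions: y1 = y2 = init before the first sample
    d <- dema_filter_vec(v, params$lambda1, init) -
      dema_filter_vec(v, params$lambda2, init)
    sma_causal(d, params$sma_len)
  }
  if (is.matrix(x)) t(apply(x, 1, f)) else f(x)
}

#' MACD-style band-pass filter (streaming)
#'
#' Processes one sample (per channel) and updates the persistent
#' [filter_state()]. Processing a signal sample-by-sample equals the batch
#' [macd_bandpass()] result to within floating-point rounding.
#'
#' @param x_n scalar or per-channel vector input.
#' @param state a [filter_state()].
#' @return List with `y` (per-channel output) and the updated `state`.
#' @export
macd_step <- function(x_n, state) {
  p <- state$params
  if (length(x_n) != state$n_channels)
    stop("input length does not match filter state channel count")
  if (!state$seeded && p$init == "first") {
    state$y1a <- state$y2a <- state$y1b <- state$y2b <- x_n
  }
  state$seeded <- TRUE
  a <- dema_step(x_n, p$lambda1, list(y1 = state$y1a, y2 = state$y2a))
  b <- dema_step(x_n, p$lambda2, list(y1 = state$y1b, y2 = state$y2b))
  state$y1a <- a$state$y1; state$y2a <- a$state$y2
  state$y1b <- b$state$y1; state$y2b <- b$state$y2
  d <- a$y - b$y
  slot <- (state$count %% p$sma_len) + 1L
  state$ring[, slot] <- d
  state$count <- state$count + 1L
  k <- min(state$count, p$sma_len)
  y <- rowSums(state$ring[, seq_len(k), drop = FALSE]) / k
  ## ring order does not matter for a plain mean, but warm-up must divide
  ## by the fill level, matching sma_causal()
  list(y = y, state = state)
}

#' Baseline-correct a series against its initial resting window
#'
#' Subtracts, per channel, the mean over the first `baseline_window_s`
#' seconds (the pre-stimulus resting state), so concentration changes are
#' relative to rest.
#'
#' @param x a `hemo_episode`, or a channel x sample matrix.
#' @param baseline_window_s resting window length in seconds.
#' @param timestamps sample times; required for matrix input.
#' @return Same type as `x`, baseline-corrected (both chromophores for an
#'   episode).
#' @export
baseline_correct <- function(x, baseline_window_s = 20, timestamps = NULL) {
  if (inherits(x, "hemo_episode")) {
    x$hbo <- baseline_correct(x$hbo, baseline_window_s, x$timestamps)
    x$hbr <- baseline_correct(x$hbr, baseline_window_s, x$timestamps)
    return(x)
  }
  if (is.null(timestamps)) stop("timestamps required for matrix input")
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  idx <- timestamps <= timestamps[1] + baseline_window_s
  if (max(timestamps) - timestamps[1] <= baseline_window_s)
    stop("series shorter than the baseline window")
  x - rowMeans(x[, idx, drop = FALSE])
}

#' Resample an irregular series to a uniform 50 Hz grid
#'
#' Cubic-spline interpolation (classic piecewise-cubic spline,
#' Forsythe-Malcolm-Moler end conditions) evaluated on a uniform grid at
#' `fs` Hz spanning the input range.
#'
#' @param timestamps strictly increasing sample times (>= 4 samples).
#' @param values numeric vector, or channel x sample matrix.
#' @param fs target rate, Hz.
#' @return List with `time` (uniform grid) and `values` (same shape
#'   convention as the input).
#' @export
resample_50hz <- function(timestamps, values, fs = 50) {
  if (length(timestamps) < 4) stop("need at least 4 samples")
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  grid <- seq(timestamps[1], timestamps[length(timestamps)], by = 1 / fs)
  interp <- function(v) splinefun(timestamps, v, method = "fmm")(grid)
  out <- if (is.matrix(values)) t(apply(values, 1, interp)) else interp(values)
  list(time = grid, values = out)
}

#' Oxygen-exchange index
#'
#' `coe = (hbr - hbo) / 2`, the brain-activity indicator used for feature
#' extraction (cortical activation raises dHbO and lowers dHbR, so
#' activation drives it negative).
#'
#' @param hbr,hbo equal-shape matrices or vectors (uM).
#' @return Elementwise `(hbr - hbo) / 2`.
#' @export
compute_coe <- function(hbr, hbo) {
  if (!identical(dim(hbr), dim(hbo)) || length(hbr) != length(hbo))
    stop("hbr and hbo must have identical shape")
  (hbr - hbo) / 2
}

#' Run the full preprocessing chain and emit rolling 5-s slices
#'
#' Baseline-corrects, resamples to 50 Hz, band-pass filters both
#' chromophores separately (as a stream), computes the oxygen-exchange
#' index, and emits 5-s (`fs * 5`-sample) buffers every `stride_s` seconds
#' once the buffer is full. Each slice retains the filter warm-up so its
#' newest 4 s are valid for feature extraction.
#'
#' @param episode a `hemo_episode`.
#' @param params a [filter_params()].
#' @param stride_s emission cadence in seconds.
#' @param buffer_s buffer length in seconds (5 s = 250 samples at 50 Hz).
#' @return List of `hemo_slice` objects: fields `hbo`, `hbr`, `coe`
#'   (channel x `fs*buffer_s` matrices), `t_end` (time of newest sample) and
#'   `label` (button state at the newest sample).
#' @export
slice_stream <- function(episode, params = filter_params(), stride_s = 0.2,
                         buffer_s = 5) {
  stopifnot(inherits(episode, "hemo_episode"))
  fs <- params$fs
  ep <- baseline_correct(episode, episode$baseline_s %||% 20)
  ro <- resample_50hz(ep$timestamps, ep$hbo, fs)
  rr <- resample_50hz(ep$timestamps, ep$hbr, fs)
  hbo_f <- macd_bandpass(ro$values, params)
  hbr_f <- macd_bandpass(rr$values, params)
  coe <- compute_coe(hbr_f, hbo_f)
  ## nearest-sample button state on the uniform grid
  btn <- stats::approx(ep$timestamps, as.numeric(ep$button), xout = ro$time,
                       method = "constant", rule = 2)$y > 0.5

  win <- round(buffer_s * fs)
  stride <- max(1L, round(stride_s * fs))
  n <- length(ro$time)
  if (n < win) return(list())
  ends <- seq(win, n, by = stride)
  lapply(ends, function(e) {
    idx <- (e - win + 1L):e
    structure(list(hbo = hbo_f[, idx, drop = FALSE],
                   hbr = hbr_f[, idx, drop = FALSE],
                   coe = coe[, idx, drop = FALSE],
                   t_end = ro$time[e], label = btn[e]),
              class = "hemo_slice")
  })
}

#' Analytic magnitude response of the filter cascade
#'
#' Closed-form frequency response of the DEMA-difference band-pass, with the
#' SMA smoother optionally included. An EMA with constant `lambda` has
#' transfer function `lambda / (1 - (1-lambda) z^-1)`; DEMA is `2 H - H^2`;
#' the SMA is `(1 - z^-L) / (L (1 - z^-1))`.
#'
#' @param freq frequencies (Hz) at which to evaluate.
#' @param params a [filter_params()].
#' @param include_sma include the SMA smoother in the response? The SMA's
#'   long window dominates the upper edge, so the band-pass
#'   characterisation conventionally refers to the DEMA-difference stage
#'   (the default here); set `TRUE` to audit the full chain.
#' @return Numeric vector of gains `|H(f)|`.
#' @export
freq_response <- function(freq, params = filter_params(), include_sma = FALSE) {
  z_inv <- exp(-1i * 2 * pi * freq / params$fs)
  ema <- function(l) l / (1 - (1 - l) * z_inv)
  dema <- function(l) { h <- ema(l); 2 * h - h^2 }
  H <- dema(params$lambda1) - dema(params$lambda2)
  if (include_sma) {
    L <- params$sma_len
    sma <- ifelse(abs(1 - z_inv) < 1e-15, 1, (1 - z_inv^L) / (L * (1 - z_inv)))
    H <- H * sma
  }
  abs(H)
}

#' Locate the -3 dB passband edges of the filter
#'
#' Finds the passband maximum of [freq_response()] and the two frequencies
#' where the gain falls to `1/sqrt(2)` of it, by grid bracketing plus root
#' refinement.
#'
#' @inheritParams freq_response
#' @return Named vector `c(lower = ..., upper = ...)` in Hz.
#' @export
band_edges <- function(params = filter_params(), include_sma = FALSE) {
  g <- function(f) freq_response(f, params, include_sma)
  grid <- 10^seq(log10(1e-4), log10(params$fs / 2), length.out = 20000)
  gv <- g(grid)
  ipk <- which.max(gv)
  pk <- optimize(g, interval = grid[c(max(1, ipk - 1), min(length(grid), ipk + 1))],
                 maximum = TRUE)
  thr <- pk$objective / sqrt(2)
  above <- which(gv >= thr)
  lo_i <- min(above); hi_i <- max(above)
  lower <- if (lo_i == 1) grid[1] else
    uniroot(function(f) g(f) - thr, c(grid[lo_i - 1], grid[lo_i]),
            tol = 1e-10)$root
  upper <- if (hi_i == length(grid)) grid[hi_i] else
    uniroot(function(f) g(f) - thr, c(grid[hi_i], grid[hi_i + 1]),
            tol = 1e-10)$root
  c(lower = lower, upper = upper)
}

#' Export the frequency response as a table
#'
#' Audit table of frequency vs gain for the configured cascade.
#'
#' @inheritParams freq_response
#' @param n number of logarithmically spaced frequencies.
#' @param path optional CSV output path.
#' @return `data.frame(freq_hz, gain)`, invisibly written to `path` if given.
#' @export
freq_response_table <- function(params = filter_params(), include_sma = TRUE,
                                n = 1000, path = NULL) {
  f <- 10^seq(log10(1e-3), log10(params$fs / 2), length.out = n)
  df <- data.frame(freq_hz = f, gain = freq_response(f, params, include_sma))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
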