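#' Physiological noise profile for synthetic fNIRS episodes
#'
#' Describes the additive interference mixed into generated concentration
#' signals: sinusoidal cardiac, respiratory and Mayer-wave components, a
#' linear drift and white sensor noise, with a per-channel gain vector.
#' Defaults are chosen to exercise a 0.01--0.90 Hz band-pass: the cardiac
#' component sits above the passband, the Mayer wave inside it, and the
#' drift below it.
#'
#' @param cardiac_hz,cardiac_amp cardiac oscillation frequency (Hz) and
#'   amplitude (uM).
#' @param resp_hz,resp_amp respiratory component frequency and amplitude.
#' @param mayer_hz,mayer_amp Mayer-wave component frequency and amplitude.
#' @param drift_slope linear drift in uM per second.
#' @param white_sd standard deviation of white sensor noise (uM).
#' @param channel_gain per-channel multiplicative gain applied to all noise
#'   components (length recycled to the channel count at generation time).
#' @return An object of class `noise_profile`.
#' @export
noise_profile <- function(cardiac_hz = 1.1, cardiac_amp = 0.05,
                          resp_hz = 0.25, resp_amp = 0.03,
                          mayer_hz = 0.1, mayer_amp = 0.04,
                          drift_slope = 0.002, white_sd = 0.02,
                          channel_gain = 1) {
  amps <- c(cardiac_amp, resp_amp, mayer_amp, white_sd)
  if (any(amps < 0)) stop("noise amplitudes must be >= 0")
  freqs <- c(cardiac_hz, resp_hz, mayer_hz)
  if (any(freqs <= 0)) stop("noise frequencies must be positive")
  structure(list(cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp,
                 resp_hz = resp_hz, resp_amp = resp_amp,
                 mayer_hz = mayer_hz, mayer_amp = mayer_amp,
                 drift_slope = drift_slope, white_sd = white_sd,
                 channel_gain = channel_gain),
            class = "noise_profile")
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF (peak near 5--6 s, undershoot near 15--16 s)
#' used to model the seconds-scale blood-oxygen response to a risk event.
#'
#' @param t time in seconds (vector); values `< 0` give 0.
#' @param peak1,peak2 shape parameters of the response and undershoot gamma
#'   densities (rate fixed at 1/s).
#' @param undershoot_ratio relative amplitude of the undershoot.
#' @return HRF values, peak-normalised to 1.
#' @export
hrf_double_gamma <- function(t, peak1 = 6, peak2 = 16, undershoot_ratio = 1 / 6) {
  h <- ifelse(t < 0, 0,
              stats::dgamma(t, shape = peak1, rate = 1) -
                undershoot_ratio * stats::dgamma(t, shape = peak2, rate = 1))
  h / max(stats::dgamma(seq(0, 30, by = 0.01), shape = peak1, rate = 1))
}

validate_intervals <- function(risk_intervals, duration_s) {
  if (length(risk_intervals) == 0L) return(invisible(NULL))
  m <- do.call(rbind, lapply(risk_intervals, function(iv) {
    if (length(iv) != 2L || iv[2] <= iv[1])
      stop("each risk interval must be (onset, offset) with offset > onset")
    iv
  }))
  if (any(m < 0) || any(m > duration_s))
    stop("risk intervals must lie within [0, duration_s]")
  o <- order(m[, 1])
  m <- m[o, , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1, 1] < m[-nrow(m), 2]))
    stop("risk intervals must not overlap")
  invisible(NULL)
}

in_intervals <- function(t, intervals, shift = 0) {
  out <- rep(FALSE, length(t))
  for (iv in intervals)
    out <- out | (t >= iv[1] + shift & t < iv[2] + shift)
  out
}

#' Generate one synthetic fNIRS episode
#'
#' Produces per-channel oxy- (dHbO) and deoxy-hemoglobin (dHbR)
#' concentration-change series containing a risk-evoked hemodynamic
#' response plus structured physiological noise, together with a
#' reaction-delayed subjective-risk button trace. The dHbO response is the
#' risk boxcar convolved with a double-gamma HRF; dHbR is a negatively
#' scaled (-1/3) copy lagged by 1 s, following standard fNIRS modelling
#' practice. Sample timestamps are jittered around the nominal rate so the
#' resampling stage is genuinely exercised.
#'
#' @param duration_s episode length in seconds; must exceed `baseline_s`.
#' @param risk_intervals list of `c(onset_s, offset_s)` pairs; must be
#'   non-overlapping and inside `[0, duration_s]`.
#' @param noise a [noise_profile()].
#' @param hrf_amplitude peak dHbO response amplitude in uM.
#' @param reaction_delay_s latency between risk onset and the button press.
#' @param fs_nominal nominal sampling rate (Hz).
#' @param n_channels number of channels (8 for the 2x4 optode montage).
#' @param baseline_s initial resting-state span (no stimulus expected).
#' @param jitter relative timestamp jitter; 0 yields an exactly uniform grid.
#' @param seed integer seed; identical seeds give identical episodes.
#' @return An object of class `hemo_episode` with fields `timestamps`,
#'   `hbo`, `hbr` (channel x sample matrices, uM), `fs_nominal`,
#'   `risk_intervals`, `button`, `n_channels`.
#' @export
generate_episode <- function(duration_s = 40, risk_intervals = list(),
                             noise = noise_profile(), hrf_amplitude = 0.3,
                             reaction_delay_s = 0.8, fs_nominal = 50,
                             n_channels = 8, baseline_s = 20,
                             jitter = 0.1, seed = 1) {
  if (duration_s <= baseline_s)
    stop("duration_s must exceed the baseline length (", baseline_s, " s)")
  validate_intervals(risk_intervals, duration_s)
  set.seed(as.integer(seed))

  n <- round(duration_s * fs_nominal)
  dt <- (1 / fs_nominal) * if (jitter > 0) runif(n, 1 - jitter, 1 + jitter) else rep(1, n)
  ts <- cumsum(dt)
  ts <- ts - ts[1]

  ## HRF component on a uniform internal grid, then read off at sample times
  grid <- seq(0, duration_s, by = 1 / fs_nominal)
  box <- as.numeric(in_intervals(grid, risk_intervals))
  kern <- hrf_double_gamma(seq(0, 30, by = 1 / fs_nominal))
  resp <- if (any(box > 0)) {
    full <- convolve(box, rev(kern), type = "open")[seq_along(grid)] / fs_nominal
    full
  } else rep(0, length(grid))
  hrf_at <- function(tt, lag = 0) {
    approx_vals <- stats::approx(grid, resp, xout = pmax(tt - lag, 0),
                                 rule = 2)$y
    approx_vals
  }

  gain <- rep_len(noise$channel_gain, n_channels)
  hrf_gain <- runif(n_channels, 0.6, 1)  # spatial variation across channels
  hbo <- matrix(0, n_channels, n)
  hbr <- matrix(0, n_channels, n)
  hbo_resp <- hrf_amplitude * hrf_at(ts)
  hbr_resp <- -(hrf_amplitude / 3) * hrf_at(ts, lag = 1)
  for (ch in seq_len(n_channels)) {
    ph <- runif(3, 0, 2 * pi)
    osc <- noise$cardiac_amp * sin(2 * pi * noise$cardiac_hz * ts + ph[1]) +
      noise$resp_amp * sin(2 * pi * noise$resp_hz * ts + ph[2]) +
      noise$mayer_amp * sin(2 * pi * noise$mayer_hz * ts + ph[3])
    drift <- noise$drift_slope * ts
    hbo[ch, ] <- hrf_gain[ch] * hbo_resp +
      gain[ch] * (osc + drift + rnorm(n, 0, noise$white_sd))
    hbr[ch, ] <- hrf_gain[ch] * hbr_resp +
      0.3 * gain[ch] * (-osc - drift + rnorm(n, 0, noise$white_sd))
  }

  button <- in_intervals(ts, risk_intervals, shift = reaction_delay_s)
  structure(list(timestamps = ts, hbo = hbo, hbr = hbr,
                 fs_nominal = fs_nominal, risk_intervals = risk_intervals,
                 button = button, n_channels = n_channels,
                 baseline_s = baseline_s,
                 params = list(hrf_amplitude = hrf_amplitude,
                               reaction_delay_s = reaction_delay_s,
                               noise = noise, seed = seed)),
            class = "hemo_episode")
}

#' @export
print.hemo_episode <- function(x, ...) {
  cat("<hemo_episode> ", x$n_channels, " channels, ",
      length(x$timestamps), " samples (~",
      round(max(x$timestamps), 1), " s at ", x$fs_nominal, " Hz nominal), ",
      length(x$risk_intervals), " risk interval(s)\n", sep = "")
  invisible(x)
}

#' Scenario timing profile for episode generation
#'
#' Encodes the task-1 recording structure: a resting baseline, 10 s of
#' stable driving, then a single randomised risk event. Risk onset is drawn
#' uniformly inside `onset_jitter_s` after the stable phase and its duration
#' uniformly from `risk_duration_s`.
#'
#' @param scenario scenario id (1 = emergency braking, 2 = cut-in,
#'   3 = pedestrian crossing); affects only metadata here, the hemodynamic
#'   generator is shared.
#' @param duration_s,baseline_s,stable_s episode, baseline and stable-phase
#'   lengths in seconds.
#' @param onset_jitter_s range (s, relative to end of the stable phase) for
#'   the risk onset draw.
#' @param risk_duration_s range of risk-event durations (s).
#' @param noise a [noise_profile()].
#' @param hrf_amplitude passed to [generate_episode()].
#' @return An object of class `scenario_profile`.
#' @export
scenario_profile <- function(scenario = 1, duration_s = 40, baseline_s = 20,
                             stable_s = 10, onset_jitter_s = c(0, 5),
                             risk_duration_s = c(3, 6),
                             noise = noise_profile(), hrf_amplitude = 0.3) {
  stopifnot(scenario %in% 1:3)
  structure(list(scenario = scenario, duration_s = duration_s,
                 baseline_s = baseline_s, stable_s = stable_s,
                 onset_jitter_s = onset_jitter_s,
                 risk_duration_s = risk_duration_s,
                 noise = noise, hrf_amplitude = hrf_amplitude),
            class = "scenario_profile")
}

#' Generate a set of synthetic fNIRS episodes
#'
#' Draws `n_episodes` episodes from a [scenario_profile()], each with one
#' risk interval starting after the baseline plus 10 s of stable driving.
#' Per-episode seeds are derived deterministically from the master seed.
#'
#' @param n_episodes number of episodes (>= 1).
#' @param profile a [scenario_profile()].
#' @param seed master seed.
#' @return List of `hemo_episode` objects with attribute `risk_fraction`,
#'   the overall fraction of button-true samples.
#' @export
generate_dataset <- function(n_episodes = 30, profile = scenario_profile(),
                             seed = 1) {
  if (n_episodes < 1) stop("n_episodes must be >= 1")
  stopifnot(inherits(profile, "scenario_profile"))
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_episodes)
  onsets <- profile$baseline_s + profile$stable_s +
    runif(n_episodes, profile$onset_jitter_s[1], profile$onset_jitter_s[2])
  durs <- runif(n_episodes, profile$risk_duration_s[1], profile$risk_duration_s[2])
  eps <- lapply(seq_len(n_episodes), function(i) {
    generate_episode(duration_s = profile$duration_s,
                     risk_intervals = list(c(onsets[i],
                                             min(onsets[i] + durs[i],
                                                 profile$duration_s))),
                     noise = profile$noise,
                     hrf_amplitude = profile$hrf_amplitude,
                     baseline_s = profile$baseline_s,
                     seed = sub_seeds[i])
  })
  frac <- mean(unlist(lapply(eps, function(e) e$button)))
  attr(eps, "risk_fraction") <- frac
  eps
}

#' Write an episode to a delimited text file
#'
#' One row per sample: `time`, `hbo_1..C`, `hbr_1..C`, `button`. A JSON
#' manifest with the generation parameters is written alongside when
#' `manifest = TRUE`.
#'
#' @param episode a `hemo_episode`.
#' @param path output file path (tab-separated).
#' @param manifest write `<path>.json` with seeds/parameters?
#' @return `path`, invisibly.
#' @export
write_episode <- function(episode, path, manifest = TRUE) {
  stopifnot(inherits(episode, "hemo_episode"))
  df <- data.frame(time = episode$timestamps,
                   t(episode$hbo), t(episode$hbr),
                   button = as.integer(episode$button))
  names(df) <- c("time", paste0("hbo_", seq_len(episode$n_channels)),
                 paste0("hbr_", seq_len(episode$n_channels)), "button")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (manifest) {
    meta <- list(n_channels = episode$n_channels,
                 fs_nominal = episode$fs_nominal,
                 risk_intervals = episode$risk_intervals,
                 baseline_s = episode$baseline_s,
                 seed = episode$params$seed,
                 hrf_amplitude = episode$params$hrf_amplitude,
                 reaction_delay_s = episode$params$reaction_delay_s)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read an episode written by [write_episode()]
#'
#' @param path file written by [write_episode()].
#' @return A `hemo_episode` (generation parameters restored from the
#'   manifest when present).
#' @export
read_episode <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  hbo_cols <- grep("^hbo_", names(df))
  hbr_cols <- grep("^hbr_", names(df))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  ivs <- lapply(meta$risk_intervals, function(iv) unlist(iv))
  structure(list(timestamps = df$time,
                 hbo = t(as.matrix(df[, hbo_cols])),
                 hbr = t(as.matrix(df[, hbr_cols])),
                 fs_nominal = meta$fs_nominal %||% 50,
                 risk_intervals = ivs,
                 button = df$button > 0,
                 n_channels = length(hbo_cols),
                 baseline_s = meta$baseline_s %||% 20,
                 params = meta),
            class = "hemo_episode")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
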