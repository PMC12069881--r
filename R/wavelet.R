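## Daubechies-4 (8-tap) analysis filters. The scaling (low-pass) filter g
## and wavelet (high-pass) filter h form an orthogonal quadrature-mirror
## pair; synthesis filters are their time reverses.
db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
db4_dec_hi <- c(-0.2303778133088965, 0.7148465705529157,
                -0.6308807679298589, -0.027983769416859854,
                0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)

## one analysis step with half-point symmetric extension; returns
## floor((n + L - 1)/2) coefficients (pyramid bookkeeping as in standard
## DWT implementations)
dwt_step_sym <- function(x, filt) {
  L <- length(filt)
  n <- length(x)
  ext <- c(x[(L - 1):1], x, x[n:(n - L + 2)])
  full <- convolve(ext, rev(filt), type = "open")
  full[seq(L + 1, by = 2, length.out = (n + L - 1) %/% 2)]
}

## one synthesis step: upsample, convolve with reversed filters, trim
idwt_step_sym <- function(ca, cd, filt_lo, filt_hi, n_out) {
  L <- length(filt_lo)
  up <- function(c) { u <- numeric(2 * length(c)); u[seq(1, 2 * length(c), by = 2)] <- c; u }
  rec <- convolve(up(ca), rev(rev(filt_lo)), type = "open") +
    convolve(up(cd), rev(rev(filt_hi)), type = "open")
  ## synthesis filters are the time-reversed analysis filters, so the two
  ## rev() calls cancel: convolve(x, rev(b)) computes sum x[j] b[k-j]
  rec[(L - 1):(L - 2 + n_out)]
}

## circular (periodised) analysis step for even n: orthogonal, so energy
## is conserved exactly
dwt_step_per <- function(x, filt) {
  n <- length(x)
  if (n %% 2 != 0) stop("periodic mode requires even length at every level")
  L <- length(filt)
  vapply(seq_len(n / 2) - 1L, function(i) {
    sum(filt * x[((2 * i - seq_len(L) + 1L + 4L) %% n) + 1L])
  }, numeric(1))
}

idwt_step_per <- function(ca, cd, filt_lo, filt_hi) {
  n <- 2L * length(ca)
  L <- length(filt_lo)
  x <- numeric(n)
  for (i in seq_along(ca) - 1L) {
    idx <- ((2 * i - seq_len(L) + 1L + 4L) %% n) + 1L
    x[idx] <- x[idx] + ca[i + 1] * filt_lo + cd[i + 1] * filt_hi
  }
  x
}

#' Multilevel Daubechies-4 wavelet decomposition
#'
#' Recursively convolves the signal with the DB4 scaling and wavelet
#' filters and downsamples by 2, producing one detail-coefficient set per
#' level plus the final approximation set (5 sets for 4 levels). Boundary
#' handling is half-point symmetric extension by default; `"periodic"`
#' (circular) extension gives an exactly orthogonal transform for lengths
#' divisible by `2^levels`.
#'
#' @param x numeric signal (for the pipeline: 200 samples = 4 s at 50 Hz).
#' @param levels decomposition depth.
#' @param mode boundary extension mode.
#' @return An object of class `wavelet_coeffs`: `approx` (level-`levels`
#'   approximation), `details` (list, coarsest level first: d4, d3, d2, d1
#'   for 4 levels), `lengths` (per-level input lengths, needed for exact
#'   reconstruction), `mode`, `levels`.
#' @export
db4_decompose <- function(x, levels = 4, mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  L <- length(db4_dec_lo)
  if (length(x) < 2^levels)
    stop("signal too short for ", levels, "-level decomposition")
  a <- as.numeric(x)
  details <- vector("list", levels)
  lens <- integer(levels)
  for (lev in seq_len(levels)) {
    if (mode == "symmetric" && length(a) < L)
      stop("signal shorter than the filter support at level ", lev)
    lens[lev] <- length(a)
    if (mode == "symmetric") {
      details[[lev]] <- dwt_step_sym(a, db4_dec_hi)
      a <- dwt_step_sym(a, db4_dec_lo)
    } else {
      details[[lev]] <- dwt_step_per(a, db4_dec_hi)
      a <- dwt_step_per(a, db4_dec_lo)
    }
  }
  structure(list(approx = a, details = rev(details), lengths = lens,
                 mode = mode, levels = levels),
            class = "wavelet_coeffs")
}

#' Inverse DB4 wavelet transform
#'
#' Reconstructs the signal from a [db4_decompose()] result. For an
#' orthogonal wavelet this is exact to floating-point rounding.
#'
#' @param wc a `wavelet_coeffs` object.
#' @return The reconstructed signal.
#' @export
db4_reconstruct <- function(wc) {
  stopifnot(inherits(wc, "wavelet_coeffs"))
  a <- wc$approx
  for (lev in seq(wc$levels, 1)) {
    d <- wc$details[[wc$levels - lev + 1L]]
    if (wc$mode == "symmetric") {
      a <- idwt_step_sym(a, d, db4_dec_lo, db4_dec_hi, wc$lengths[lev])
    } else {
      a <- idwt_step_per(a, d, db4_dec_lo, db4_dec_hi)
    }
  }
  a
}

#' All five coefficient sets in fixed order
#'
#' Order: approximation (a4), then details coarsest to finest (d4, d3, d2,
#' d1). This order is the one the feature registry uses.
#'
#' @param wc a `wavelet_coeffs` object.
#' @return Named list of numeric vectors.
#' @export
coeff_sets <- function(wc) {
  stopifnot(inherits(wc, "wavelet_coeffs"))
  sets <- c(list(wc$approx), wc$details)
  names(sets) <- c(paste0("a", wc$levels),
                   paste0("d", seq(wc$levels, 1)))
  sets
}
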