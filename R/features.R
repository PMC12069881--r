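feature_stat_names <- c("entropy", "p05", "p25", "p75", "p95", "median",
                        "mean", "sd", "var", "rms", "zero_cross", "mean_cross")

#' Twelve summary features of one wavelet coefficient set
#'
#' Returns, in fixed order: Shannon entropy of the energy distribution;
#' the 5, 25, 75 and 95 percentiles and the median; mean; standard
#' deviation and variance; root mean square; and the zero-crossing and
#' mean-crossing counts.
#'
#' The entropy uses the normalised squared coefficients
#' \eqn{p_i = c_i^2 / \sum_j c_j^2} as the probability distribution
#' (natural log; zero coefficients contribute nothing, an all-zero set has
#' entropy 0). Crossing counts are the number of adjacent sign changes
#' around 0 and around the mean respectively.
#'
#' @param coeffs non-empty numeric vector.
#' @return Named numeric vector of length 12 (names in
#'   `entropy, p05, p25, p75, p95, median, mean, sd, var, rms, zero_cross,
#'   mean_cross` order).
#' @export
featurize_set <- function(coeffs) {
  if (length(coeffs) == 0) stop("empty coefficient array")
  e <- coeffs^2
  tot <- sum(e)
  ent <- if (tot > 0) {
    p <- e[e > 0] / tot
    -sum(p * log(p))
  } else 0
  q <- quantile(coeffs, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
  n <- length(coeffs)
  sdev <- if (n > 1) sd(coeffs) else 0
  cross <- function(v) sum(diff(sign(v)[sign(v) != 0]) != 0)
  out <- c(ent, q[1], q[2], q[3], q[4], median(coeffs), mean(coeffs),
           sdev, sdev^2, sqrt(mean(e)),
           cross(coeffs), cross(coeffs - mean(coeffs)))
  names(out) <- feature_stat_names
  out
}

#' Raw 60-feature vector for one channel window
#'
#' Decomposes a 4-s (200-sample) window with [db4_decompose()] and computes
#' the 12 features of [featurize_set()] for each of the 5 coefficient sets
#' (a4, d4, d3, d2, d1), giving 60 named features.
#'
#' @param x numeric window (one channel).
#' @param levels wavelet depth.
#' @param mode boundary mode (recorded in the names via the registry,
#'   since coefficient lengths depend on it).
#' @return Named numeric vector of length `12 * (levels + 1)`.
#' @export
featurize_channel <- function(x, levels = 4, mode = "symmetric") {
  sets <- coeff_sets(db4_decompose(x, levels, mode))
  out <- unlist(lapply(names(sets), function(nm) {
    f <- featurize_set(sets[[nm]])
    names(f) <- paste(nm, names(f), sep = "_")
    f
  }))
  out
}

#' Raw feature matrix row for a multichannel window
#'
#' Applies [featurize_channel()] to the latest `window` samples of every
#' channel of an oxygen-exchange-index slice (the newest 4 s = 200 of the
#' 250 buffered samples, which excludes the filter warm-up).
#'
#' @param coe channel x sample matrix (an element of a [slice_stream()]
#'   slice).
#' @param window number of newest samples to featurise.
#' @param levels,mode passed to [featurize_channel()].
#' @return Named numeric vector of length `n_channels * 60` with names
#'   `ch<c>_<set>_<stat>`.
#' @export
featurize_window <- function(coe, window = 200, levels = 4,
                             mode = "symmetric") {
  stopifnot(is.matrix(coe), ncol(coe) >= window)
  idx <- (ncol(coe) - window + 1L):ncol(coe)
  out <- unlist(lapply(seq_len(nrow(coe)), function(ch) {
    f <- featurize_channel(coe[ch, idx], levels, mode)
    names(f) <- paste0(sprintf("ch%02d", ch), "_", names(f))
    f
  }))
  out
}

#' Information gain of a feature for binary labels
#'
#' Mutual information `I(X;Y) = H(Y) - H(Y|X)` in bits, with the continuous
#' feature discretised into quantile bins (default) or split at the single
#' best threshold. Always >= 0 up to floating-point rounding; 0 when the
#' feature is independent of the labels or the labels are single-class.
#'
#' @param x numeric feature column (finite values).
#' @param y binary labels (logical or two-level).
#' @param bins number of quantile bins.
#' @param method `"quantile"` bins or `"threshold"` (best single split).
#' @return Information gain in bits.
#' @export
information_gain <- function(x, y, bins = 10, method = c("quantile", "threshold")) {
  method <- match.arg(method)
  if (!all(is.finite(x))) stop("feature values must be finite")
  y <- as.integer(as.factor(y))
  if (length(unique(y)) < 2L) return(0)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hy <- H(table(y) / length(y))
  if (method == "quantile") {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 2L) return(0)  # constant feature
    g <- cut(x, breaks = br, include.lowest = TRUE)
  } else {
    cand <- sort(unique(x))
    if (length(cand) < 2L) return(0)
    thr <- (head(cand, -1) + tail(cand, -1)) / 2
    best <- vapply(thr, function(tt) {
      g <- x <= tt
      cond_entropy(g, y, H)
    }, numeric(1))
    return(max(0, hy - min(best)))
  }
  max(0, hy - cond_entropy(g, y, H))
}

cond_entropy <- function(g, y, H) {
  tab <- table(g, y)
  pg <- rowSums(tab) / length(y)
  sum(vapply(seq_along(pg), function(i) {
    if (pg[i] == 0) return(0)
    pg[i] * H(tab[i, ] / sum(tab[i, ]))
  }, numeric(1)))
}

#' Fit a per-channel information-gain feature selector
#'
#' For each channel, scores its 60 raw features by [information_gain()]
#' against the window labels and keeps the top `n_per_channel` (default 4),
#' giving `4 x 8 = 32` selected features for an 8-channel montage. Ties are
#' broken deterministically in favour of the lowest feature index. Fitting
#' is done independently per subject and per scenario.
#'
#' @param features window x feature matrix from [featurize_window()] rows
#'   (column names `ch<c>_<set>_<stat>`).
#' @param labels binary window labels.
#' @param n_per_channel features kept per channel.
#' @param bins,method passed to [information_gain()].
#' @return An object of class `ig_selector`: per-channel selected column
#'   names, all scores, and a `flags` field naming channels whose scores
#'   were all (near) zero (degenerate channels, selected by tie-break).
#' @export
fit_selector <- function(features, labels, n_per_channel = 4, bins = 10,
                         method = "quantile") {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  cn <- colnames(features)
  chans <- unique(sub("_.*", "", cn))
  scores <- vapply(seq_len(ncol(features)),
                   function(j) information_gain(features[, j], labels, bins, method),
                   numeric(1))
  names(scores) <- cn
  flags <- character(0)
  sel <- lapply(chans, function(ch) {
    j <- which(startsWith(cn, paste0(ch, "_")))
    if (length(j) < n_per_channel)
      stop("fewer than ", n_per_channel, " candidate features for ", ch)
    s <- scores[j]
    ## stable order: descending score, lowest index wins ties
    o <- order(-s, seq_along(s))
    if (max(s) <= 1e-12) flags <<- c(flags, ch)
    cn[j[o[seq_len(n_per_channel)]]]
  })
  names(sel) <- chans
  structure(list(selected = sel, scores = scores, flags = flags,
                 n_per_channel = n_per_channel, bins = bins, method = method),
            class = "ig_selector")
}

#' @export
print.ig_selector <- function(x, ...) {
  cat("<ig_selector> ", length(x$selected), " channels x ",
      x$n_per_channel, " features (", x$method, " discretisation)\n", sep = "")
  if (length(x$flags))
    cat("  degenerate channels (all-zero scores):",
        paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a fitted selector
#'
#' @param selector an `ig_selector`.
#' @param features window x feature matrix with the same column registry
#'   the selector was fitted on.
#' @return Matrix with `n_channels * n_per_channel` columns (32 for the
#'   default montage), in channel order.
#' @export
apply_selector <- function(selector, features) {
  stopifnot(inherits(selector, "ig_selector"))
  cols <- unlist(selector$selected)
  missing <- setdiff(cols, colnames(features))
  if (length(missing))
    stop("feature registry mismatch: missing ", paste(missing, collapse = ", "))
  features[, cols, drop = FALSE]
}

#' Build a labelled training set from synthetic episodes
#'
#' Runs the preprocessing chain on each episode, featurises every emitted
#' slice and collects the raw 60-per-channel feature matrix with window
#' labels (button state at the newest sample). Slices whose newest sample
#' falls in the baseline span are kept (they are valid non-risk windows).
#'
#' @param episodes list of `hemo_episode` objects.
#' @param params a [filter_params()].
#' @param stride_s slice cadence in seconds.
#' @param window feature window length in samples.
#' @return List with `features` (matrix), `labels` (logical), `time`
#'   (slice end times) and `episode` (index).
#' @export
collect_windows <- function(episodes, params = filter_params(),
                            stride_s = 0.2, window = 200) {
  rows <- list(); labs <- logical(0); tms <- numeric(0); eps <- integer(0)
  for (i in seq_along(episodes)) {
    slices <- slice_stream(episodes[[i]], params, stride_s)
    for (s in slices) {
      rows[[length(rows) + 1L]] <- featurize_window(s$coe, window)
      labs <- c(labs, s$label)
      tms <- c(tms, s$t_end)
      eps <- c(eps, i)
    }
  }
  list(features = do.call(rbind, rows), labels = labs, time = tms,
       episode = eps)
}
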