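#' Driving risk field parameters
#'
#' Constants of the kinetic-energy driving risk field: field gain `G`,
#' road-condition factor `R2`, vehicle mass `M` (kg), distance-decay
#' exponent `k1` and speed-modulation gain `k2`.
#'
#' @param G,R2,M,k1,k2 positive constants; defaults are the conventional
#'   values for a mid-size passenger car.
#' @return An object of class `risk_field_params`.
#' @export
risk_field_params <- function(G = 0.001, R2 = 1, M = 1705, k1 = 1,
                              k2 = 0.05) {
  if (any(c(G, R2, M, k1, k2) <= 0)) stop("all parameters must be positive")
  structure(list(G = G, R2 = R2, M = M, k1 = k1, k2 = k2),
            class = "risk_field_params")
}

#' Driving risk field magnitude
#'
#' `|Ev| = G * R2 * M / |r|^k1 * exp(k2 * |v2| * cos(theta2))`, where `r`
#' is the relative position vector between the other vehicle and the ego
#' vehicle, `v2` the other vehicle's speed, and `theta2` the angle between
#' `r` and `v2`. Decays as a power law in distance and is amplified when
#' the other vehicle moves along `r` (towards the ego vehicle in the
#' default front-on-ego orientation). The field direction is along the
#' unit vector of `r`.
#'
#' @param r relative distance `|r|` in metres (> 0); vectorised.
#' @param v2 other vehicle's speed (m/s).
#' @param theta2 angle between `r` and `v2` (radians).
#' @param p a [risk_field_params()].
#' @return Field magnitude(s).
#' @export
risk_field <- function(r, v2 = 0, theta2 = 0, p = risk_field_params()) {
  if (any(r <= 0)) stop("relative distance must be positive")
  p$G * p$R2 * p$M / r^p$k1 * exp(p$k2 * abs(v2) * cos(theta2))
}

#' Time to collision
#'
#' `TTC = (gap - l) / (-gap_rate)` when the gap is closing
#' (`gap_rate < 0`); `Inf` when opening or constant (no collision course);
#' 0 at contact (`gap == l`, a collision).
#'
#' @param gap centre-to-centre (or raw) distance between the two agents
#'   (m); must be `>= vehicle_length`.
#' @param vehicle_length contact distance `l` (m).
#' @param gap_rate time derivative of the gap (m/s; negative = closing).
#' @return TTC in seconds (vectorised).
#' @export
ttc <- function(gap, vehicle_length, gap_rate) {
  if (any(gap < vehicle_length))
    stop("gap below vehicle length: agents already overlap")
  out <- ifelse(gap_rate < 0, (gap - vehicle_length) / (-gap_rate), Inf)
  ifelse(gap == vehicle_length, 0, out)
}

#' Per-episode jerk summary
#'
#' Differentiates an acceleration series (central differences, one-sided
#' at the endpoints) and averages the positive and negative jerk samples
#' separately; an empty side averages to 0.
#'
#' @param accel acceleration series (m/s^2), >= 2 samples.
#' @param dt sampling step (s).
#' @return Named vector `c(mean_pos, mean_neg)` in m/s^3
#'   (`mean_pos >= 0`, `mean_neg <= 0`).
#' @export
jerk_stats <- function(accel, dt) {
  if (dt <= 0) stop("dt must be positive")
  n <- length(accel)
  if (n < 2) stop("need at least 2 acceleration samples")
  j <- numeric(n)
  j[1] <- (accel[2] - accel[1]) / dt
  j[n] <- (accel[n] - accel[n - 1]) / dt
  if (n > 2) j[2:(n - 1)] <- (accel[3:n] - accel[1:(n - 2)]) / (2 * dt)
  c(mean_pos = if (any(j > 0)) mean(j[j > 0]) else 0,
    mean_neg = if (any(j < 0)) mean(j[j < 0]) else 0)
}

#' Friedman omnibus test with Nemenyi post hoc comparisons
#'
#' Compares classifier balanced accuracies across subjects (rows) and
#' models (columns): Friedman rank test for the omnibus difference, then
#' all-pairs Nemenyi comparisons using the studentised range distribution
#' on the mean-rank differences.
#'
#' @param ba_matrix subjects x models numeric matrix (>= 2 subjects,
#'   >= 3 models); column names label the models.
#' @return List with `friedman` (htest), `mean_ranks`, `nemenyi_p`
#'   (pairwise p-value matrix), `critical_difference` (at `alpha`), and
#'   `constant_rows` (flagged undefined-rank rows, excluded).
#' @param alpha level for the critical-difference threshold.
#' @export
compare_classifiers <- function(ba_matrix, alpha = 0.05) {
  m <- as.matrix(ba_matrix)
  if (ncol(m) < 3) stop("need at least 3 models")
  const <- apply(m, 1, function(r) diff(range(r)) == 0)
  if (all(const)) {
    ## no information to rank: statistic 0 by convention
    k <- ncol(m)
    p <- matrix(1, k, k, dimnames = list(colnames(m), colnames(m)))
    return(list(friedman = list(statistic = c(`Friedman chi-squared` = 0),
                                p.value = 1),
                mean_ranks = rep((k + 1) / 2, k), nemenyi_p = p,
                critical_difference = NA_real_,
                constant_rows = which(const)))
  }
  if (any(const)) m <- m[!const, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 subjects with non-constant rows")
  n <- nrow(m); k <- ncol(m)
  fr <- friedman.test(m)
  ranks <- t(apply(m, 1, function(r) rank(-r)))  # rank 1 = best
  mr <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  q <- abs(outer(mr, mr, "-")) / se
  p <- stats::ptukey(q * sqrt(2), k, Inf, lower.tail = FALSE)
  diag(p) <- 1
  cd <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2) * se
  dimnames(p) <- list(colnames(m), colnames(m))
  list(friedman = fr, mean_ranks = mr, nemenyi_p = p,
       critical_difference = cd, constant_rows = which(const))
}

#' Robust z-score outlier mask
#'
#' `z = (x - median) / (1.4826 * MAD)`; values with `|z| > threshold` are
#' outliers. A zero MAD (over half the values identical) disables removal.
#'
#' @param x numeric vector.
#' @param threshold robust z threshold.
#' @return Logical vector, `TRUE` = keep.
#' @export
robust_z_keep <- function(x, threshold = 3) {
  med <- median(x)
  madv <- 1.4826 * median(abs(x - med))
  if (madv == 0) return(rep(TRUE, length(x)))
  abs(x - med) / madv <= threshold
}

#' One-sided Wilcoxon comparison of an episode metric
#'
#' Removes robust z-score outliers (per group when independent; on the
#' pair differences when paired), then runs a one-sided Wilcoxon test of
#' group B against group A.
#'
#' @param group_a,group_b numeric metric values (equal length if paired).
#' @param side `"b_greater"` or `"b_less"`: the alternative for B relative
#'   to A.
#' @param paired paired (signed-rank) or independent (rank-sum) mode.
#' @param threshold robust z threshold for outlier removal.
#' @return List with `p_value`, `statistic`, `n_removed`, `n_used`.
#' @export
compare_episode_metric <- function(group_a, group_b,
                                   side = c("b_greater", "b_less"),
                                   paired = FALSE, threshold = 3) {
  side <- match.arg(side)
  alt <- if (side == "b_greater") "greater" else "less"
  if (paired) {
    stopifnot(length(group_a) == length(group_b))
    keep <- robust_z_keep(group_b - group_a, threshold)
    a <- group_a[keep]; b <- group_b[keep]
    removed <- sum(!keep)
  } else {
    ka <- robust_z_keep(group_a, threshold)
    kb <- robust_z_keep(group_b, threshold)
    a <- group_a[ka]; b <- group_b[kb]
    removed <- sum(!ka) + sum(!kb)
  }
  if (length(a) < 3 || length(b) < 3)
    stop("fewer than 3 observations survive outlier removal")
  wt <- suppressWarnings(wilcox.test(b, a, alternative = alt,
                                     paired = paired, exact = FALSE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_removed = removed, n_used = c(a = length(a), b = length(b)))
}

#' Windowed episode metric report
#'
#' Splits a protocol log into episode windows (by default the first,
#' middle and last 10 test or training episodes) and tabulates the safety
#' and comfort metrics per window.
#'
#' @param log episode log from [run_protocol()] (or any data frame with
#'   `episode`, `min_ttc`, `max_risk_field`, `mean_pos_jerk`,
#'   `mean_neg_jerk` columns).
#' @param windows named list of episode-index vectors (positions within
#'   `log`, after any filtering by the caller).
#' @return List with `table` (per-window medians and means) and `values`
#'   (per-window metric vectors, for plotting/tests).
#' @export
episode_report <- function(log,
                           windows = list(first10 = 1:10, middle10 = 11:20,
                                          last10 = 21:30)) {
  if (nrow(log) < max(unlist(windows)))
    stop("fewer episodes (", nrow(log), ") than the window specification")
  vals <- lapply(windows, function(w)
    list(min_ttc = log$min_ttc[w], max_risk_field = log$max_risk_field[w],
         mean_pos_jerk = log$mean_pos_jerk[w],
         mean_neg_jerk = log$mean_neg_jerk[w]))
  tab <- do.call(rbind, lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    data.frame(window = nm,
               median_min_ttc = median(v$min_ttc),
               mean_max_risk_field = mean(v$max_risk_field),
               mean_pos_jerk = mean(v$mean_pos_jerk),
               mean_neg_jerk = mean(v$mean_neg_jerk))
  }))
  list(table = tab, values = vals)
}
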