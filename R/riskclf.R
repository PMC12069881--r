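#' Specification of the six-member soft-voting ensemble
#'
#' Members: adaptively boosted decision tree (AB-DT), Gaussian naive Bayes
#' (AB-GNB), support vector machine (AB-SVM) and logistic regression
#' (AB-LR), plus a random forest (RF) and a multilayer perceptron (MLP).
#' All members expose class probabilities; the vote is their unweighted
#' mean.
#'
#' @param n_rounds boosting rounds for the AB members.
#' @param tree_depth depth of the boosted decision trees.
#' @param svm_cost,svm_gamma radial-kernel SVM hyperparameters
#'   (`svm_gamma = NULL` uses the kernel default 1/dim).
#' @param rf_trees random-forest size.
#' @param mlp_size,mlp_decay,mlp_maxit hidden units, weight decay and
#'   iteration cap of the MLP.
#' @return An object of class `ensemble_spec` (exactly 6 members).
#' @export
ensemble_spec <- function(n_rounds = 50, tree_depth = 2, svm_cost = 1,
                          svm_gamma = NULL, rf_trees = 300, mlp_size = 16,
                          mlp_decay = 1e-3, mlp_maxit = 200) {
  structure(list(members = c("ab_dt", "ab_gnb", "ab_svm", "ab_lr",
                             "rf", "mlp"),
                 n_rounds = n_rounds, tree_depth = tree_depth,
                 svm_cost = svm_cost, svm_gamma = svm_gamma,
                 rf_trees = rf_trees, mlp_size = mlp_size,
                 mlp_decay = mlp_decay, mlp_maxit = mlp_maxit),
            class = "ensemble_spec")
}

## ---- adaptive boosting (SAMME, two classes) over weighted base learners

fit_base <- function(kind, df, w, spec) {
  n <- nrow(df)
  switch(kind,
    dt = rpart::rpart(label ~ ., df, weights = w * n, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = spec$tree_depth, cp = 0, minsplit = 4,
                        xval = 0)),
    lr = suppressWarnings(glm(label ~ ., df, weights = w * n,
                              family = binomial())),
    gnb = {  # no native weights: weighted resample
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      e1071::naiveBayes(label ~ ., df[idx, , drop = FALSE])
    },
    svm = {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      d <- df[idx, , drop = FALSE]
      if (length(unique(d$label)) < 2L)
        d <- df  # degenerate resample: fall back to the full set
      e1071::svm(label ~ ., d, kernel = "radial", cost = spec$svm_cost,
                 gamma = spec$svm_gamma %||% (1 / (ncol(df) - 1)),
                 probability = TRUE)
    },
    stop("unknown base learner ", kind))
}

prob_base <- function(kind, fit, df) {
  p <- switch(kind,
    dt = predict(fit, df, type = "prob")[, "TRUE"],
    lr = suppressWarnings(predict(fit, df, type = "response")),
    gnb = predict(fit, df, type = "raw")[, "TRUE"],
    svm = attr(predict(fit, df, probability = TRUE),
               "probabilities")[, "TRUE"])
  unname(p)
}

fit_adaboost <- function(x, y, kind, spec) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$label <- factor(y, levels = c(FALSE, TRUE))
  n <- nrow(df)
  w <- rep(1 / n, n)
  fits <- list(); alphas <- numeric(0)
  for (m in seq_len(spec$n_rounds)) {
    fit <- fit_base(kind, df, w, spec)
    p <- prob_base(kind, fit, df)
    pred <- p >= 0.5
    err <- sum(w[pred != y])
    if (err <= 0) {          # perfect learner: keep with a large vote, stop
      fits[[length(fits) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) {
      if (length(fits) == 0L) {  # keep one member so probabilities exist
        fits[[1L]] <- fit
        alphas <- 1e-8
      }
      break
    }
    alpha <- log((1 - err) / err)
    fits[[length(fits) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  structure(list(kind = kind, fits = fits, alphas = alphas,
                 feat_names = setdiff(names(df), "label")),
            class = "adaboost")
}

predict_adaboost <- function(model, x) {
  df <- as.data.frame(x)
  names(df) <- model$feat_names
  probs <- vapply(model$fits, function(f) prob_base(model$kind, f, df),
                  numeric(nrow(df)))
  probs <- matrix(probs, nrow = nrow(df))
  as.numeric(probs %*% model$alphas / sum(model$alphas))
}

#' Train the six-member soft-voting risk detector
#'
#' Fits the ensemble of [ensemble_spec()] on selected feature vectors
#' (32-dimensional for the default montage) and binary risk labels. One
#' detector per subject per scenario.
#'
#' @param features window x feature matrix (selected features).
#' @param labels logical risk labels; both classes must be present.
#' @param spec an [ensemble_spec()].
#' @param seed integer seed (boosting resamples, RF, MLP initialisation).
#' @return An object of class `risk_detector`.
#' @export
train_detector <- function(features, labels, spec = ensemble_spec(),
                           seed = 1) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  set.seed(as.integer(seed))
  x <- features
  fn <- paste0("f", seq_len(ncol(x)))
  df <- as.data.frame(x); names(df) <- fn
  df$label <- factor(labels, levels = c(FALSE, TRUE))
  ## standardise for the scale-sensitive members (SVM, MLP)
  mu <- colMeans(x); sdv <- apply(x, 2, sd); sdv[sdv == 0] <- 1
  xs <- scale(x, mu, sdv)
  members <- list(
    ab_dt = fit_adaboost(x, labels, "dt", spec),
    ab_gnb = fit_adaboost(x, labels, "gnb", spec),
    ab_svm = fit_adaboost(xs, labels, "svm", spec),
    ab_lr = fit_adaboost(xs, labels, "lr", spec),
    rf = randomForest::randomForest(x, df$label, ntree = spec$rf_trees),
    mlp = nnet::nnet(xs, as.numeric(labels), size = spec$mlp_size,
                     decay = spec$mlp_decay, maxit = spec$mlp_maxit,
                     entropy = TRUE, trace = FALSE)
  )
  structure(list(members = members, spec = spec, seed = seed,
                 n_features = ncol(x), center = mu, scale = sdv,
                 feat_names = colnames(features)),
            class = "risk_detector")
}

member_probs <- function(model, features) {
  xs <- scale(features, model$center, model$scale)
  cbind(
    ab_dt = predict_adaboost(model$members$ab_dt, features),
    ab_gnb = predict_adaboost(model$members$ab_gnb, features),
    ab_svm = predict_adaboost(model$members$ab_svm, xs),
    ab_lr = predict_adaboost(model$members$ab_lr, xs),
    rf = predict(model$members$rf, features, type = "prob")[, "TRUE"],
    mlp = as.numeric(predict(model$members$mlp, xs))
  )
}

#' Soft-voting prediction
#'
#' The risky-class probability is the unweighted mean of the six members'
#' probabilities; the decision threshold is `p >= 0.5` (ties resolve to
#' risky).
#'
#' @param model a `risk_detector`.
#' @param features feature matrix (or single vector) with the dimension
#'   the model was trained on.
#' @return `data.frame(p_risky, is_risky)` with one row per window.
#' @export
predict_soft <- function(model, features) {
  stopifnot(inherits(model, "risk_detector"))
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != model$n_features)
    stop("feature dimension ", ncol(features), " does not match the ",
         "detector (", model$n_features, ")")
  pm <- member_probs(model, features)
  p <- rowMeans(pm)
  data.frame(p_risky = p, is_risky = p >= 0.5)
}

#' @export
print.risk_detector <- function(x, ...) {
  cat("<risk_detector> 6-member soft-voting ensemble on ",
      x$n_features, " features (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Confusion counts and balanced accuracy
#'
#' Balanced accuracy is the mean of sensitivity and specificity,
#' `BA = (TP/(TP+FN) + TN/(TN+FP)) / 2`, robust to class imbalance;
#' predicting a single class on any mix scores 0.5.
#'
#' @param truth,pred logical vectors (risky = `TRUE`).
#' @return `confusion_counts()`: named vector `TP, TN, FP, FN`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  c(TP = sum(truth & pred), TN = sum(!truth & !pred),
    FP = sum(!truth & pred), FN = sum(truth & !pred))
}

#' @rdname confusion_counts
#' @param counts named vector with `TP, TN, FP, FN` (alternative to
#'   `truth`/`pred`).
#' @export
balanced_accuracy <- function(truth = NULL, pred = NULL, counts = NULL) {
  if (is.null(counts)) counts <- confusion_counts(truth, pred)
  if (counts["TP"] + counts["FN"] == 0 || counts["TN"] + counts["FP"] == 0)
    stop("balanced accuracy undefined: a class is absent from the truth")
  unname((counts["TP"] / (counts["TP"] + counts["FN"]) +
            counts["TN"] / (counts["TN"] + counts["FP"])) / 2)
}

#' Stratified k-fold cross-validated balanced accuracy
#'
#' @param features,labels training data (selected features).
#' @param spec an [ensemble_spec()].
#' @param k folds.
#' @param seed integer seed (fold assignment and member training).
#' @return List with `ba` (mean over folds), `fold_ba`, and pooled
#'   out-of-fold `pred`/`p_risky`/`truth` for downstream tests.
#' @export
cross_val_ba <- function(features, labels, spec = ensemble_spec(), k = 5,
                         seed = 1) {
  labels <- as.logical(labels)
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in c(TRUE, FALSE)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  pred <- logical(length(labels)); p <- numeric(length(labels))
  fold_ba <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- train_detector(features[tr, , drop = FALSE], labels[tr], spec,
                        seed = seed + f)
    out <- predict_soft(m, features[!tr, , drop = FALSE])
    pred[!tr] <- out$is_risky; p[!tr] <- out$p_risky
    fold_ba[f] <- balanced_accuracy(labels[!tr], out$is_risky)
  }
  list(ba = mean(fold_ba), fold_ba = fold_ba, pred = pred, p_risky = p,
       truth = labels)
}

#' Permutation test for above-chance balanced accuracy
#'
#' Tests whether fixed predictions are associated with the labels by
#' permuting the labels: the null distribution is the BA of the predictions
#' against shuffled labels, and
#' `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param pred predicted labels (e.g. pooled out-of-fold predictions).
#' @param truth true labels.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List with `ba`, `p_value`, `null` (null BA draws).
#' @export
permutation_test_ba <- function(pred, truth, n_perm = 999, seed = 1) {
  set.seed(as.integer(seed))
  obs <- balanced_accuracy(truth, pred)
  null <- vapply(seq_len(n_perm), function(i)
    balanced_accuracy(sample(truth), pred), numeric(1))
  list(ba = obs, p_value = (1 + sum(null >= obs)) / (n_perm + 1),
       null = null)
}

#' Online risk detection over an fNIRS stream
#'
#' Runs the preprocessing chain over an episode, featurises each emitted
#' slice (newest 4 s), applies the fitted selector and detector, and
#' returns the risk gate `k_fnirs(t)` at the slice cadence.
#'
#' @param episode a `hemo_episode`.
#' @param model a `risk_detector`.
#' @param selector the `ig_selector` fitted with the model (same
#'   subject/scenario).
#' @param params a [filter_params()].
#' @param stride_s detection cadence in seconds.
#' @param window feature window length in samples.
#' @return `data.frame(time, p_risky, k_fnirs)`; one row per emission,
#'   none before the 5-s buffer warm-up.
#' @export
online_detect <- function(episode, model, selector,
                          params = filter_params(), stride_s = 0.2,
                          window = 200) {
  slices <- slice_stream(episode, params, stride_s)
  if (length(slices) == 0L)
    return(data.frame(time = numeric(0), p_risky = numeric(0),
                      k_fnirs = integer(0)))
  feats <- do.call(rbind, lapply(slices, function(s)
    featurize_window(s$coe, window)))
  sel <- apply_selector(selector, feats)
  out <- predict_soft(model, sel)
  data.frame(time = vapply(slices, function(s) s$t_end, numeric(1)),
             p_risky = out$p_risky,
             k_fnirs = as.integer(out$is_risky))
}
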