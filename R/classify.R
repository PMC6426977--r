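#' Fold protocol for classifier evaluation
#'
#' Each fold trains on a random half (by default) of the training set and
#' predicts the entire validation set; fold-to-fold variability comes only
#' from the training subsample. `within_session` validates on the complement
#' of the training half inside the same feature set; `cross_session` and
#' `cross_subject_pooled` validate on a feature set from (an)other
#' recording(s).
#'
#' @param n_folds number of random train/validate repetitions.
#' @param train_fraction fraction of the training set drawn each fold.
#' @param seed integer seed for the fold draws.
#' @param scheme validation scheme.
#' @return object of class `fold_protocol`.
#' @export
fold_protocol <- function(n_folds = 100, train_fraction = 0.5, seed = 1L,
                          scheme = c("within_session", "cross_session",
                                     "cross_subject_pooled")) {
  scheme <- match.arg(scheme)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)")
  if (n_folds < 1L) stop("n_folds must be >= 1")
  structure(list(n_folds = as.integer(n_folds),
                 train_fraction = train_fraction,
                 seed = as.integer(seed), scheme = scheme),
            class = "fold_protocol")
}

#' Train a linear SVM on standardized features
#'
#' Features are standardized per dimension (mean/sd fitted on the training
#' data only; near-constant dimensions get unit scale), then a linear-kernel
#' support vector machine is fitted. The decision function is reduced to an
#' explicit weight vector and bias, oriented so that positive scores mean
#' `"anesthetized"`.
#'
#' @param x a [feature_set()], or a numeric matrix of feature rows.
#' @param labels per-row labels when `x` is a matrix.
#' @param C soft-margin regularization parameter (default 1).
#' @param standardize standardize features before fitting (default `TRUE`).
#' @return object of class `linear_svm` with `w`, `b`, `center`, `scale`.
#' @export
train_svm <- function(x, labels = NULL, C = 1, standardize = TRUE) {
  if (inherits(x, "feature_set")) { labels <- x$labels; x <- x$vectors }
  x <- as.matrix(x)
  y <- factor(as.character(labels), levels = c("awake", "anesthetized"))
  if (nlevels(droplevels(y)) < 2L)
    stop("protocol error: training set contains a single class")
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  fit <- e1071::svm(xs, y, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  score <- drop(xs %*% w) + b
  # orient: positive score = anesthetized
  if (mean(score[y == "anesthetized"]) < mean(score[y == "awake"])) {
    w <- -w; b <- -b
  }
  structure(list(w = w, b = b, center = ctr, scale = scl, C = C,
                 n_train = nrow(x)),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> dim %d, C = %g, trained on %d vectors\n",
              length(x$w), x$C, x$n_train))
  invisible(x)
}

#' Predict from a linear SVM
#' @param object a [train_svm()] model.
#' @param newdata feature matrix or [feature_set()].
#' @param type `"class"` for labels, `"score"` for decision values
#'   (positive = anesthetized; the class boundary is score >= 0).
#' @return factor of labels or numeric scores.
#' @export
predict.linear_svm <- function(object, newdata,
                               type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_set")) newdata <- newdata$vectors
  xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
              object$scale, "/")
  score <- drop(xs %*% object$w) + object$b
  if (type == "score") return(score)
  factor(ifelse(score >= 0, "anesthetized", "awake"),
         levels = c("awake", "anesthetized"))
}

# ROC by threshold sweep over scores (positive at score >= threshold),
# positive class = "anesthetized"; returns closed curve from (0,0) to (1,1)
roc_points <- function(scores, truth) {
  pos <- truth == "anesthetized"
  P <- sum(pos); Nn <- sum(!pos)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- pos[o]
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tied block
  tpr <- cumsum(y)[keep] / P
  fpr <- cumsum(!y)[keep] / Nn
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Evaluate a classifier under a fold protocol
#'
#' Per fold, a random `train_fraction` of the training set trains a linear
#' SVM and the full validation set is predicted; the percent of wrong
#' classifications is recorded. The ROC curve is built by sweeping the
#' decision threshold over the validation scores pooled across folds, and
#' the AUC is the trapezoid-rule area under it.
#'
#' @param protocol a [fold_protocol()].
#' @param train_set a [feature_set()].
#' @param valid_set a [feature_set()] from a different recording/session for
#'   the cross schemes; must be omitted for `within_session`, where each
#'   fold validates on the complement of its training half.
#' @param C soft-margin parameter passed to [train_svm()].
#' @return object of class `eval_report`: `errors_pct` (per fold), `roc`,
#'   `auc`, `config`.
#' @export
evaluate <- function(protocol, train_set, valid_set = NULL, C = 1) {
  stopifnot(inherits(protocol, "fold_protocol"),
            inherits(train_set, "feature_set"))
  within <- protocol$scheme == "within_session"
  if (within && !is.null(valid_set))
    stop("protocol error: within_session validates on held-out training data;",
         " do not pass valid_set")
  if (!within && is.null(valid_set))
    stop("protocol error: scheme ", protocol$scheme,
         " requires a validation feature set")
  n <- nrow(train_set$vectors)
  n_tr <- max(2L, floor(protocol$train_fraction * n))
  set.seed(protocol$seed)
  errors <- numeric(protocol$n_folds)
  all_scores <- vector("list", protocol$n_folds)
  all_truth <- vector("list", protocol$n_folds)
  for (fold in seq_len(protocol$n_folds)) {
    for (try in 1:100) {
      idx <- sample.int(n, n_tr)
      if (nlevels(droplevels(train_set$labels[idx])) == 2L) break
      if (try == 100L)
        stop("protocol error: could not draw a two-class training half")
    }
    model <- train_svm(train_set$vectors[idx, , drop = FALSE],
                       train_set$labels[idx], C = C)
    if (within) {
      vx <- train_set$vectors[-idx, , drop = FALSE]
      vy <- train_set$labels[-idx]
    } else {
      vx <- valid_set$vectors
      vy <- valid_set$labels
    }
    score <- predict(model, vx, type = "score")
    pred <- ifelse(score >= 0, "anesthetized", "awake")
    errors[fold] <- 100 * mean(pred != as.character(vy))
    all_scores[[fold]] <- score
    all_truth[[fold]] <- as.character(vy)
  }
  roc <- roc_points(unlist(all_scores), unlist(all_truth))
  structure(list(errors_pct = errors, roc = roc, auc = trapezoid_auc(roc),
                 config = list(n_folds = protocol$n_folds,
                               train_fraction = protocol$train_fraction,
                               seed = protocol$seed,
                               scheme = protocol$scheme, C = C,
                               n_train_pool = n,
                               source = train_set$source,
                               surrogate = train_set$surrogate,
                               window_s = train_set$window_s)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s/%s, Delta=%g s, %d folds (%s)\n",
    x$config$source, x$config$surrogate, x$config$window_s,
    x$config$n_folds, x$config$scheme))
  cat(sprintf("  error %%: median %.2f (IQR %.2f-%.2f)   AUC %.4f\n",
              stats::median(x$errors_pct),
              stats::quantile(x$errors_pct, 0.25),
              stats::quantile(x$errors_pct, 0.75), x$auc))
  invisible(x)
}

#' @export
plot.eval_report <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "false-positive rate",
                 ylab = "true-positive rate",
                 main = sprintf("AUC = %.4f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Classification performance as a function of window length
#'
#' Runs the full featurize-train-evaluate pipeline for each window length
#' Delta and each feature source, and tabulates the median fold error and
#' AUC. Sources: `"ds"`, `"fft"`, and DS on surrogate data (`"ds+phase"`,
#' `"ds+stagger"`, `"ds+global"`); surrogates are applied to training and
#' validation data alike.
#'
#' @param train_rec,train_intervals training recording and its labels.
#' @param windows numeric vector of Delta values (seconds).
#' @param valid_rec,valid_intervals validation recording/labels for the
#'   cross-session scheme; omit both for within-session evaluation.
#' @param sources subset of
#'   `c("ds", "fft", "ds+phase", "ds+stagger", "ds+global")`.
#' @param n_per_interval vectors per interval per set.
#' @param n_folds folds per evaluation.
#' @param seed integer seed (features and folds).
#' @param C soft-margin parameter.
#' @return data frame with columns `window_s`, `source`,
#'   `median_error_pct`, `auc`.
#' @export
performance_vs_window <- function(train_rec, train_intervals, windows,
                                  valid_rec = NULL, valid_intervals = NULL,
                                  sources = c("ds", "fft", "ds+phase",
                                              "ds+stagger", "ds+global"),
                                  n_per_interval = 50, n_folds = 50,
                                  seed = 1L, C = 1) {
  sources <- match.arg(sources, several.ok = TRUE)
  cross <- !is.null(valid_rec)
  scheme <- if (cross) "cross_session" else "within_session"
  out <- list()
  for (w in windows) for (src in sources) {
    kind <- if (src == "fft") "fft" else "ds"
    surr <- switch(src, "ds+phase" = "phase", "ds+stagger" = "stagger",
                   "ds+global" = "global_stagger", "none")
    build <- function(rec, iv, s_off) {
      if (kind == "ds")
        make_ds_vectors(rec, iv, w, n_per_interval, surrogate = surr,
                        seed = seed + s_off)
      else
        make_fft_vectors(rec, iv, w, n_per_interval, surrogate = surr,
                         seed = seed + s_off)
    }
    tr <- build(train_rec, train_intervals, 0L)
    va <- if (cross) build(valid_rec, valid_intervals, 1000L) else NULL
    rep <- evaluate(fold_protocol(n_folds, seed = seed, scheme = scheme),
                    tr, va, C = C)
    out[[length(out) + 1L]] <- data.frame(
      window_s = w, source = src,
      median_error_pct = stats::median(rep$errors_pct), auc = rep$auc)
  }
  do.call(rbind, out)
}
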