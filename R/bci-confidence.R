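## ---- zero-phase IIR filtering with steady-state initial conditions ----
## signal::filtfilt starts both passes from zero initial conditions, which
## leaves long edge transients for filters with very low cutoff frequencies
## (a 0.15 Hz high-pass settles over seconds). We therefore run the
## forward-backward pass ourselves with the steady-state initial state
## (the state for which a constant input yields a constant output) plus a
## short odd-reflection extension, as standard zero-phase implementations do.

## steady-state filter state for a unit-step input (direct form II transposed)
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  a <- c(a, rep(0, nf - length(a)))
  b <- c(b, rep(0, nf - length(b)))
  b <- b / a[1]
  a <- a / a[1]
  comp <- matrix(0, nf - 1, nf - 1)
  comp[1, ] <- -a[2:nf]
  if (nf > 2) comp[cbind(2:(nf - 1), 1:(nf - 2))] <- 1
  B <- b[2:nf] - a[2:nf] * b[1]
  solve(diag(nf - 1) - t(comp), B)
}

## direct form II transposed IIR filter with initial state
lfilter <- function(b, a, x, zi) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  z <- c(zi, 0)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    for (j in seq_len(nf - 1)) {
      z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * y[i]
    }
  }
  y
}

## zero-phase forward-backward filtering, scipy-style
filtfilt_ss <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  nf <- max(length(a), length(b))
  padlen <- min(3L * (nf - 1L), length(x) - 1L)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[(padlen + 1):2]
    post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)]
    xt <- c(pre, x, post)
  } else {
    xt <- x
  }
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, xt, zi * xt[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + length(x))]
  y
}

#' Preprocess a continuous multichannel EEG recording
#'
#' Applies, in order: (1) re-referencing to the average of the reference
#' channels (e.g. earlobes), (2) zero-phase Butterworth band-pass filtering
#' (order-2 high-pass cascaded with an order-4 low-pass, each run
#' forward-backward), and (3) ocular-artefact removal by least-squares
#' regression: the filtered EOG channel is projected out of every scalp
#' channel. Reference and EOG rows are dropped from the output.
#'
#' @param raw numeric matrix, channels x samples.
#' @param fs sampling rate (Hz).
#' @param band band-pass edges `(low, high)` in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param ref_channels integer indices of reference channels (optional).
#' @param eog_channel integer index of the EOG channel (optional).
#' @return channels x samples matrix of preprocessed scalp channels.
#' @export
preprocess_continuous <- function(raw, fs, band = c(0.15, 40),
                                  ref_channels = NULL, eog_channel = NULL) {
  stopifnot(is.matrix(raw), fs > 0, length(band) == 2)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2)) {
    stop(sprintf("band [%g, %g] Hz must lie strictly inside (0, fs/2 = %g)",
                 band[1], band[2], fs / 2))
  }
  idx_all <- seq_len(nrow(raw))
  if (!is.null(ref_channels)) {
    stopifnot(all(ref_channels %in% idx_all))
    ref <- colMeans(raw[ref_channels, , drop = FALSE])
    raw <- sweep(raw, 2, ref)
  }
  if (!is.null(eog_channel)) stopifnot(eog_channel %in% idx_all)

  hp <- signal::butter(2, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(4, band[2] / (fs / 2), type = "low")
  filt <- t(apply(raw, 1, function(ch) {
    filtfilt_ss(lp, filtfilt_ss(hp, ch))
  }))

  scalp <- setdiff(idx_all, c(ref_channels, eog_channel))
  out <- filt[scalp, , drop = FALSE]
  if (!is.null(eog_channel)) {
    eog <- filt[eog_channel, ]
    denom <- sum(eog^2)
    if (denom > 0) {
      beta <- as.vector(out %*% eog) / denom
      out <- out - tcrossprod(beta, eog)
    }
  }
  rownames(out) <- rownames(raw)[scalp]
  out
}

#' Extract a response-locked epoch
#'
#' Cuts the window `[response - pre_s, response - pre_s + len_s)` out of a
#' continuous recording: by default 1 s before the response and lasting
#' 1.5 s (so 0.5 s after it).
#'
#' @param raw channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param response_sample sample index of the response.
#' @param pre_s seconds before the response at which the epoch starts.
#' @param len_s epoch length in seconds.
#' @param trial_id optional id used in error messages.
#' @return channels x `round(len_s * fs)` matrix with attribute `fs`.
#' @export
extract_epoch <- function(raw, fs, response_sample, pre_s = 1.0, len_s = 1.5,
                          trial_id = NA) {
  stopifnot(is.matrix(raw), fs > 0)
  n_out <- as.integer(round(len_s * fs))
  start <- as.integer(round(response_sample - pre_s * fs))
  if (start < 1L || start + n_out - 1L > ncol(raw)) {
    stop(sprintf(
      "epoch window [%d, %d] out of recording bounds [1, %d] (trial %s)",
      start, start + n_out - 1L, ncol(raw), as.character(trial_id)))
  }
  ep <- raw[, start:(start + n_out - 1L), drop = FALSE]
  attr(ep, "fs") <- fs
  ep
}

#' Baseline-correct an epoch
#'
#' Subtracts from every channel its mean voltage over the `window_s` seconds
#' preceding stimulus onset (taken from the continuous recording).
#'
#' @param epoch channels x samples matrix.
#' @param raw channels x samples continuous recording (same channel order).
#' @param fs sampling rate of `raw` (Hz).
#' @param stimulus_sample sample index of stimulus onset in `raw`.
#' @param window_s baseline window length in seconds (default 0.2).
#' @return the baseline-corrected epoch.
#' @export
baseline_correct <- function(epoch, raw, fs, stimulus_sample, window_s = 0.2) {
  stopifnot(is.matrix(epoch), is.matrix(raw), nrow(epoch) == nrow(raw))
  n_b <- as.integer(round(window_s * fs))
  start <- as.integer(stimulus_sample) - n_b
  if (start < 1L || stimulus_sample - 1L > ncol(raw)) {
    stop("baseline window out of recording bounds")
  }
  base <- rowMeans(raw[, start:(stimulus_sample - 1L), drop = FALSE])
  epoch - base
}

#' Downsample an epoch with anti-alias filtering
#'
#' Low-pass filters (zero-phase order-8 Butterworth, cutoff at 80% of the new
#' Nyquist) and then decimates by the integer factor `fs / target_fs`.
#'
#' @param epoch channels x samples matrix.
#' @param fs current sampling rate; taken from `attr(epoch, "fs")` if missing.
#' @param target_fs new sampling rate (must divide `fs`).
#' @return decimated epoch with attribute `fs = target_fs`.
#' @export
downsample_epoch <- function(epoch, fs = attr(epoch, "fs"), target_fs = 32) {
  stopifnot(is.matrix(epoch), !is.null(fs))
  if (target_fs >= fs) stop("target_fs must be smaller than fs")
  factor <- fs / target_fs
  if (abs(factor - round(factor)) > 1e-8) {
    stop(sprintf("fs = %g is not an integer multiple of target_fs = %g",
                 fs, target_fs))
  }
  factor <- as.integer(round(factor))
  ## decimate in stages of at most 8 (IIR anti-alias filters with very low
  ## relative cutoffs are numerically fragile); each stage low-passes at 80%
  ## of its new Nyquist with an order-8 zero-phase Butterworth
  out <- epoch
  cur_fs <- fs
  remaining <- factor
  while (remaining > 1L) {
    stage <- max(which(remaining %% seq_len(min(8L, remaining)) == 0L))
    if (stage == 1L) stage <- remaining     # prime factor > 8: single stage
    new_fs <- cur_fs / stage
    lp <- signal::butter(8, 0.8 * (new_fs / 2) / (cur_fs / 2), type = "low")
    filt <- t(apply(out, 1, function(ch) filtfilt_ss(lp, ch)))
    out <- filt[, seq(1L, ncol(filt), by = stage), drop = FALSE]
    cur_fs <- new_fs
    remaining <- remaining %/% stage
  }
  attr(out, "fs") <- target_fs
  out
}

## scalar shrinkage towards mu*I until the condition number is acceptable
shrink_cov <- function(S, max_cond = 1e6) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  mu <- mean(diag(S))
  lo <- min(ev)
  hi <- max(ev)
  if (lo > 0 && hi / lo <= max_cond) return(S)
  ## smallest gamma with ((1-g)hi + g mu) / ((1-g)lo + g mu) <= max_cond
  g <- (hi - max_cond * lo) / (hi - max_cond * lo + (max_cond - 1) * mu)
  g <- clamp(max(g, 1e-12), 0, 1)
  warning(sprintf(
    "rank-deficient/ill-conditioned covariance: applying scalar shrinkage (gamma = %.3g)",
    g))
  (1 - g) * S + g * mu * diag(nrow(S))
}

#' Common Spatial Patterns from class covariance matrices
#'
#' Algebraic core of CSP: given the two class covariances, returns the filter
#' matrix `W` (rows = spatial filters) that simultaneously diagonalises both,
#' normalised so that `W (Sa + Sb) W' = I`. Row `j`'s eigenvalue is the
#' variance fraction `w_j' Sa w_j / (w_j' (Sa + Sb) w_j)` captured from class
#' A; rows are ordered by decreasing eigenvalue, so the first filter
#' maximises class-A relative variance and the last maximises class B's.
#' Each row's sign is fixed by making its largest-magnitude entry positive.
#'
#' @param Sa,Sb symmetric positive (semi-)definite class covariance matrices.
#' @param max_cond condition-number limit above which scalar shrinkage is
#'   applied (with a warning).
#' @return object of class `csp_model`: list with `W`, `eigenvalues`,
#'   `patterns` (activation patterns, the columns of `solve(W)` up to the
#'   whitening metric), and `class_order`.
#' @export
csp_from_cov <- function(Sa, Sb, max_cond = 1e6) {
  stopifnot(is.matrix(Sa), is.matrix(Sb), all(dim(Sa) == dim(Sb)),
            nrow(Sa) == ncol(Sa))
  Sa <- (Sa + t(Sa)) / 2
  Sb <- (Sb + t(Sb)) / 2
  C <- shrink_cov(Sa + Sb, max_cond)
  ec <- eigen(C, symmetric = TRUE)
  if (min(ec$values) <= 0) stop("pooled covariance is not positive definite")
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)      # whitener: P C P' = I
  S <- P %*% Sa %*% t(P)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)          # eigenvalues in [0,1]
  W <- t(es$vectors) %*% P
  ## sign convention: largest-|entry| of each filter positive
  for (j in seq_len(nrow(W))) {
    if (W[j, which.max(abs(W[j, ]))] < 0) W[j, ] <- -W[j, ]
  }
  structure(
    list(W = W, eigenvalues = es$values,
         patterns = C %*% t(W), class_order = c("correct", "incorrect")),
    class = "csp_model"
  )
}

#' Fit Common Spatial Patterns to labelled epochs
#'
#' Estimates the two class covariances (average over epochs of the
#' row-centred sample covariance) and solves the CSP generalised
#' eigenproblem via [csp_from_cov()]. Class A is `"correct"`, class B
#' `"incorrect"`.
#'
#' @param epochs `eeg_epochs` object, or a `channels x samples x epochs`
#'   array combined with `labels`.
#' @param labels factor/character of `"correct"`/`"incorrect"` per epoch
#'   (ignored when `epochs` is an `eeg_epochs` object).
#' @param max_cond shrinkage trigger, see [csp_from_cov()].
#' @return a `csp_model`.
#' @export
fit_csp <- function(epochs, labels = NULL, max_cond = 1e6) {
  if (inherits(epochs, "eeg_epochs")) {
    labels <- epochs$label
    arr <- epochs$data
  } else {
    arr <- epochs
  }
  stopifnot(length(dim(arr)) == 3, !is.null(labels),
            length(labels) == dim(arr)[3])
  labels <- factor(as.character(labels), levels = c("correct", "incorrect"))
  if (any(is.na(labels))) stop("labels must be 'correct' or 'incorrect'")
  counts <- table(labels)
  if (any(counts < 2)) {
    stop(sprintf("need >= 2 epochs per class (got correct=%d, incorrect=%d)",
                 counts[["correct"]], counts[["incorrect"]]))
  }
  class_cov <- function(idx) {
    S <- 0
    for (i in idx) {
      X <- arr[, , i]
      X <- X - rowMeans(X)
      S <- S + tcrossprod(X) / (ncol(X) - 1L)
    }
    S / length(idx)
  }
  csp_from_cov(class_cov(which(labels == "correct")),
               class_cov(which(labels == "incorrect")),
               max_cond = max_cond)
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d filters; eigenvalues %.3f .. %.3f\n",
              nrow(x$W), max(x$eigenvalues), min(x$eigenvalues)))
  invisible(x)
}

#' CSP log-variance features of one epoch
#'
#' Projects the epoch through the CSP filters and returns the log-variances of
#' the first and last projected components (the two most class-discriminative
#' directions).
#'
#' @param epoch channels x samples matrix.
#' @param model a `csp_model`.
#' @return numeric length-2 vector `c(logvar_first, logvar_last)`.
#' @export
csp_features <- function(epoch, model) {
  stopifnot(inherits(model, "csp_model"), is.matrix(epoch),
            nrow(epoch) == ncol(model$W))
  Y <- model$W[c(1L, nrow(model$W)), , drop = FALSE] %*% epoch
  v <- apply(Y, 1, stats::var)
  if (any(v <= 0)) stop("zero-variance CSP projection: log feature undefined")
  log(v)
}

## feature matrix for a whole epoch set
csp_feature_matrix <- function(arr, model) {
  t(vapply(seq_len(dim(arr)[3]),
           function(i) csp_features(arr[, , i], model),
           numeric(2)))
}

#' Fit the L2-penalised logistic confidence model
#'
#' Ridge logistic regression of correctness on the CSP features, giving the
#' per-trial probability `w_p` that the decision was correct. Penalty
#' parameterised by the inverse strength `C` (ridge `lambda = 1/(n * C)`);
#' the intercept is unpenalised. If the training labels contain only one
#' class, an intercept-only model predicting the (lightly smoothed) base rate
#' is returned.
#'
#' @param features n x p numeric matrix.
#' @param correct logical vector of length n.
#' @param C inverse regularisation strength (> 0), default 1.
#' @return object of class `confidence_model` with `coefficients`,
#'   `intercept`, `lambda`.
#' @export
fit_confidence_model <- function(features, correct, C = 1) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(correct), C > 0,
            all(is.finite(features)))
  correct <- as.logical(correct)
  n <- length(correct)
  if (length(unique(correct)) < 2L ||
        all(apply(features, 2, stats::var) == 0)) {
    ## one-class labels or no usable predictors: intercept-only base rate
    p_hat <- clamp((sum(correct) + 0.5) / (n + 1), 1e-6, 1 - 1e-6)
    return(structure(
      list(coefficients = rep(0, ncol(features)),
           intercept = stats::qlogis(p_hat), lambda = NA_real_),
      class = "confidence_model"))
  }
  lambda <- 1 / (n * C)
  fit <- glmnet::glmnet(features, factor(correct, levels = c(FALSE, TRUE)),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = FALSE, thresh = 1e-10)
  structure(
    list(coefficients = as.vector(fit$beta), intercept = as.vector(fit$a0),
         lambda = lambda),
    class = "confidence_model"
  )
}

#' Predict decision confidence
#'
#' @param object a `confidence_model`.
#' @param features n x p matrix of CSP features.
#' @param ... unused.
#' @return vector of probabilities `w_p` in `(0, 1)`.
#' @export
predict.confidence_model <- function(object, features, ...) {
  features <- as.matrix(features)
  as.vector(stats::plogis(object$intercept +
                            features %*% object$coefficients))
}

#' Stratified cross-validation folds
#'
#' Assigns trials to `k` folds, stratified by label, with fold sizes made
#' exactly equal whenever `k` divides the trial count (remainders otherwise
#' differ by at most one trial).
#'
#' @param labels vector defining the strata (e.g. correctness).
#' @param k number of folds.
#' @param seed integer seed (own substream) or `NULL`.
#' @return integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(labels, k, seed = NULL) {
  n <- length(labels)
  if (k > n) stop(sprintf("k = %d folds exceed the %d available trials", k, n))
  if (!is.null(seed)) set.seed(substream_seed(seed, "folds"))
  fold <- integer(n)
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  ## per-class assignment is balanced within each stratum (+-1); when k
  ## divides n, rebalance across strata so every fold has exactly n/k trials
  if (n %% k == 0L) {
    repeat {
      sizes <- tabulate(fold, k)
      if (max(sizes) == min(sizes)) break
      from <- which(fold == which.max(sizes))
      fold[from[sample.int(length(from), 1L)]] <- which.min(sizes)
    }
  }
  fold
}

## fit CSP + logistic model on training epochs; returns both models
fit_confidence_pipeline <- function(arr, correct, C = 1, max_cond = 1e6) {
  labels <- factor(ifelse(correct, "correct", "incorrect"),
                   levels = c("correct", "incorrect"))
  csp <- fit_csp(arr, labels, max_cond = max_cond)
  feats <- csp_feature_matrix(arr, csp)
  list(csp = csp, clf = fit_confidence_model(feats, correct, C = C))
}

## apply a fitted pipeline to epochs
predict_confidence_pipeline <- function(fit, arr) {
  predict(fit$clf, csp_feature_matrix(arr, fit$csp))
}

#' Cross-validated EEG decision-confidence estimates
#'
#' The complete per-participant confidence decoder: trials are split into `k`
#' stratified folds; for each fold the CSP filters and the logistic model are
#' fitted on the training epochs only, and out-of-fold confidence `w_p` is
#' emitted for the test epochs. Every trial receives exactly one out-of-fold
#' estimate.
#'
#' @param epochs `eeg_epochs` object (single agent), or a 3D array with
#'   `correct` supplied.
#' @param correct logical vector (ignored for `eeg_epochs`, where labels are
#'   used).
#' @param k number of folds (default 8).
#' @param C inverse L2 strength for the logistic model.
#' @param seed integer seed for the fold assignment.
#' @return data.frame with `agent_id`, `trial_id`, `fold_id`, `correct`,
#'   `w_p`.
#' @export
crossval_confidence <- function(epochs, correct = NULL, k = 8, C = 1,
                                seed = NULL) {
  if (inherits(epochs, "eeg_epochs")) {
    arr <- epochs$data
    correct <- epochs$label == "correct"
    trial_id <- epochs$trial_id
    agent_id <- epochs$agent_id
  } else {
    arr <- epochs
    stopifnot(!is.null(correct))
    trial_id <- seq_len(dim(arr)[3])
    agent_id <- rep(NA_integer_, dim(arr)[3])
  }
  n <- dim(arr)[3]
  if (k > n) stop("more folds than trials")
  fold <- make_folds(correct, k, seed = seed)
  w_p <- numeric(n)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    fit <- fit_confidence_pipeline(arr[, , tr, drop = FALSE], correct[tr],
                                   C = C)
    w_p[te] <- predict_confidence_pipeline(fit, arr[, , te, drop = FALSE])
  }
  data.frame(agent_id = agent_id, trial_id = trial_id, fold_id = fold,
             correct = correct, w_p = w_p)
}
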