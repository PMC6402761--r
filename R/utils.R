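`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible substream seed
#'
#' Maps a master seed plus an arbitrary label path to a deterministic integer
#' in `[0, 2^31 - 2]`, so each pipeline stage (schedule, agents, decisions,
#' eeg, distances, folds, fusion coins, ...) draws from its own named stream
#' and stages stay independently reproducible.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer seed.
#' @export
#' @examples
#' substream_seed(1, "schedule")
#' substream_seed(1, "fuse", "b", "2-5")
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Rank-based AUC of `scores` for separating `labels` (logical or 0/1, TRUE =
#' positive class). Equals the probability that a random positive outscores a
#' random negative, with ties counted as 1/2.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("auc_score() needs at least one positive and one negative label")
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Encode trial truth as a vote
#'
#' The voting convention throughout the package is `-1` = "target",
#' `+1` = "nontarget"; the ideal decision maker's vote on a trial is the
#' encoded truth.
#'
#' @param truth character/factor vector of `"target"`/`"nontarget"`, or a
#'   vector already in `{-1, +1}` (returned unchanged).
#' @return integer vector in `{-1, +1}`.
#' @export
truth_to_vote <- function(truth) {
  if (is.numeric(truth)) {
    if (!all(truth %in% c(-1, 1))) stop("numeric truth must be in {-1, +1}")
    return(as.integer(truth))
  }
  truth <- as.character(truth)
  if (!all(truth %in% c("target", "nontarget"))) {
    stop("truth labels must be 'target' or 'nontarget'")
  }
  ifelse(truth == "target", -1L, 1L)
}

## draw from N(mu, sd) truncated to [0, Inf) by inverse-CDF
rtruncnorm0 <- function(n, mu, sd) {
  lo <- stats::pnorm(0, mean = mu, sd = sd)
  u <- stats::runif(n, min = lo, max = 1)
  stats::qnorm(u, mean = mu, sd = sd)
}
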