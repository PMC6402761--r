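#' Hamming loss between two decision vectors
#'
#' Fraction of trials on which two decision makers disagree. Against the
#' ideal decision maker (votes = encoded truths) it equals the error rate.
#'
#' @param votes_a,votes_b aligned vote vectors.
#' @return fraction in `[0, 1]`.
#' @export
hamming_loss <- function(votes_a, votes_b) {
  if (length(votes_a) == 0L) stop("empty input")
  if (length(votes_a) != length(votes_b)) stop("vote vectors differ in length")
  mean(votes_a != votes_b)
}

#' Pairwise Hamming-loss matrix over all decision makers
#'
#' Builds the symmetric disagreement matrix over the human agents, the
#' machine (optional), and the ideal decision maker whose votes are the
#' encoded truths. The entry of any agent against `ideal` is that agent's
#' error rate; the matrix quantifies decision diversity (error-correction
#' potential) across the cohort.
#'
#' @param decisions data.frame (`agent_id`, `trial_id`, `vote`).
#' @param machine_decisions optional data.frame (`trial_id`, `vote`).
#' @param truths truth labels aligned with the sorted unique trial ids.
#' @return square numeric matrix with dimnames over
#'   `agents (+ "machine") + "ideal"`.
#' @export
build_hamming_matrix <- function(decisions, machine_decisions = NULL, truths) {
  agents <- sort(unique(decisions$agent_id))
  trials <- sort(unique(decisions$trial_id))
  V <- matrix(NA_integer_, length(agents), length(trials),
              dimnames = list(as.character(agents), NULL))
  V[cbind(match(decisions$agent_id, agents),
          match(decisions$trial_id, trials))] <- decisions$vote
  if (anyNA(V)) stop("missing votes for some (agent, trial) pair")
  rows <- V
  if (!is.null(machine_decisions)) {
    mv <- machine_decisions$vote[match(trials, machine_decisions$trial_id)]
    if (anyNA(mv)) stop("machine decisions missing for some trials")
    rows <- rbind(rows, machine = mv)
  }
  stopifnot(length(truths) == length(trials))
  rows <- rbind(rows, ideal = truth_to_vote(truths))
  n <- nrow(rows)
  H <- matrix(0, n, n, dimnames = list(rownames(rows), rownames(rows)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      H[i, j] <- H[j, i] <- hamming_loss(rows[i, ], rows[j, ])
    }
  }
  H
}

#' Summarise group performance by method and size
#'
#' Computes each group's confusion metrics over trials and aggregates them
#' (mean, SD) by fusion method and group size — the per-size performance
#' curves of the analysis.
#'
#' @param records data.frame from [run_campaign()].
#' @param truths truth labels aligned with the sorted unique trial ids in
#'   `records`, or a data.frame with `trial_id` and `truth` columns.
#' @return list of class `performance_summary` with `per_group` (one row per
#'   method x size x group: accuracy, specificity, sensitivity) and `by_size`
#'   (means and SDs per method x size, plus the group count `n_groups`).
#' @export
summarize_by_size <- function(records, truths) {
  trials <- sort(unique(records$trial_id))
  if (is.data.frame(truths)) {
    tv <- truth_to_vote(truths$truth[match(trials, truths$trial_id)])
  } else {
    stopifnot(length(truths) == length(trials))
    tv <- truth_to_vote(truths)
  }
  tt <- tv[match(records$trial_id, trials)]
  key <- paste(records$method, records$m, records$group_id, sep = "\r")
  ind <- cbind(
    tp = as.numeric(records$fused_vote == -1L & tt == -1L),
    fp = as.numeric(records$fused_vote == -1L & tt == 1L),
    tn = as.numeric(records$fused_vote == 1L & tt == 1L),
    fn = as.numeric(records$fused_vote == 1L & tt == -1L)
  )
  agg <- rowsum(ind, key, reorder = FALSE)
  ks <- strsplit(rownames(agg), "\r", fixed = TRUE)
  per_group <- data.frame(
    method = vapply(ks, `[`, "", 1L),
    m = as.integer(vapply(ks, `[`, "", 2L)),
    group_id = vapply(ks, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  n <- rowSums(agg)
  per_group$accuracy <- (agg[, "tp"] + agg[, "tn"]) / n
  per_group$specificity <- ifelse(agg[, "tn"] + agg[, "fp"] > 0,
                                  agg[, "tn"] / (agg[, "tn"] + agg[, "fp"]),
                                  NA_real_)
  per_group$sensitivity <- ifelse(agg[, "tp"] + agg[, "fn"] > 0,
                                  agg[, "tp"] / (agg[, "tp"] + agg[, "fn"]),
                                  NA_real_)
  rownames(per_group) <- NULL

  sk <- interaction(per_group$method, per_group$m, drop = TRUE, lex.order = TRUE)
  by_size <- do.call(rbind, lapply(split(per_group, sk), function(df) {
    data.frame(method = df$method[1], m = df$m[1], n_groups = nrow(df),
               mean_accuracy = mean(df$accuracy),
               sd_accuracy = stats::sd(df$accuracy),
               mean_specificity = mean(df$specificity),
               sd_specificity = stats::sd(df$specificity),
               mean_sensitivity = mean(df$sensitivity),
               sd_sensitivity = stats::sd(df$sensitivity))
  }))
  by_size <- by_size[order(by_size$method, by_size$m), ]
  rownames(by_size) <- NULL
  structure(list(per_group = per_group, by_size = by_size),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("<performance_summary>\n")
  print(x$by_size, digits = 3)
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired accuracy vectors (pairs = groups).
#' Zero differences are dropped (Wilcoxon's original convention); the exact
#' null distribution is used for up to 25 nonzero, untied differences,
#' otherwise the normal approximation with tie correction. If all differences
#' are zero the test is degenerate and `p = 1` is returned with a warning.
#'
#' @param x,y paired numeric vectors (same groups, two methods).
#' @return list with `p`, `statistic` (V, sum of positive ranks),
#'   `n_effective` (nonzero pairs).
#' @export
paired_wilcoxon <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 pairs")
  d <- x - y
  nz <- d != 0
  if (!any(nz)) {
    warning("all paired differences are zero; signed-rank test degenerate")
    return(list(p = 1, statistic = NA_real_, n_effective = 0L))
  }
  dn <- d[nz]
  exact <- length(dn) <= 25 && !any(duplicated(abs(dn)))
  wt <- suppressWarnings(
    stats::wilcox.test(x[nz], y[nz], paired = TRUE, exact = exact,
                       correct = !exact))
  list(p = unname(wt$p.value), statistic = unname(wt$statistic),
       n_effective = sum(nz))
}

#' Pairwise Wilcoxon comparison table across methods and sizes
#'
#' For each group size, runs [paired_wilcoxon()] on the per-group accuracies
#' of selected method pairs (groups are the pairing unit). Sizes with fewer
#' than 5 groups, or with only one group, are reported as `NA`. Note that
#' overlapping groups violate the independence assumption of the test; the
#' comparisons replicate the analysis convention regardless.
#'
#' @param summary a `performance_summary` from [summarize_by_size()].
#' @param pairs list of 2-character method pairs; default the six columns
#'   (a,b), (a,c), (b,c), (c,d), (b,d), (d,e).
#' @return data.frame: one row per size, one column of p-values per pair.
#' @export
wilcoxon_table <- function(summary,
                           pairs = list(c("a", "b"), c("a", "c"),
                                        c("b", "c"), c("c", "d"),
                                        c("b", "d"), c("d", "e"))) {
  pg <- summary$per_group
  sizes <- sort(unique(pg$m))
  out <- data.frame(m = sizes)
  for (pr in pairs) {
    col <- paste0(pr[1], "_vs_", pr[2])
    out[[col]] <- vapply(sizes, function(mm) {
      xa <- pg[pg$method == pr[1] & pg$m == mm, ]
      xb <- pg[pg$method == pr[2] & pg$m == mm, ]
      if (nrow(xa) < 5 || nrow(xb) < 5) return(NA_real_)
      xb <- xb[match(xa$group_id, xb$group_id), ]
      if (anyNA(xb$accuracy)) return(NA_real_)
      tryCatch(suppressWarnings(paired_wilcoxon(xa$accuracy, xb$accuracy)$p),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  out
}

#' Confidence-distribution tests by correctness
#'
#' Compares the confidence values assigned to correct vs incorrect decisions:
#' Kruskal-Wallis test for a location difference, Levene's test (median
#' centred) for a spread difference, plus per-class medians and SDs. A
#' well-behaved confidence estimator assigns higher and tighter confidence to
#' correct decisions.
#'
#' @param confidences numeric vector of confidence values.
#' @param correct logical vector, same length.
#' @return list with `kruskal_p`, `levene_p`, `medians` (named: correct,
#'   incorrect), `sds` (idem), and class counts `n`.
#' @export
confidence_distribution_tests <- function(confidences, correct) {
  stopifnot(length(confidences) == length(correct))
  correct <- as.logical(correct)
  if (!any(correct) || all(correct)) {
    stop("both correct and incorrect decisions are required")
  }
  g <- factor(ifelse(correct, "correct", "incorrect"),
              levels = c("correct", "incorrect"))
  kp <- stats::kruskal.test(confidences, g)$p.value
  lev <- car::leveneTest(confidences, g, center = stats::median)
  list(
    kruskal_p = unname(kp),
    levene_p = lev[["Pr(>F)"]][1],
    medians = c(correct = stats::median(confidences[correct]),
                incorrect = stats::median(confidences[!correct])),
    sds = c(correct = stats::sd(confidences[correct]),
            incorrect = stats::sd(confidences[!correct])),
    n = c(correct = sum(correct), incorrect = sum(!correct))
  )
}
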