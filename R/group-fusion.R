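#' Randomising sign operator
#'
#' Returns `+1` ("nontarget") where `x > 0`, `-1` ("target") where `x < 0`,
#' and a fair coin from the current RNG stream where `x == 0` — the
#' tie-breaking device of weighted majority fusion.
#'
#' @param x finite numeric vector.
#' @return integer vector in `{-1, +1}`.
#' @export
#' @examples
#' set.seed(1)
#' rsign(c(2.5, -0.1, 0))
rsign <- function(x) {
  if (any(!is.finite(x))) stop("rsign() requires finite arguments")
  s <- sign(x)
  z <- s == 0
  if (any(z)) s[z] <- ifelse(stats::runif(sum(z)) < 0.5, -1, 1)
  as.integer(s)
}

#' Fuse human votes by (confidence-)weighted majority
#'
#' Group decision `rsign(sum(w_p * d_p))`. With unit weights this is standard
#' majority voting (method "a"); with EEG-decoded confidences as weights it
#' is BCI-assisted voting (method "b"). Ties are resolved by [rsign()] from
#' the current RNG stream.
#'
#' @param votes integer votes in `{-1, +1}`.
#' @param weights nonnegative weights, same length (default all 1).
#' @return fused vote in `{-1, +1}`.
#' @export
fuse_humans <- function(votes, weights = rep(1, length(votes))) {
  if (length(votes) != length(weights)) stop("votes/weights length mismatch")
  if (any(weights < 0)) stop("weights must be nonnegative")
  rsign(sum(weights * votes))
}

#' Fuse human votes plus one machine vote
#'
#' Group decision `rsign(sum(w_p * d_p) + w_m * d_m)`: the machine joins the
#' group as one extra weighted member (methods "c" with unit weights, "d"
#' with confidence weights). A machine weight of 0 (no face detected) makes
#' the result identical to [fuse_humans()].
#'
#' @inheritParams fuse_humans
#' @param machine_vote machine vote in `{-1, +1}`.
#' @param machine_weight nonnegative machine weight.
#' @return fused vote in `{-1, +1}`.
#' @export
fuse_with_machine <- function(votes, weights = rep(1, length(votes)),
                              machine_vote, machine_weight = 1) {
  if (length(votes) != length(weights)) stop("votes/weights length mismatch")
  if (any(weights < 0) || machine_weight < 0) stop("weights must be nonnegative")
  rsign(sum(weights * votes) + machine_weight * machine_vote)
}

#' Fuse inner human-machine pairs by majority
#'
#' Method "e": each human is first paired with the (single) machine and the
#' pair decision `rsign(w_p * d_p + w_m * d_m)` is computed; the pair
#' decisions are then fused by plain majority with an outer [rsign()].
#'
#' @inheritParams fuse_with_machine
#' @return fused vote in `{-1, +1}`.
#' @export
fuse_inner_pairs <- function(votes, weights = rep(1, length(votes)),
                             machine_vote, machine_weight = 1) {
  if (length(votes) != length(weights)) stop("votes/weights length mismatch")
  if (any(weights < 0) || machine_weight < 0) stop("weights must be nonnegative")
  inner <- rsign(weights * votes + machine_weight * machine_vote)
  rsign(sum(inner))
}

#' Enumerate all groups of a given size
#'
#' All `choose(n, m)` subsets of `m` members out of a cohort of `n`, in
#' lexicographic order.
#'
#' @param n cohort size.
#' @param m group size, `1 <= m <= n`.
#' @return list of integer member-id vectors.
#' @export
#' @examples
#' length(enumerate_groups(10, 2)) # 45
enumerate_groups <- function(n, m) {
  if (!(m >= 1 && m <= n)) stop(sprintf("group size m = %d outside 1..%d", m, n))
  unname(as.list(as.data.frame(utils::combn(n, m))))
}

## internal: vectorised rsign over trials with a dedicated coin stream
rsign_stream <- function(sums, coins) {
  s <- sign(sums)
  z <- s == 0
  s[z] <- ifelse(coins[z] < 0.5, -1, 1)
  list(vote = as.integer(s), tie = z)
}

#' Run a full group-fusion campaign
#'
#' For every fusion method, group size, and enumerated group, fuses the
#' per-trial votes into group decisions. Methods:
#' \describe{
#'   \item{a}{humans, standard majority (unit weights)}
#'   \item{b}{humans, BCI-confidence weights}
#'   \item{c}{humans + machine, standard majority (machine weight 1, or 0 on
#'     no-face trials)}
#'   \item{d}{humans + machine, confidence weights (`w_p`, `w_ResNet`)}
#'   \item{e}{inner human-machine pairs (confidence-weighted), outer majority}
#' }
#' Tie coins are drawn from RNG substreams keyed by (method, group), one coin
#' per trial, so every (method, group, trial) tie is resolved independently
#' and reruns are reproducible. Method e's inner-pair ties use substreams
#' keyed by agent and are shared across groups (a pair's decision does not
#' depend on which group it sits in).
#'
#' @param decisions data.frame (`agent_id`, `trial_id`, `vote`) from
#'   [simulate_decisions()] or real data.
#' @param bci_confidences data.frame (`agent_id`, `trial_id`, `w_p`) from
#'   [crossval_confidence()]; required for methods b, d, e.
#' @param machine_decisions data.frame (`trial_id`, `vote`, `w_ResNet`,
#'   `face_found`) from [machine_decisions_cv()]; required for methods c, d,
#'   e.
#' @param methods character subset of `c("a","b","c","d","e")`.
#' @param sizes integer vector of human group sizes.
#' @param seed master seed for tie-coin substreams.
#' @return data.frame with `method`, `m`, `group_id` (members joined by "-"),
#'   `trial_id`, `fused_vote`, `tie_occurred`.
#' @export
run_campaign <- function(decisions, bci_confidences = NULL,
                         machine_decisions = NULL,
                         methods = c("a", "b", "c", "d", "e"),
                         sizes = 2:10, seed = 1) {
  methods <- match.arg(methods, c("a", "b", "c", "d", "e"),
                       several.ok = TRUE)
  agents <- sort(unique(decisions$agent_id))
  trials <- sort(unique(decisions$trial_id))
  n_agents <- length(agents)
  n_trials <- length(trials)
  if (any(sizes < 1 | sizes > n_agents)) {
    stop(sprintf("sizes must lie in 1..%d", n_agents))
  }

  to_matrix <- function(df, col) {
    M <- matrix(NA_real_, n_agents, n_trials,
                dimnames = list(agents, trials))
    M[cbind(match(df$agent_id, agents), match(df$trial_id, trials))] <- df[[col]]
    if (anyNA(M)) stop(sprintf("missing %s for some (agent, trial) pair", col))
    M
  }
  V <- to_matrix(decisions, "vote")

  need_bci <- any(methods %in% c("b", "d", "e"))
  need_machine <- any(methods %in% c("c", "d", "e"))
  Wb <- NULL
  if (need_bci) {
    if (is.null(bci_confidences)) {
      stop("methods b/d/e require bci_confidences")
    }
    Wb <- to_matrix(bci_confidences, "w_p")
  }
  mv <- mw_unit <- mw_conf <- NULL
  if (need_machine) {
    if (is.null(machine_decisions)) stop("methods c/d/e require machine_decisions")
    ord <- match(trials, machine_decisions$trial_id)
    if (anyNA(ord)) stop("machine decisions missing for some trials")
    mv <- machine_decisions$vote[ord]
    ff <- (machine_decisions$face_found %||% rep(TRUE, nrow(machine_decisions)))[ord]
    mw_unit <- as.numeric(ff)                      # method c: weight 1, 0 if no face
    mw_conf <- machine_decisions$w_ResNet[ord]     # methods d, e
  }

  ## method e: inner pair decisions depend only on (agent, trial)
  Inner <- NULL
  if ("e" %in% methods) {
    Inner <- matrix(0L, n_agents, n_trials)
    for (a in seq_len(n_agents)) {
      set.seed(substream_seed(seed, "inner", agents[a]))
      coins <- stats::runif(n_trials)
      r <- rsign_stream(Wb[a, ] * V[a, ] + mw_conf * mv, coins)
      Inner[a, ] <- r$vote
    }
  }

  WV <- if (need_bci) Wb * V else NULL
  groups_by_size <- lapply(sizes, function(m) enumerate_groups(n_agents, m))
  n_rows <- length(methods) * sum(vapply(groups_by_size, length, 0L)) * n_trials
  method_col <- character(n_rows)
  m_col <- integer(n_rows)
  gid_col <- character(n_rows)
  trial_col <- integer(n_rows)
  vote_col <- integer(n_rows)
  tie_col <- logical(n_rows)
  pos <- 0L

  for (meth in methods) {
    for (si in seq_along(sizes)) {
      m <- sizes[si]
      for (g in groups_by_size[[si]]) {
        gid <- paste(agents[g], collapse = "-")
        sums <- switch(meth,
          a = colSums(V[g, , drop = FALSE]),
          b = colSums(WV[g, , drop = FALSE]),
          c = colSums(V[g, , drop = FALSE]) + mw_unit * mv,
          d = colSums(WV[g, , drop = FALSE]) + mw_conf * mv,
          e = colSums(Inner[g, , drop = FALSE])
        )
        set.seed(substream_seed(seed, "fuse", meth, gid))
        coins <- stats::runif(n_trials)
        r <- rsign_stream(sums, coins)
        rows <- pos + seq_len(n_trials)
        method_col[rows] <- meth
        m_col[rows] <- m
        gid_col[rows] <- gid
        trial_col[rows] <- trials
        vote_col[rows] <- r$vote
        tie_col[rows] <- r$tie
        pos <- pos + n_trials
      }
    }
  }
  data.frame(method = method_col, m = m_col, group_id = gid_col,
             trial_id = trial_col, fused_vote = vote_col,
             tie_occurred = tie_col, stringsAsFactors = FALSE)
}
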