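#' Generate a block-structured trial schedule
#'
#' Builds the stimulus schedule of the face-search experiment: `n_blocks`
#' blocks of `trials_per_block` trials, each block containing exactly
#' `prevalence * trials_per_block` target trials at randomised positions.
#' Each block carries a condition tag (stimulus sequence x camera viewpoint);
#' with six blocks the tags cycle through the six sequence/viewpoint
#' combinations.
#'
#' @param n_blocks number of blocks (default 6).
#' @param trials_per_block trials in each block (default 48).
#' @param prevalence fraction of target trials per block (default 0.25);
#'   `prevalence * trials_per_block` must be integral.
#' @param seed integer seed (the schedule draws from its own substream);
#'   `NULL` uses the current RNG state.
#' @return data.frame with columns `trial_id`, `block`, `condition_tag`,
#'   `truth` (`"target"`/`"nontarget"`).
#' @export
#' @examples
#' sched <- generate_schedule(6, 48, 0.25, seed = 1)
#' table(sched$block, sched$truth)
generate_schedule <- function(n_blocks = 6, trials_per_block = 48,
                              prevalence = 0.25, seed = NULL) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1,
            prevalence >= 0, prevalence <= 1)
  n_targets <- prevalence * trials_per_block
  if (abs(n_targets - round(n_targets)) > 1e-8) {
    stop(sprintf(
      "prevalence %g x %d trials/block = %g targets per block is not integral",
      prevalence, trials_per_block, n_targets))
  }
  n_targets <- as.integer(round(n_targets))
  if (!is.null(seed)) set.seed(substream_seed(seed, "schedule"))

  tags <- apply(expand.grid(viewpoint = c("L", "C", "R"), sequence = 1:2),
                1L, function(r) paste0("S", r[["sequence"]], "-", r[["viewpoint"]]))
  truth <- character(0)
  for (b in seq_len(n_blocks)) {
    tb <- rep("nontarget", trials_per_block)
    tb[sample.int(trials_per_block, n_targets)] <- "target"
    truth <- c(truth, tb)
  }
  data.frame(
    trial_id = seq_len(n_blocks * trials_per_block),
    block = rep(seq_len(n_blocks), each = trials_per_block),
    condition_tag = rep(tags[(seq_len(n_blocks) - 1L) %% length(tags) + 1L],
                        each = trials_per_block),
    truth = truth,
    stringsAsFactors = FALSE
  )
}

#' Sample heterogeneous decision-agent profiles
#'
#' Draws per-agent sensitivity (target trials) and specificity (nontarget
#' trials) from independent Gaussians, clamped to `[0.01, 0.99]` (exact values
#' when the SD is zero). Defaults reproduce the observer population of the
#' face-search study: mean sensitivity 56.9% (SD 10.9%), mean specificity
#' 77.4% (SD 15.8%). `coupling` is the loading of every agent on a shared
#' per-trial difficulty latent and controls how strongly errors co-occur
#' across agents (0 = independent errors).
#'
#' @param n_agents number of agents.
#' @param mean_sens,sd_sens mean/SD of sensitivity.
#' @param mean_spec,sd_spec mean/SD of specificity.
#' @param coupling shared-difficulty loading in `[0, 1]`.
#' @param seed integer seed (own substream) or `NULL`.
#' @return data.frame with columns `agent_id`, `sensitivity`, `specificity`,
#'   `coupling`.
#' @export
sample_agent_profiles <- function(n_agents, mean_sens = 0.569, sd_sens = 0.109,
                                  mean_spec = 0.774, sd_spec = 0.158,
                                  coupling = 0.5, seed = NULL) {
  stopifnot(n_agents >= 1, sd_sens >= 0, sd_spec >= 0,
            coupling >= 0, coupling <= 1,
            mean_sens >= 0, mean_sens <= 1, mean_spec >= 0, mean_spec <= 1)
  if (!is.null(seed)) set.seed(substream_seed(seed, "agents"))
  draw <- function(mu, sd) {
    if (sd == 0) rep(mu, n_agents) else clamp(stats::rnorm(n_agents, mu, sd), 0.01, 0.99)
  }
  data.frame(
    agent_id = seq_len(n_agents),
    sensitivity = draw(mean_sens, sd_sens),
    specificity = draw(mean_spec, sd_spec),
    coupling = rep(coupling, n_agents)
  )
}

#' Simulate behavioural decisions for a cohort
#'
#' For every agent-trial pair, draws a vote in `{-1 (target), +1 (nontarget)}`.
#' An agent is correct on a trial with probability equal to its sensitivity
#' (target trials) or specificity (nontarget trials). Error co-occurrence is
#' induced by a Gaussian-copula construction: trial difficulty
#' `z_t ~ N(0, 1)` is shared by all agents, agent noise is independent, and
#' agent `p` is correct iff
#' `pnorm(rho_p * z_t + sqrt(1 - rho_p^2) * eps_pt) < p_correct`,
#' with `rho_p` the agent's coupling. Marginals are exact; coupling > 0 pushes
#' pairwise Hamming loss below the independence level.
#'
#' @param profiles data.frame from [sample_agent_profiles()].
#' @param schedule data.frame from [generate_schedule()].
#' @param seed integer seed (own substream) or `NULL`.
#' @return data.frame with columns `agent_id`, `trial_id`, `vote`, `correct`.
#' @export
simulate_decisions <- function(profiles, schedule, seed = NULL) {
  stopifnot(nrow(profiles) >= 1, nrow(schedule) >= 1)
  if (!is.null(seed)) set.seed(substream_seed(seed, "decisions"))
  n_trials <- nrow(schedule)
  n_agents <- nrow(profiles)
  truth_vote <- truth_to_vote(schedule$truth)
  is_target <- truth_vote == -1L

  z <- stats::rnorm(n_trials)
  out <- vector("list", n_agents)
  for (a in seq_len(n_agents)) {
    rho <- profiles$coupling[a]
    p_correct <- ifelse(is_target, profiles$sensitivity[a], profiles$specificity[a])
    u <- stats::pnorm(rho * z + sqrt(1 - rho^2) * stats::rnorm(n_trials))
    correct <- u < p_correct
    vote <- ifelse(correct, truth_vote, -truth_vote)
    out[[a]] <- data.frame(
      agent_id = profiles$agent_id[a],
      trial_id = schedule$trial_id,
      vote = as.integer(vote),
      correct = correct
    )
  }
  do.call(rbind, out)
}

#' Simulate EEG epochs with class-dependent spatial covariance
#'
#' Generates one response-locked epoch per decision record. Correct-class
#' epochs carry extra variance along one fixed spatial pattern, incorrect
#' epochs along a second (orthogonal) pattern, on top of isotropic unit
#' noise: for an epoch of class c, `X = sqrt(snr) * a_c %*% t(s) + E` with
#' `s, E ~ N(0,1)`. The class covariances are therefore
#' `I + snr * a_c a_c'`, so a decoder can recover correctness from spatial
#' variance structure, and at `snr = 0` the classes are indistinguishable.
#' The generative patterns are stored in the result for recovery checks.
#'
#' @param decisions data.frame from [simulate_decisions()] (one epoch per row).
#' @param n_channels number of EEG channels (>= 2).
#' @param fs sampling rate (Hz). Epochs are generated directly at the rate the
#'   decoder consumes (32 Hz by default, the post-downsampling rate).
#' @param duration epoch length in seconds.
#' @param snr signal-to-noise variance ratio (>= 0).
#' @param seed integer seed (own substream) or `NULL`.
#' @return an object of class `eeg_epochs`: list with `data`
#'   (`channels x samples x epochs` array), `fs`, `trial_id`, `agent_id`,
#'   `label` (factor `correct`/`incorrect`), `patterns`
#'   (`channels x 2` matrix, columns `correct`, `incorrect`), `snr`.
#' @export
simulate_eeg <- function(decisions, n_channels = 16, fs = 32, duration = 1.5,
                         snr = 0.18, seed = NULL) {
  stopifnot(n_channels >= 2, fs > 0, duration > 0, snr >= 0)
  if (!is.null(seed)) set.seed(substream_seed(seed, "eeg"))
  n_samples <- as.integer(round(duration * fs))
  n_epochs <- nrow(decisions)

  ## two orthonormal generative patterns (QR of a random matrix)
  Q <- qr.Q(qr(matrix(stats::rnorm(n_channels * 2), n_channels, 2)))
  patterns <- Q * rep(sign(Q[apply(abs(Q), 2, which.max) +
                              (seq_len(2) - 1L) * n_channels]), each = n_channels)
  colnames(patterns) <- c("correct", "incorrect")

  flat <- matrix(stats::rnorm(n_channels * n_samples * n_epochs),
                 nrow = n_channels)
  if (snr > 0) {
    sig <- matrix(stats::rnorm(n_samples * n_epochs), nrow = n_samples)
    cls <- ifelse(decisions$correct, 1L, 2L)
    for (k in 1:2) {
      idx <- which(cls == k)
      if (!length(idx)) next
      cols <- as.vector(outer(seq_len(n_samples), (idx - 1L) * n_samples, `+`))
      flat[, cols] <- flat[, cols] +
        sqrt(snr) * patterns[, k, drop = FALSE] %*% t(as.vector(sig[, idx]))
    }
  }
  structure(
    list(
      data = array(flat, dim = c(n_channels, n_samples, n_epochs)),
      fs = fs,
      trial_id = decisions$trial_id,
      agent_id = decisions$agent_id,
      label = factor(ifelse(decisions$correct, "correct", "incorrect"),
                     levels = c("correct", "incorrect")),
      patterns = patterns,
      snr = snr
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs, %d channels x %d samples @ %g Hz\n",
              d[3], d[1], d[2], x$fs))
  cat("  labels:", paste(sprintf("%s=%d", levels(x$label), table(x$label)),
                         collapse = ", "), "\n")
  invisible(x)
}

## subset an eeg_epochs object by epoch index
subset_epochs <- function(x, idx) {
  structure(
    list(data = x$data[, , idx, drop = FALSE], fs = x$fs,
         trial_id = x$trial_id[idx], agent_id = x$agent_id[idx],
         label = x$label[idx], patterns = x$patterns, snr = x$snr),
    class = "eeg_epochs"
  )
}

#' Simulate face-embedding distances
#'
#' Draws the per-trial minimum embedding distance `d` between faces in the
#' stimulus and the target face. Target trials draw from a low-mean Gaussian,
#' nontarget trials from a high-mean one, both truncated at 0. With
#' probability `p_no_face` (class-independent) no face is detected and `d` is
#' absent. Defaults are calibrated so that the accuracy-maximising threshold
#' sits near 0.526 and the thresholded machine reproduces a high-specificity
#' (~0.99) / low-sensitivity (~0.42) profile at 25% target prevalence.
#'
#' @param schedule data.frame from [generate_schedule()].
#' @param mu_target,mu_nontarget class-conditional distance means
#'   (`mu_target < mu_nontarget`).
#' @param sigma class SDs; scalar or length-2 `(target, nontarget)`.
#' @param p_no_face probability that no face is detected on a trial.
#' @param seed integer seed (own substream) or `NULL`.
#' @return data.frame with columns `trial_id`, `truth`, `d` (NA when no face),
#'   `face_found`.
#' @export
simulate_distances <- function(schedule, mu_target = 0.572,
                               mu_nontarget = 0.658,
                               sigma = c(0.22, 0.06), p_no_face = 0.01,
                               seed = NULL) {
  stopifnot(mu_target >= 0, mu_target < mu_nontarget,
            all(sigma > 0), length(sigma) %in% c(1L, 2L),
            p_no_face >= 0, p_no_face <= 1)
  sigma <- rep(sigma, length.out = 2L)
  if (!is.null(seed)) set.seed(substream_seed(seed, "distances"))
  n <- nrow(schedule)
  is_target <- truth_to_vote(schedule$truth) == -1L
  d <- numeric(n)
  d[is_target] <- rtruncnorm0(sum(is_target), mu_target, sigma[1])
  d[!is_target] <- rtruncnorm0(sum(!is_target), mu_nontarget, sigma[2])
  face_found <- stats::runif(n) >= p_no_face
  d[!face_found] <- NA_real_
  data.frame(
    trial_id = schedule$trial_id,
    truth = schedule$truth,
    d = d,
    face_found = face_found,
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_schedule()],
#' [sample_agent_profiles()], [simulate_decisions()], [simulate_distances()]
#' and (optionally) [simulate_eeg()] with named substreams from one master
#' seed.
#'
#' @param config configuration list as produced by [default_config()]; only
#'   the `cohort`, `eeg` and `distances` sections are used.
#' @param seed master seed overriding `config$seed` (optional).
#' @param with_eeg generate EEG epochs (TRUE by default).
#' @return list with `schedule`, `profiles`, `decisions`, `distances`, and
#'   `epochs` (NULL when `with_eeg = FALSE`).
#' @export
simulate_cohort <- function(config = default_config(), seed = NULL,
                            with_eeg = TRUE) {
  seed <- seed %||% config$seed
  ch <- config$cohort
  schedule <- generate_schedule(ch$n_blocks, ch$trials_per_block,
                                ch$prevalence, seed = seed)
  profiles <- sample_agent_profiles(ch$n_agents, ch$mean_sens, ch$sd_sens,
                                    ch$mean_spec, ch$sd_spec, ch$coupling,
                                    seed = seed)
  decisions <- simulate_decisions(profiles, schedule, seed = seed)
  ds <- config$distances
  distances <- simulate_distances(schedule, ds$mu_target, ds$mu_nontarget,
                                  c(ds$sigma_target, ds$sigma_nontarget),
                                  ds$p_no_face, seed = seed)
  epochs <- NULL
  if (with_eeg) {
    eg <- config$eeg
    epochs <- simulate_eeg(decisions, eg$n_channels, eg$fs, eg$duration,
                           eg$snr, seed = seed)
  }
  list(schedule = schedule, profiles = profiles, decisions = decisions,
       distances = distances, epochs = epochs)
}
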