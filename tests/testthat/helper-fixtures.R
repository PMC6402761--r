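## shared fixture builders (everything generated in code, no stored data)

## single-block schedule for quick marginal checks
flat_schedule <- function(n_trials, prevalence = 0.25, seed = 1) {
  generate_schedule(1, n_trials, prevalence, seed = seed)
}

## one-agent cohort with epochs, for decoder tests
one_agent_epochs <- function(seed, snr = NULL, n_trials = 288) {
  cfg <- default_config()
  sched <- generate_schedule(6, n_trials / 6, 0.25, seed = seed)
  prof <- sample_agent_profiles(1, seed = seed)
  dec <- simulate_decisions(prof, sched, seed = seed)
  simulate_eeg(dec, cfg$eeg$n_channels, cfg$eeg$fs, cfg$eeg$duration,
               snr = snr %||% cfg$eeg$snr, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## random SPD 2x2 matrix
random_spd2 <- function() {
  A <- matrix(rnorm(4), 2, 2)
  crossprod(A) + diag(2) * 0.1
}

## brute-force CSP oracle: max variance ratio w'Sa w / w'Sb w over
## n_dir unit-circle directions
csp_bruteforce_ratio <- function(Sa, Sb, n_dir = 1e4) {
  th <- seq(0, pi, length.out = n_dir)
  W <- rbind(cos(th), sin(th))
  num <- colSums(W * (Sa %*% W))
  den <- colSums(W * (Sb %*% W))
  max(num / den)
}

## independent threshold-search oracle: evaluate the metric at every
## candidate (midpoints of sorted distinct distances + extremes) with
## classification_metrics(); ties toward the smallest candidate
oracle_best_threshold <- function(d, face_found, truth, metric) {
  dv <- sort(unique(d[face_found & !is.na(d)]))
  gap <- if (length(dv) > 1) min(diff(dv)) / 2 else max(dv[1] / 2, 0.01)
  cand <- c(dv[1] - gap,
            if (length(dv) > 1) (dv[-1] + dv[-length(dv)]) / 2,
            dv[length(dv)] + gap)
  vals <- vapply(cand, function(t) {
    votes <- machine_decide(d, face_found, t)
    m <- classification_metrics(votes, truth)
    v <- m[[metric]]
    if (is.na(v)) 0 else v
  }, numeric(1))
  cand[which.max(vals)]
}

## exact two-sided signed-rank p by enumeration of all sign assignments
## (no ties, no zeros assumed)
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)                 # null distribution of V
  v_obs <- sum(r[d > 0])
  p <- 2 * min(mean(W <= v_obs), mean(W >= v_obs))
  min(p, 1)
}
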