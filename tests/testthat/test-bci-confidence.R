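test_that("preprocessing removes DC, keeps in-band signal, rejects bad bands", {
  fs <- 256
  t <- seq(0, 4, by = 1 / fs)[-1]
  dc <- matrix(5, nrow = 2, ncol = length(t))
  out <- preprocess_continuous(dc, fs, band = c(0.15, 40))
  expect_lt(max(abs(out)), 0.05)

  sine <- rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))
  outs <- preprocess_continuous(sine, fs, band = c(0.15, 40))
  mid <- seq(fs, length(t) - fs)   # ignore filter edges
  amp_ratio <- stats::sd(outs[1, mid]) / stats::sd(sine[1, mid])
  expect_lt(abs(amp_ratio - 1), 0.05)

  expect_error(preprocess_continuous(sine, fs, band = c(0.15, 200)),
               "fs/2")
})

test_that("EOG regression removes the projected ocular component", {
  set.seed(42)
  fs <- 256
  n <- 4 * fs
  t <- seq_len(n) / fs
  eog <- 3 * sin(2 * pi * 0.7 * t) + rnorm(n)
  clean <- rbind(sin(2 * pi * 9 * t) + 0.3 * rnorm(n),
                 cos(2 * pi * 13 * t) + 0.3 * rnorm(n))
  raw <- rbind(clean[1, ] + 0.8 * eog, clean[2, ] - 0.5 * eog, eog)
  out <- preprocess_continuous(raw, fs, band = c(0.15, 40), eog_channel = 3)
  eog_f <- preprocess_continuous(matrix(eog, 1), fs, band = c(0.15, 40))
  expect_equal(nrow(out), 2)
  for (ch in 1:2) {
    expect_lt(abs(stats::cor(out[ch, ], eog_f[1, ])), 0.05)
  }
})

test_that("epoch extraction yields the documented window", {
  fs <- 2048
  raw <- matrix(rnorm(3 * 5 * fs), nrow = 3)
  ep <- extract_epoch(raw, fs, response_sample = 3 * fs)
  expect_equal(ncol(ep), 3072)  # 1.5 s at 2048 Hz
  expect_equal(ep[, 1], raw[, 3 * fs - fs])  # starts 1 s before response
  expect_error(extract_epoch(raw, fs, response_sample = 10, trial_id = 99),
               "99")
  ## determinism: same slice twice
  expect_identical(ep, extract_epoch(raw, fs, response_sample = 3 * fs))
})

test_that("baseline correction subtracts the pre-stimulus channel means", {
  fs <- 100
  raw <- matrix(0, nrow = 2, ncol = 400)
  raw[1, ] <- 1
  raw[2, ] <- -2
  ep <- matrix(c(1, -2), nrow = 2, ncol = 50)
  out <- baseline_correct(ep, raw, fs, stimulus_sample = 200)
  expect_equal(out, matrix(0, 2, 50))
  ## zero-mean baseline leaves the epoch unchanged
  raw0 <- matrix(rep(c(1, -1), 200), nrow = 2, ncol = 400)  # alternating, mean 0
  raw0[2, ] <- -raw0[2, ]
  out2 <- baseline_correct(ep, raw0 - rowMeans(raw0), fs, stimulus_sample = 200)
  expect_equal(out2, ep)
  expect_error(baseline_correct(ep, raw, fs, stimulus_sample = 10), "bounds")
})

test_that("downsampling decimates correctly and suppresses aliasing", {
  fs <- 2048
  n <- round(1.5 * fs)
  dc <- matrix(3, nrow = 2, ncol = n)
  out <- downsample_epoch(dc, fs, 32)
  expect_equal(ncol(out), 48)   # 1.5 s at 32 Hz
  expect_equal(attr(out, "fs"), 32)
  expect_lt(max(abs(out - 3)), 1e-6)

  t <- seq_len(n) / fs
  s20 <- matrix(sin(2 * pi * 20 * t), nrow = 1)  # above the 16 Hz new Nyquist
  out20 <- downsample_epoch(s20, fs, 32)
  expect_lt(mean(out20^2) / mean(s20^2), 0.1)

  s5 <- matrix(sin(2 * pi * 5 * t), nrow = 1)    # in-band survives
  out5 <- downsample_epoch(s5, fs, 32)
  expect_gt(mean(out5^2) / mean(s5^2), 0.8)

  expect_error(downsample_epoch(dc, fs, 4096), "smaller")
  expect_error(downsample_epoch(dc, 100, 32), "integer multiple")
})

test_that("csp_from_cov solves the diagonal case in closed form", {
  m <- csp_from_cov(diag(c(4, 1)), diag(c(1, 4)))
  expect_equal(m$eigenvalues, c(0.8, 0.2), tolerance = 1e-10)
  ## first filter along axis 1, last along axis 2 (up to scale)
  expect_lt(abs(m$W[1, 2] / m$W[1, 1]), 1e-8)
  expect_lt(abs(m$W[2, 1] / m$W[2, 2]), 1e-8)

  ## identical class covariances: no discrimination, all eigenvalues 1/2
  S <- random_spd2()
  m2 <- csp_from_cov(S, S)
  expect_equal(m2$eigenvalues, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("CSP filters simultaneously diagonalise both class covariances", {
  set.seed(10)
  for (i in 1:10) {
    A <- matrix(rnorm(16), 4, 4); Sa <- crossprod(A) + 0.1 * diag(4)
    B <- matrix(rnorm(16), 4, 4); Sb <- crossprod(B) + 0.1 * diag(4)
    m <- csp_from_cov(Sa, Sb)
    Da <- m$W %*% Sa %*% t(m$W)
    Db <- m$W %*% Sb %*% t(m$W)
    expect_lt(max(abs(Da[upper.tri(Da)])), 1e-8)
    expect_lt(max(abs(Db[upper.tri(Db)])), 1e-8)
    ## eigenvalues sorted and consistent: diag(Da) = lambda, Da + Db = I
    expect_equal(diag(Da), m$eigenvalues, tolerance = 1e-8)
    expect_equal(diag(Da) + diag(Db), rep(1, 4), tolerance = 1e-8)
    expect_true(all(diff(m$eigenvalues) <= 1e-12))
  }
})

test_that("fit_csp recovers generative patterns from epochs", {
  sched <- flat_schedule(200, 0.25, seed = 12)
  prof <- sample_agent_profiles(1, seed = 12)
  dec <- simulate_decisions(prof, sched, seed = 12)
  ep <- simulate_eeg(dec, 6, 32, 1.5, snr = 8, seed = 12)
  m <- fit_csp(ep)
  ## the first filter should isolate the correct-class pattern: high
  ## eigenvalue, and the corresponding activation pattern aligned with it
  expect_gt(m$eigenvalues[1], 0.7)
  a <- ep$patterns[, "correct"]
  p1 <- m$patterns[, 1]
  alignment <- abs(sum(a * p1)) / sqrt(sum(a^2) * sum(p1^2))
  expect_gt(alignment, 0.9)
  expect_error(fit_csp(ep$data, rep("correct", dim(ep$data)[3])), ">= 2 epochs")
})

test_that("csp_features scale quadratically and demand nonzero variance", {
  m <- csp_from_cov(diag(c(4, 1)), diag(c(1, 4)))
  set.seed(3)
  ep <- matrix(rnorm(2 * 50), 2, 50)
  f1 <- csp_features(ep, m)
  f2 <- csp_features(2 * ep, m)
  expect_equal(f2 - f1, rep(log(4), 2), tolerance = 1e-10)
  expect_identical(f1, csp_features(ep, m))
  expect_error(csp_features(matrix(0, 2, 50), m), "zero-variance")
})

test_that("confidence model: base-rate intercept, separable case, one-class fallback", {
  ## zero-variance feature: prediction collapses to the base rate
  n <- 80
  X <- cbind(rep(1, n), rep(2, n))
  y <- rep(c(TRUE, FALSE), c(60, 20))
  fit <- fit_confidence_model(X, y, C = 1)
  expect_equal(unname(predict(fit, X)[1]), 0.75, tolerance = 0.01)

  ## perfectly separating feature: monotone probabilities, training AUC 1
  set.seed(5)
  x <- c(runif(40, -3, -1), runif(40, 1, 3))
  y2 <- rep(c(FALSE, TRUE), each = 40)
  fit2 <- fit_confidence_model(cbind(x, 0 * x), y2, C = 100)
  p <- predict(fit2, cbind(x, 0 * x))
  expect_equal(auc_score(p, y2), 1)
  expect_true(all(diff(p[order(x)]) >= -1e-12))

  ## all-correct labels: intercept-only fallback near 1
  fit3 <- fit_confidence_model(cbind(rnorm(20), rnorm(20)), rep(TRUE, 20))
  expect_gt(unname(predict(fit3, cbind(0, 0))[1]), 0.9)
})

test_that("stratified folds partition trials with exact sizes when possible", {
  labels <- rep(c(TRUE, FALSE), c(208, 80))
  fold <- make_folds(labels, 8, seed = 1)
  expect_equal(sort(unique(fold)), 1:8)
  expect_true(all(tabulate(fold, 8) == 36))
  ## off-balance strata still give exact fold sizes after rebalancing
  labels2 <- rep(c(TRUE, FALSE), c(201, 87))
  fold2 <- make_folds(labels2, 8, seed = 2)
  expect_true(all(tabulate(fold2, 8) == 36))
  ## non-divisible case: near-equal
  fold3 <- make_folds(rep(c(TRUE, FALSE), c(100, 44)), 7, seed = 3)
  expect_lte(max(tabulate(fold3, 7)) - min(tabulate(fold3, 7)), 2)
  expect_error(make_folds(labels, 300, seed = 1), "exceed")
})

test_that("out-of-fold estimates depend only on the training fold", {
  ep <- one_agent_epochs(21, snr = 0.5, n_trials = 96)
  cv <- crossval_confidence(ep, k = 4, seed = 21)
  expect_true(all(cv$w_p >= 0 & cv$w_p <= 1))
  expect_equal(sort(cv$trial_id), sort(ep$trial_id))  # one estimate per trial

  ## recompute one fold by hand from its training epochs only
  f <- 2
  tr <- which(cv$fold_id != f)
  te <- which(cv$fold_id == f)
  fit <- cyborgcrowd:::fit_confidence_pipeline(
    ep$data[, , tr, drop = FALSE], (ep$label == "correct")[tr], C = 1)
  w_manual <- cyborgcrowd:::predict_confidence_pipeline(
    fit, ep$data[, , te, drop = FALSE])
  expect_equal(unname(cv$w_p[te]), unname(w_manual), tolerance = 1e-12)

  ## removing one test trial leaves the others' estimates untouched
  keep <- te[-1]
  w_subset <- cyborgcrowd:::predict_confidence_pipeline(
    fit, ep$data[, , keep, drop = FALSE])
  expect_equal(unname(w_subset), unname(cv$w_p[keep]), tolerance = 1e-12)
})

test_that("decoded confidence separates correct from incorrect decisions", {
  ## Location difference in w_p between classes, checked over several
  ## cohorts; majority must show a significant Kruskal-Wallis difference.
  hits <- 0L
  for (s in 1:10) {
    ep <- one_agent_epochs(100 + s)
    cv <- crossval_confidence(ep, k = 8, seed = s)
    ct <- confidence_distribution_tests(cv$w_p, cv$correct)
    if (ct$medians["correct"] > ct$medians["incorrect"] &&
          ct$kruskal_p < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_gt(hits, 5)
})

test_that("crossval is reproducible for a fixed seed", {
  ep <- one_agent_epochs(33, n_trials = 96)
  cv1 <- crossval_confidence(ep, k = 8, seed = 9)
  cv2 <- crossval_confidence(ep, k = 8, seed = 9)
  expect_identical(cv1, cv2)
  expect_error(crossval_confidence(ep, k = 200, seed = 1), "folds")
})
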