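test_that("rsign returns the sign and flips a fair coin at zero", {
  expect_equal(rsign(c(2.5, -0.1, 7)), c(1L, -1L, 1L))
  set.seed(1)
  draws <- rsign(rep(0, 10000))
  expect_true(all(draws %in% c(-1L, 1L)))
  expect_lt(abs(mean(draws == 1) - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(rsign(c(1, NA)), "finite")
  expect_error(rsign(Inf), "finite")
})

test_that("human fusion implements weighted majority with tie coins", {
  expect_equal(fuse_humans(c(-1, -1, 1)), -1L)                 # strict majority
  expect_equal(fuse_humans(c(-1, 1, 1), c(0.9, 0.3, 0.3)), -1L) # confident minority
  set.seed(7)
  tie1 <- fuse_humans(c(-1, 1))
  expect_true(tie1 %in% c(-1L, 1L))
  ## tie resolution follows the RNG stream deterministically
  set.seed(7)
  expect_identical(fuse_humans(c(-1, 1)), tie1)
  expect_error(fuse_humans(c(-1, 1), c(1, 1, 1)), "mismatch")
  expect_error(fuse_humans(c(-1, 1), c(-1, 1)), "nonnegative")
})

test_that("machine fusion breaks ties and reduces to human fusion at weight 0", {
  expect_equal(fuse_with_machine(c(-1, 1), machine_vote = 1), 1L)
  expect_equal(fuse_with_machine(c(1, -1), c(0.3, 0.4),
                                 machine_vote = 1, machine_weight = 0.2), 1L)
  set.seed(3)
  a <- fuse_with_machine(c(-1, 1), machine_vote = 1, machine_weight = 0)
  set.seed(3)
  b <- fuse_humans(c(-1, 1))
  expect_identical(a, b)
})

test_that("inner-pair fusion: reductions and machine dominance", {
  set.seed(5)
  one_pair <- fuse_inner_pairs(-1, 0.4, machine_vote = 1, machine_weight = 0.9)
  set.seed(5)
  expect_identical(one_pair,
                   fuse_with_machine(-1, 0.4, machine_vote = 1,
                                     machine_weight = 0.9))
  ## dominant machine weight forces every inner pair to its vote
  expect_equal(fuse_inner_pairs(c(-1, -1, -1), c(0.1, 0.1, 0.1),
                                machine_vote = 1, machine_weight = 5), 1L)
  ## zero-weight machine: inner decisions are the human votes; 2-way tie
  set.seed(11)
  r <- fuse_inner_pairs(c(-1, 1), c(1, 1), machine_vote = 1,
                        machine_weight = 0)
  expect_true(r %in% c(-1L, 1L))
})

test_that("group enumeration matches the binomial counts in lexicographic order", {
  g2 <- enumerate_groups(10, 2)
  expect_length(g2, 45)
  expect_equal(g2[[1]], c(1, 2))
  expect_equal(g2[[45]], c(9, 10))
  expect_length(enumerate_groups(10, 3), 120)
  expect_length(enumerate_groups(4, 4), 1)
  expect_error(enumerate_groups(4, 5), "outside")
  ## lexicographic: first differing member decides the order
  keys <- sapply(enumerate_groups(5, 3), paste, collapse = ",")
  expect_equal(keys, sort(keys))
})

test_that("weight scaling never changes fused votes", {
  set.seed(2)
  for (i in 1:50) {
    votes <- sample(c(-1L, 1L), 5, replace = TRUE)
    w <- runif(5)
    seed <- sample.int(1e6, 1)
    set.seed(seed); r1 <- fuse_humans(votes, w)
    set.seed(seed); r2 <- fuse_humans(votes, w * 7.3)
    expect_identical(r1, r2)
  }
})

test_that("permutation of members never changes the fused vote", {
  set.seed(4)
  for (i in 1:50) {
    votes <- sample(c(-1L, 1L), 4, replace = TRUE)
    w <- runif(4)
    perm <- sample(4)
    seed <- sample.int(1e6, 1)
    set.seed(seed); r1 <- fuse_with_machine(votes, w, 1L, 0.5)
    set.seed(seed); r2 <- fuse_with_machine(votes[perm], w[perm], 1L, 0.5)
    expect_identical(r1, r2)
  }
})

test_that("campaign produces the full record grid, deterministically", {
  sched <- flat_schedule(24, 0.25, seed = 6)
  prof <- sample_agent_profiles(5, seed = 6)
  dec <- simulate_decisions(prof, sched, seed = 6)
  rec <- run_campaign(dec, methods = "a", sizes = 2, seed = 6)
  expect_equal(nrow(rec), choose(5, 2) * 24)
  expect_equal(length(unique(rec$group_id)), choose(5, 2))
  rec2 <- run_campaign(dec, methods = "a", sizes = 2, seed = 6)
  expect_identical(rec, rec2)

  ## unanimity: groups of clones never tie and return the common vote
  clone_dec <- do.call(rbind, lapply(1:3, function(a) {
    transform(dec[dec$agent_id == 1, ], agent_id = a)
  }))
  rec3 <- run_campaign(clone_dec, methods = "a", sizes = 3, seed = 1)
  expect_true(all(!rec3$tie_occurred))
  expect_equal(rec3$fused_vote,
               dec$vote[dec$agent_id == 1][match(rec3$trial_id, sched$trial_id)])
})

test_that("campaign validates its inputs", {
  sched <- flat_schedule(12, 0.25, seed = 8)
  prof <- sample_agent_profiles(3, seed = 8)
  dec <- simulate_decisions(prof, sched, seed = 8)
  expect_error(run_campaign(dec, methods = "b", sizes = 2, seed = 1),
               "require bci_confidences")
  expect_error(run_campaign(dec, methods = "c", sizes = 2, seed = 1),
               "require machine_decisions")
  expect_error(run_campaign(dec, methods = "a", sizes = 9, seed = 1),
               "sizes")
  ## missing confidence for one (agent, trial) pair is rejected
  conf <- data.frame(agent_id = rep(1:3, each = 12),
                     trial_id = rep(sched$trial_id, 3),
                     w_p = runif(36))
  expect_error(run_campaign(dec, conf[-1, ], methods = "b", sizes = 2, seed = 1),
               "missing w_p")
})

test_that("no-face trials make methods c and d collapse onto a and b", {
  sched <- flat_schedule(30, 0.2, seed = 13)
  prof <- sample_agent_profiles(4, seed = 13)
  dec <- simulate_decisions(prof, sched, seed = 13)
  conf <- data.frame(agent_id = dec$agent_id, trial_id = dec$trial_id,
                     w_p = runif(nrow(dec), 0.4, 0.9))
  ## machine never finds a face: vote +1, weight 0 everywhere
  machine <- data.frame(trial_id = sched$trial_id, vote = 1L,
                        w_ResNet = 0, face_found = FALSE)
  rec <- run_campaign(dec, conf, machine, methods = c("a", "b", "c", "d"),
                      sizes = c(2, 3), seed = 99)
  key <- function(m) {
    r <- rec[rec$method == m, ]
    r[order(r$m, r$group_id, r$trial_id), c("group_id", "trial_id", "fused_vote")]
  }
  ka <- key("a"); kc <- key("c")
  kb <- key("b"); kd <- key("d")
  ## same weighted sums; ties are re-randomised per method, so compare
  ## only trials that are not ties under either method
  ra <- rec[rec$method == "a", ]; rc <- rec[rec$method == "c", ]
  ra <- ra[order(ra$m, ra$group_id, ra$trial_id), ]
  rc <- rc[order(rc$m, rc$group_id, rc$trial_id), ]
  expect_identical(ra$tie_occurred, rc$tie_occurred)
  nt <- !ra$tie_occurred
  expect_identical(ra$fused_vote[nt], rc$fused_vote[nt])
  rb <- rec[rec$method == "b", ]; rd <- rec[rec$method == "d", ]
  rb <- rb[order(rb$m, rb$group_id, rb$trial_id), ]
  rd <- rd[order(rd$m, rd$group_id, rd$trial_id), ]
  expect_identical(rb$tie_occurred, rd$tie_occurred)
  nt2 <- !rb$tie_occurred
  expect_identical(rb$fused_vote[nt2], rd$fused_vote[nt2])
})
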