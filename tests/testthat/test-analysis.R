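# Builds a synthetic experiment log directly (no simulation), so the analysis
# functions can be checked against hand-computable expectations.
fake_log <- function(infield, cues, turns = NULL, variant = "cue_dependent") {
  n_trials <- nrow(infield)
  n <- ncol(infield)
  p <- sim_params(n_inp = max(n, 100L), n = n, t_plateau = seq_len(n) - 1)
  if (is.null(turns)) turns <- sample(c("D", "E"), n_trials, replace = TRUE)
  correct <- (cues == "A" & turns == "D") | (cues == "B" & turns == "E")
  structure(list(
    preset = list(name = "fake", task = task_spec(variant)),
    params = p, seed = 0L,
    trials = data.frame(trial = seq_len(n_trials), cue = cues, turn = turns,
                        was_random = FALSE, reward = as.numeric(correct),
                        correct = correct, v_D = 0, v_E = 0,
                        stringsAsFactors = FALSE),
    infield = infield, betas = infield * 0, traces = list(),
    checkpoints = list(), events = list(), state = list()),
    class = "hpc_experiment")
}

test_that("splitness is zero for cue-identical activity and rho for a perfect splitter", {
  set.seed(1)
  cues <- rep(c("A", "B"), 100)
  # in-field rate identical on A and B trials (cue-independent place field)
  x <- fake_log(cbind(rep(0.7, 200), runif(200)), cues)
  s1 <- splitness(x, 0)
  expect_true(all(abs(s1[!is.na(s1)]) < 1e-12))
  # perfect A-splitter with field rate 0.8
  inf <- matrix(0, 200, 2)
  inf[cues == "A", 1] <- 0.8
  x2 <- fake_log(inf, cues)
  s2 <- splitness(x2, 0)
  expect_equal(s2[200], 0.8)
  expect_equal(attr(s2, "peak"), 0.8)
  crit <- split_criterion(s2)
  expect_true(all(crit[!is.na(crit)][-(1:2)]))
})

test_that("splitness is missing, not zero, when the window lacks a cue type", {
  cues <- c(rep("A", 30), rep("B", 30))
  inf <- matrix(1, 60, 1)
  x <- fake_log(inf, cues)
  s <- splitness(x, 0, window = 10)
  expect_true(all(is.na(s[1:30])))       # no B trials seen yet
  expect_true(all(!is.na(s[31:39])))     # both types inside the window
  expect_true(all(is.na(s[40:60])))      # A trials have left the window
})

test_that("windowed means equal a brute-force computation on random logs", {
  set.seed(7)
  n_trials <- 150
  cues <- sample(c("A", "B"), n_trials, replace = TRUE)
  inf <- matrix(runif(n_trials * 3), n_trials, 3)
  x <- fake_log(inf, cues)
  w <- 25
  s <- splitness(x, 1, window = w)
  for (k in c(5, 26, 80, 150)) {
    use <- max(1, k - w + 1):k
    a <- inf[use[cues[use] == "A"], 2]
    b <- inf[use[cues[use] == "B"], 2]
    expected <- if (length(a) && length(b)) mean(a) - mean(b) else NA_real_
    expect_equal(unclass(s)[k], expected, tolerance = 1e-12)
  }
})

test_that("raising the split threshold never increases the split count", {
  set.seed(3)
  cues <- sample(c("A", "B"), 300, replace = TRUE)
  inf <- matrix(runif(300 * 4), 300, 4)
  inf[cues == "A", 2] <- inf[cues == "A", 2] + 0.5
  x <- fake_log(inf, cues)
  counts <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
    sum(sapply(0:3, function(nr) sum(split_criterion(splitness(x, nr), th),
                                     na.rm = TRUE)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("split onsets require persistence and report NA when never split", {
  cues <- rep(c("A", "B"), 150)
  inf <- matrix(0, 300, 2)
  inf[cues == "A" & seq_len(300) > 100, 1] <- 1   # splits from trial 101
  x <- fake_log(inf, cues)
  on <- split_onset_times(x, neurons = 0:1, window = 20, persist = 10)
  expect_false(is.na(on[1]))
  expect_true(on[1] >= 101 && on[1] <= 130)
  expect_true(is.na(on[2]))
})

test_that("behavioral performance matches a brute-force running mean", {
  set.seed(11)
  cues <- sample(c("A", "B"), 120, replace = TRUE)
  turns <- sample(c("D", "E"), 120, replace = TRUE)
  x <- fake_log(matrix(0, 120, 1), cues, turns)
  perf <- behavioral_performance(x, window = 30, per_cue = TRUE)
  corr <- as.numeric((cues == "A" & turns == "D") | (cues == "B" & turns == "E"))
  for (k in c(1, 15, 30, 77, 120)) {
    use <- max(1, k - 29):k
    expect_equal(perf$value[k], mean(corr[use]))
    a_use <- use[cues[use] == "A"]
    expect_equal(perf$A[k],
                 if (length(a_use)) mean(corr[a_use]) else NA_real_)
  }
  expect_true(all(perf$value >= 0 & perf$value <= 1))
  expect_equal(attr(perf, "measure"), "fraction_correct")
})

test_that("random-reward performance reports the labelled fraction-to-D", {
  cues <- rep("A", 50)
  turns <- rep(c("D", "D", "E"), length.out = 50)
  x <- fake_log(matrix(0, 50, 1), cues, turns, variant = "random_reward")
  perf <- behavioral_performance(x, window = 50)
  expect_equal(attr(perf, "measure"), "fraction_to_D")
  expect_equal(perf$value[50], mean(turns == "D"))
})

test_that("naive chance-level agents sit near 0.5 correct", {
  x <- cached_run("small20", run_experiment(small_preset(n_trials = 20), seed = 8))
  perf <- behavioral_performance(x, window = 20)
  expect_gt(perf$value[20], 0.1)
  expect_lt(perf$value[20], 0.9)
})

test_that("rate maps align trials, respect cue filters, and need traces", {
  pr <- small_preset(n_trials = 10)
  pr$trace_neurons <- 5L
  x <- run_experiment(pr, seed = 2)
  rm_all <- rate_map(x, 5)
  expect_equal(dim(rm_all), c(10L, 16L))
  rm_a <- rate_map(x, 5, cue = "A", align_trial = 4)
  expect_equal(nrow(rm_a), sum(x$trials$cue == "A"))
  expect_equal(rownames(rm_a), as.character(which(x$trials$cue == "A") - 4))
  expect_error(rate_map(x, 6), "traced")
})

test_that("zipper ordering returns stem ids and a correlation", {
  p <- sim_params()
  expect_equal(range(stem_neurons(p)), c(20L, 59L))
  cues <- rep(c("A", "B"), 300)
  inf <- matrix(0, 600, p$n)
  # construct a clean zipper: stem neuron id i splits at trial 5*(i-19)+100
  for (i in stem_neurons(p)) {
    start <- 100 + 5 * (i - 19)
    rows <- which(cues == (if (i %% 2 == 0) "A" else "B"))
    inf[rows[rows > start], i + 1] <- 1
  }
  x <- fake_log(inf, cues)
  z <- zipper_ordering(x, window = 50, persist = 20)
  expect_gt(z$rho, 0.9)
  expect_equal(z$n_split, 40)
})
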