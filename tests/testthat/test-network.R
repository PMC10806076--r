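test_that("activation nonlinearity has the right fixed points and limits", {
  expect_equal(gamma_act(1.4, 5, 1.4), 0.5)
  expect_equal(gamma_act(1e6, 1, 5), 1)
  expect_equal(gamma_act(-1e6, 1, 5), 0)
  # reference values m_beta = 5, c_beta = 1.4 at zero input
  expect_equal(gamma_act(0, 5, 1.4), 0.5 * (tanh(-7) + 1), tolerance = 1e-15)
  expect_equal(gamma_act(0, 5, 1.4), 8.315280277e-07, tolerance = 1e-9)
  # strictly increasing
  x <- seq(-3, 3, by = 0.1)
  expect_true(all(diff(gamma_act(x, 1, 5)) > 0))
})

test_that("beta is the weight-sum nonlinearity, monotone in W", {
  p <- sim_params()
  W <- matrix(0, p$n, p$n)
  b0 <- compute_beta(W, p)
  expect_equal(b0, rep(gamma_act(0, p$m_beta, p$c_beta), p$n))
  W[3, ] <- p$c_beta / p$n
  b1 <- compute_beta(W, p)
  expect_equal(b1[3], 0.5)
  W[3, 5] <- W[3, 5] + 0.01
  expect_gt(compute_beta(W, p)[3], 0.5)
})

test_that("with zero recurrent weights the soma reads out the basal input", {
  p <- sim_params()
  bank <- build_tuning_curves(p)
  streams <- rng_streams(7)
  w <- init_weights(p, streams)
  w$W[] <- 0
  beta <- compute_beta(w$W, p)
  st <- new_network_state(p, beta = beta)
  for (x in c(10, 40, 55)) {
    u <- external_input(bank, x, "B")
    step_network(st, w, u, p)
    expect_lt(max(abs(st$s - u) / pmax(u, 1e-12)), 1e-5)
  }
})

test_that("zero basal input silences the soma regardless of apical drive", {
  p <- small_params()
  streams <- rng_streams(1)
  w <- init_weights(p, streams)
  w$W[] <- p$w_max
  st <- new_network_state(p, beta = compute_beta(w$W, p))
  st$s <- rep(1, p$n)   # strong previous somatic activity -> apical drive
  step_network(st, w, rep(0, p$n_inp), p)
  expect_true(all(st$s == 0))
  expect_true(any(st$a > 0))
})

test_that("eligibility converges to tau_e times a constant somatic rate", {
  p <- small_params()
  streams <- rng_streams(1)
  w <- init_weights(p, streams)
  w$W[] <- 0
  st <- new_network_state(p, beta = compute_beta(w$W, p))
  u <- rep(0.5, p$n_inp)
  for (k in 1:400) step_network(st, w, u, p)
  expect_equal(st$e, st$s * p$tau_e, tolerance = 1e-6)
  expect_equal(st$e_action, st$s * p$tau_ea, tolerance = 1e-6)
})

test_that("non-finite dynamics abort with a diagnostic", {
  p <- small_params()
  streams <- rng_streams(1)
  w <- init_weights(p, streams)
  st <- new_network_state(p)
  st$s <- rep(Inf, p$n)
  expect_error(step_network(st, w, rep(1, p$n_inp), p), "non-finite")
})

test_that("induction schedule alternates parities and honors holdouts", {
  p <- sim_params()
  sa <- make_induction_schedule("A", p)
  sb <- make_induction_schedule("B", p)
  expect_equal(nrow(sa), p$n / 2)
  expect_true(all(sa$neuron %% 2 == 0))
  expect_true(all(sb$neuron %% 2 == 1))
  expect_true(81 %in% sb$neuron)
  expect_false(80 %in% sb$neuron)
  # plateau time equals the neuron id
  expect_equal(sa$t_plateau, sa$neuron)
  sh <- make_induction_schedule("B", p, holdouts = c(80, 81))
  expect_false(81 %in% sh$neuron)
  expect_equal(nrow(sh), p$n / 2 - 1)
})

test_that("plateau filter passes activity only inside the window", {
  p <- small_params(plateau_halfwidth = 2)
  sched <- make_induction_schedule("A", p)
  s <- runif(p$n, 0.5, 1)
  phi <- plateau_filter(s, sched, t = 6, p)
  inside <- sched$neuron[abs(6 - sched$t_plateau) <= 2] + 1
  expect_equal(phi[inside], s[inside])
  expect_true(all(phi[-inside] == 0))
  empty <- sched[0, ]
  expect_equal(plateau_filter(s, empty, 6, p), numeric(p$n))
})

test_that("proto-weights collapse to a single outer product for one plateau", {
  p <- small_params(plateau_halfwidth = 0)
  n <- p$n
  proto <- matrix(0, n, n)
  s <- runif(n); e <- runif(n, 0, 5)
  phi <- numeric(n); phi[4] <- s[4]
  proto <- accumulate_proto_weights(proto, phi, e)
  expect_equal(proto[4, ], s[4] * e)
  expect_true(all(proto[-4, ] == 0))
  expect_true(all(proto >= 0))
})

test_that("recurrent update potentiates, depresses, decays and clips", {
  p <- sim_params()
  W <- matrix(0.01, 4, 4)
  proto <- matrix(1, 4, 4)
  # at baseline reward the update is pure decay whatever the proto-weights
  expect_equal(update_recurrent_weights(W, proto, p$r0, p),
               W * (1 - p$lambda_w), tolerance = 1e-15)
  up <- update_recurrent_weights(W, proto, 1, p)
  dn <- update_recurrent_weights(W, proto, 0, p)
  expect_true(all(up > W * (1 - p$lambda_w)))
  expect_true(all(dn < W * (1 - p$lambda_w)))
  # clipping at the bounds
  big <- update_recurrent_weights(matrix(p$w_max, 4, 4), proto * 1e4, 1, p)
  expect_true(all(big == p$w_max))
  neg <- update_recurrent_weights(matrix(1e-4, 4, 4), proto * 1e4, 0, p)
  expect_true(all(neg == 0))
  # frozen rows stay at zero
  fr <- update_recurrent_weights(W, proto, 1, p, freeze_rows = 2L)
  expect_true(all(fr[3, ] == 0))
})

test_that("decay-only closed form holds over many trials", {
  p <- sim_params()
  W0 <- matrix(runif(25, 0, p$w_max / 2), 5, 5)
  zero <- matrix(0, 5, 5)
  W <- W0
  for (k in 1:40) W <- update_recurrent_weights(W, zero, 1, p)
  expect_equal(W, W0 * (1 - p$lambda_w)^40, tolerance = 1e-12)
})

test_that("input weights learn by plateau/input coactivation and saturate", {
  p <- small_params(input_plasticity = TRUE)
  M <- matrix(0.1, p$n, p$n_inp)
  expect_equal(update_input_weights(M, matrix(0, p$n, p$n_inp), p), M)
  proto <- matrix(0, p$n, p$n_inp)
  u <- runif(p$n_inp); s4 <- 0.8
  proto[4, ] <- u * s4
  M1 <- update_input_weights(M, proto, p)
  expect_equal(M1[4, ], pmin(M[4, ] + p$eta_m * u * s4, p$m_max))
  expect_equal(M1[-4, ], M[-4, ])
  for (k in 1:200) M1 <- update_input_weights(M1, proto, p)
  expect_equal(max(M1[4, ]), p$m_max)
  # frozen identity M is a config error
  p0 <- small_params()
  expect_error(update_input_weights(diag(p0$n), proto, p0), "frozen")
})

test_that("weight bounds hold after every trial of a short run", {
  x <- run_experiment(small_preset(n_trials = 15), seed = 3)
  p <- x$params
  expect_true(all(x$state$W >= 0 & x$state$W <= p$w_max))
  expect_true(all(x$state$Q >= p$q_min & x$state$Q <= p$q_max))
})
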