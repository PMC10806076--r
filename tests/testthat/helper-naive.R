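# Independent reference implementation of one closed-loop trial, written as
# plain double loops over neurons and timesteps (no matrix algebra, no shared
# code with the package internals). Used as the oracle for the vectorized
# trial dynamics.
#
# Inputs are plain matrices/vectors; the caller supplies the per-step action
# noise, the policy draws and the reward coin so that no RNG state is shared
# with the implementation under test.
naive_trial <- function(params, U_by_turn, W, Q, Imat, beta, schedule,
                        noise, pol_draws, reward_u, task_variant) {
  n <- params$n
  n_steps <- as.integer(round(params$len / params$dx_dt))
  a <- numeric(n); s <- numeric(n); e <- numeric(n); ea <- numeric(n)
  v <- numeric(2)
  proto_W <- matrix(0, n, n)
  proto_Q <- matrix(0, 2, n)
  S <- matrix(0, n_steps, n)
  V <- matrix(0, n_steps, 2)
  turn <- NULL; was_random <- FALSE; winner <- NA; clamp <- 0L
  U <- U_by_turn$D
  for (ti in 1:n_steps) {
    t <- ti - 1L
    if (t == params$t_choice) {
      was_random <- pol_draws$u_rand < params$p_rand
      if (was_random) {
        winner <- if (pol_draws$u_dir < 0.5) 1L else 2L
      } else {
        best <- -Inf
        for (l in 1:2) {
          val <- v[l] + pol_draws$pol[l]
          if (val > best) { best <- val; winner <- l }
        }
      }
      turn <- c("D", "E")[winner]
      clamp <- params$clamp_steps
      U <- U_by_turn[[turn]]
    }
    # apical: integrates previous step's somatic activity
    for (i in 1:n) {
      drive <- 0
      for (j in 1:n) drive <- drive + W[i, j] * s[j]
      a[i] <- a[i] * (1 - 1 / params$tau_a) + drive
    }
    # basal (identity input weights) and soma
    s_new <- numeric(n)
    for (i in 1:n) {
      b <- U[ti, i]
      gate <- 0.5 * (tanh(params$m_a * (a[i] - params$c_a)) + 1)
      s_new[i] <- (1 - beta[i]) * b + beta[i] * b * gate
    }
    s <- s_new
    for (i in 1:n) {
      e[i] <- e[i] * (1 - 1 / params$tau_e) + s[i]
      ea[i] <- ea[i] * (1 - 1 / params$tau_ea) + s[i]
    }
    # plateau-filtered proto-weights
    for (k in seq_len(nrow(schedule))) {
      i <- schedule$neuron[k] + 1L
      if (abs(t - schedule$t_plateau[k]) <= params$plateau_halfwidth) {
        for (j in 1:n) proto_W[i, j] <- proto_W[i, j] + s[i] * e[j]
      }
    }
    # action neurons
    v_new <- numeric(2)
    for (l in 1:2) {
      drive <- noise[ti, l]
      for (i in 1:n) drive <- drive + Q[l, i] * s[i]
      for (m in 1:2) drive <- drive + Imat[l, m] * v[m]
      v_new[l] <- v[l] * (1 - 1 / params$tau_v) + drive
    }
    v <- v_new
    if (clamp > 0L) { v[winner] <- 1; clamp <- clamp - 1L }
    in_clamp <- !is.na(winner) && t >= params$t_choice &&
      t < params$t_choice + params$clamp_steps
    if (in_clamp) {
      for (l in 1:2) for (i in 1:n)
        proto_Q[l, i] <- proto_Q[l, i] + v[l] * ea[i]
    }
    S[ti, ] <- s
    V[ti, ] <- v
  }
  if (task_variant == "cue_dependent") {
    matched <- !is.null(attr(U_by_turn, "cue")) &&
      ((attr(U_by_turn, "cue") == "A" && turn == "D") ||
       (attr(U_by_turn, "cue") == "B" && turn == "E"))
    r <- if (matched && reward_u < 1) 1 else 0
  } else {
    r <- if (reward_u < 0.5) 1 else 0
  }
  # batch updates with clipping
  W2 <- W
  for (i in 1:n) for (j in 1:n) {
    w <- W[i, j] + params$eta_w * (r - params$r0) * proto_W[i, j] -
      params$lambda_w * W[i, j]
    W2[i, j] <- min(max(w, 0), params$w_max)
  }
  Q2 <- Q
  for (l in 1:2) for (i in 1:n) {
    q <- Q[l, i] + params$eta_q * (r - params$r_q) * proto_Q[l, i]
    Q2[l, i] <- min(max(q, params$q_min), params$q_max)
  }
  list(S = S, V = V, proto_W = proto_W, proto_Q = proto_Q,
       turn = turn, was_random = was_random, reward = r, W = W2, Q = Q2)
}

# Replays the RNG draws of a fresh context exactly as run_trial consumes
# them, so the oracle sees identical noise without touching the
# implementation's stream state.
replay_trial_draws <- function(params, seed, n_steps) {
  streams <- rng_streams(seed)
  rng_eval(streams, "init", {
    stats::runif(params$n * params$n, 0, 1e-4)
    stats::runif(1, 0, 1e-4)
  })
  noise <- rng_eval(streams, "noise",
                    matrix(stats::rnorm(n_steps * 2, 0, params$sigma_v),
                           n_steps, 2))
  pol <- rng_eval(streams, "policy",
                  list(u_rand = stats::runif(1), u_dir = stats::runif(1),
                       pol = stats::rnorm(2, 0, params$sigma_p)))
  reward_u <- rng_eval(streams, "task", stats::runif(1))
  list(noise = noise, pol = pol, reward_u = reward_u)
}
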