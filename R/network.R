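#' Sigmoidal activation used by the apical gate and the weight-sum modulation
#'
#' `gamma(x) = 0.5 * (tanh(m * (x - c)) + 1)`, a strictly increasing map of
#' the real line onto `(0, 1)`.
#'
#' @param x Input (vectorised).
#' @param m Stretch coefficient.
#' @param c Offset.
#' @return Values in `(0, 1)`.
#' @export
#' @examples
#' gamma_act(1.4, m = 5, c = 1.4)  # 0.5 at the offset
gamma_act <- function(x, m, c) {
  0.5 * (tanh(m * (x - c)) + 1)
}

#' Apical modulation factor beta
#'
#' `beta[i] = gamma(sum_j W[i, j]; m_beta, c_beta)`: the degree to which
#' neuron `i`'s soma listens to its apical (recurrent) compartment, a
#' saturating function of its total incoming recurrent weight. With `W = 0`
#' the soma is essentially a readout of basal (external) input.
#'
#' Recomputed only at trial boundaries: recurrent weights are updated in
#' batch at the end of each trial, so `beta` is constant within a trial.
#'
#' @param W `n x n` recurrent weight matrix (soma to apical dendrite).
#' @param params A [sim_params()] object.
#' @return Numeric vector of length `n`, entries in `(0, 1)`.
#' @export
compute_beta <- function(W, params) {
  gamma_act(rowSums(W), params$m_beta, params$c_beta)
}

#' Initial weight matrices
#'
#' Recurrent weights `W` start i.i.d. `U(0, 1e-4)`. The input matrix `M` is
#' the frozen identity unless input plasticity is enabled, in which case it
#' starts i.i.d. `U(0, 1e-4)` and is learned. Draws come from the `"init"`
#' RNG stream.
#'
#' @param params A [sim_params()] object.
#' @param streams An [rng_streams()] object.
#' @return List with elements `M`, `W`, and the flag `identity_M`.
#' @export
init_weights <- function(params, streams) {
  W <- rng_eval(streams, "init",
                matrix(stats::runif(params$n * params$n, 0, 1e-4),
                       params$n, params$n))
  if (!params$allow_self) diag(W) <- 0
  if (params$input_plasticity) {
    M <- rng_eval(streams, "init",
                  matrix(stats::runif(params$n * params$n_inp, 0, 1e-4),
                         params$n, params$n_inp))
    identity_M <- FALSE
  } else {
    if (params$n != params$n_inp)
      stop("identity input matrix requires n == n_inp")
    M <- diag(params$n)
    identity_M <- TRUE
  }
  list(M = M, W = W, identity_M = identity_M)
}

#' Fresh per-trial network state
#'
#' Dynamic variables (basal, apical, somatic activity, both eligibility
#' traces) start at zero each trial; `beta` is supplied from the current
#' recurrent weights. `input_mask` zeroes the basal drive of held-out
#' neurons and `s_mask` zeroes the somatic output of ablated neurons.
#'
#' @param params A [sim_params()] object.
#' @param beta Apical modulation vector (from [compute_beta()]).
#' @param input_mask,s_mask Optional 0/1 vectors of length `n`.
#' @return An environment of class `network_state` with fields `b`, `a`, `s`,
#'   `e`, `e_action`, `beta`, `input_mask`, `s_mask`.
#' @export
new_network_state <- function(params, beta = rep(gamma_act(0, params$m_beta, params$c_beta), params$n),
                              input_mask = rep(1, params$n),
                              s_mask = rep(1, params$n)) {
  st <- new.env(parent = emptyenv())
  z <- numeric(params$n)
  st$b <- z; st$a <- z; st$s <- z; st$e <- z; st$e_action <- z
  st$beta <- beta
  st$input_mask <- input_mask
  st$s_mask <- s_mask
  class(st) <- "network_state"
  st
}

#' One forward-Euler step of the three-compartment HPC network
#'
#' Update order within a step (`dt = 1`): the apical compartment integrates
#' the *previous* step's somatic activity through `W`; then basal activity is
#' read from the input; then the soma combines the two,
#' `s = (1 - beta) * b + beta * b * gamma_a(a)`; finally both eligibility
#' traces integrate the new somatic activity. The apical, eligibility and
#' action-eligibility variables are leaky integrators
#' `x <- x * (1 - dt/tau) + dt * drive`, whose fixed point under constant
#' drive is `tau * drive`.
#'
#' @param state A [new_network_state()] environment (mutated in place).
#' @param weights Weight list from [init_weights()].
#' @param u External input vector (length `n_inp`).
#' @param params A [sim_params()] object.
#' @return The state, invisibly. Aborts with a diagnostic if any dynamic
#'   variable becomes non-finite.
#' @export
step_network <- function(state, weights, u, params) {
  a <- state$a * (1 - 1 / params$tau_a) + as.vector(weights$W %*% state$s)
  b <- if (weights$identity_M) u else as.vector(weights$M %*% u)
  b <- b * state$input_mask
  s <- ((1 - state$beta) + state$beta * gamma_act(a, params$m_a, params$c_a)) * b
  s <- s * state$s_mask
  e <- state$e * (1 - 1 / params$tau_e) + s
  e_action <- state$e_action * (1 - 1 / params$tau_ea) + s
  if (!all(is.finite(a)) || !all(is.finite(s)))
    stop("non-finite network state encountered (|a| max = ",
         max(abs(a)), "); aborting run", call. = FALSE)
  state$a <- a; state$b <- b; state$s <- s
  state$e <- e; state$e_action <- e_action
  invisible(state)
}

#' Plateau induction schedule for one trial
#'
#' Even-id neurons receive a plateau on cue-A trials, odd-id neurons on
#' cue-B trials, each at its own plateau time `t_plateau[i]` (by default
#' equal to the neuron id, so plateau position matches the matching input's
#' tuning centre). Held-out neurons are excluded until released.
#'
#' @param cue `"A"` or `"B"`.
#' @param params A [sim_params()] object.
#' @param holdouts Integer vector of 0-based neuron ids to exclude.
#' @return Data frame of class `plateau_schedule` with columns `neuron`
#'   (0-based id) and `t_plateau`.
#' @export
#' @examples
#' sched <- make_induction_schedule("B", sim_params())
#' head(sched)  # odd neurons, plateau time = id
make_induction_schedule <- function(cue, params, holdouts = integer(0)) {
  ids <- seq_len(params$n) - 1L
  want <- if (cue == "A") ids %% 2L == 0L else ids %% 2L == 1L
  want[ids %in% holdouts] <- FALSE
  sched <- data.frame(neuron = ids[want], t_plateau = params$t_plateau[want])
  class(sched) <- c("plateau_schedule", "data.frame")
  sched
}

#' Plateau pass-filter
#'
#' `phi[i](t) = s[i](t)` when neuron `i` is scheduled this trial and `t` lies
#' within `plateau_halfwidth` timesteps of its plateau time, else 0. The
#' plateau gates which somatic activity enters the proto-weights.
#'
#' @param s Somatic activity vector.
#' @param schedule A [make_induction_schedule()] schedule.
#' @param t Current timestep (0-based).
#' @param params A [sim_params()] object.
#' @return Vector `phi` of length `n`.
#' @export
plateau_filter <- function(s, schedule, t, params) {
  phi <- numeric(length(s))
  if (nrow(schedule) == 0) return(phi)
  hit <- abs(t - schedule$t_plateau) <= params$plateau_halfwidth
  idx <- schedule$neuron[hit] + 1L
  phi[idx] <- s[idx]
  phi
}

# Precompute, for each timestep of a trial, the 1-based indices of neurons
# whose plateau window covers that step. Avoids re-scanning the schedule in
# the inner loop.
schedule_windows <- function(schedule, params, n_steps) {
  win <- vector("list", n_steps)
  for (ti in seq_len(n_steps)) {
    t <- ti - 1L
    hit <- abs(t - schedule$t_plateau) <= params$plateau_halfwidth
    win[[ti]] <- schedule$neuron[hit] + 1L
  }
  win
}

#' Accumulate proto-weights for one timestep
#'
#' Adds the outer product `phi(t) e(t)^T * dt` to the within-trial
#' accumulator. The accumulated integral is turned into a weight change only
#' at the end of the trial, once reward is delivered or omitted.
#'
#' @param proto_W `n x n` accumulator (zeroed at trial start).
#' @param phi Plateau-filtered somatic activity ([plateau_filter()]).
#' @param e Presynaptic eligibility vector.
#' @return Updated accumulator.
#' @export
accumulate_proto_weights <- function(proto_W, phi, e) {
  idx <- which(phi != 0)
  if (length(idx))
    proto_W[idx, ] <- proto_W[idx, ] + tcrossprod(phi[idx], e)
  proto_W
}

#' Batch update of the recurrent weights (end of trial)
#'
#' Three-factor rule: `W <- clip(W + eta_W * (r - r0) * proto_W -
#' lambda_w * W, 0, W_max)`. At baseline reward (`r = r0`) the update is pure
#' multiplicative decay; rewarded trials potentiate the plateau-tagged
#' state pairs and unrewarded trials depress them. Rows listed in
#' `freeze_rows` are pinned at zero (used by the pruning perturbation).
#'
#' @param W Current recurrent weights.
#' @param proto_W Accumulated proto-weights for the trial.
#' @param r Trial reward (0 or 1).
#' @param params A [sim_params()] object.
#' @param freeze_rows Optional 0-based neuron ids whose incoming weights are
#'   clamped at zero.
#' @return Updated weight matrix.
#' @export
update_recurrent_weights <- function(W, proto_W, r, params,
                                     freeze_rows = integer(0)) {
  W2 <- W + params$eta_w * (r - params$r0) * proto_W - params$lambda_w * W
  W2[W2 < 0] <- 0
  W2[W2 > params$w_max] <- params$w_max
  if (!params$allow_self) diag(W2) <- 0
  if (length(freeze_rows)) W2[freeze_rows + 1L, ] <- 0
  W2
}

#' Batch update of the input weights (plastic-input experiments only)
#'
#' `M <- clip(M + eta_M * proto_M, 0, M_max)` with
#' `proto_M[i, k] = integral of u_k(t) * phi[s_i(t)] dt` over the trial:
#' plateau-gated Hebbian coactivation of input channel and neuron. Calling
#' this while `M` is the frozen identity is a configuration error.
#'
#' @param M Current input weight matrix (`n x n_inp`).
#' @param proto_M Accumulated input proto-weights for the trial.
#' @param params A [sim_params()] object.
#' @return Updated input weight matrix.
#' @export
update_input_weights <- function(M, proto_M, params) {
  if (!params$input_plasticity)
    stop("input weights are frozen (identity); enable input_plasticity",
         call. = FALSE)
  M2 <- M + params$eta_m * proto_M
  M2[M2 < 0] <- 0
  M2[M2 > params$m_max] <- params$m_max
  M2
}
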