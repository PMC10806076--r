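#' Fresh action-network state
#'
#' Two mutually inhibiting action neurons (left = turn to port D, right =
#' port E). State-action weights `Q` are initialised to a single value drawn
#' once from `U(0, 1e-4)` and assigned to every entry (all initial values the
#' same; symmetry is broken by noise, not by initialisation). The inhibition
#' matrix `I` is fixed with off-diagonal -0.125.
#'
#' @param params A [sim_params()] object.
#' @param streams An [rng_streams()] object (uses the `"init"` stream).
#' @return List of class `action_state` with `Q` (`2 x n`), `I` (`2 x 2`),
#'   and helpers.
#' @export
new_action_weights <- function(params, streams) {
  q0 <- rng_eval(streams, "init", stats::runif(1, 0, 1e-4))
  Q <- matrix(q0, params$n_act, params$n)
  I <- matrix(c(0, -0.125, -0.125, 0), 2, 2)
  structure(list(Q = Q, I = I), class = "action_weights")
}

#' Per-trial action-neuron state
#'
#' Activities start at zero each trial; the clamp counter tracks the
#' post-choice fixation of the winning neuron.
#'
#' @param params A [sim_params()] object.
#' @return Environment of class `action_state` with fields `v`,
#'   `clamp_counter`, `winner`.
#' @export
new_action_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$v <- numeric(params$n_act)
  st$clamp_counter <- 0L
  st$winner <- NA_integer_
  class(st) <- "action_state"
  st
}

#' One Euler step of the action neurons
#'
#' Leaky integration `v <- v * (1 - dt/tau_v) + dt * (Q s + I v + noise)`
#' with fresh Gaussian noise of s.d. `sigma_v` per neuron per step.
#' Feedforward drive `Q s` and noise integrate at full strength, the same
#' convention as the apical compartment and the eligibility traces. The
#' fixed mutual inhibition `I` (off-diagonal -0.125) makes the difference
#' between the two units an unstable competition mode: the action network
#' has winner-take-all dynamics, and small accumulated asymmetries grow
#' toward the choice point (see `inhibition_timescale` in [sim_params()]
#' for the alternative stable reading). While the post-choice clamp is
#' active the winning neuron is held at exactly 1 (the loser keeps
#' evolving) and the counter is decremented.
#'
#' @param act A [new_action_state()] environment (mutated in place).
#' @param aw Action weights from [new_action_weights()].
#' @param s Current somatic activity vector of the HPC network.
#' @param params A [sim_params()] object.
#' @param noise Gaussian noise vector (length 2) for this step.
#' @return The state, invisibly.
#' @export
step_action <- function(act, aw, s, params, noise) {
  i_scale <- if (params$inhibition_timescale == "tau_v") params$tau_v else 1
  drive <- as.vector(aw$Q %*% s) +
    as.vector(aw$I %*% act$v) / i_scale + noise
  v <- act$v * (1 - 1 / params$tau_v) + drive
  if (params$rectify_v) v <- pmax(v, 0)
  if (act$clamp_counter > 0L) {
    v[act$winner] <- 1
    act$clamp_counter <- act$clamp_counter - 1L
  }
  act$v <- v
  invisible(act)
}

#' Select the turn at the choice point
#'
#' With probability `p_rand` the turn is a fair coin flip and the action
#' network is not consulted; otherwise the turn is the argmax of `v` plus
#' independent Gaussian policy noise (s.d. `sigma_p`) per neuron. Ties are
#' broken toward the left port (measure-zero event under Gaussian noise).
#' Selecting starts the post-choice clamp of the winner. When
#' `forced_chance` is set (behavior-reset perturbation) every turn is a coin
#' flip flagged as random.
#'
#' All three policy draws (random-turn coin, direction coin, policy noise)
#' are consumed every trial so the `"policy"` stream stays aligned whether or
#' not the turn was random.
#'
#' @param act A [new_action_state()] environment.
#' @param params A [sim_params()] object.
#' @param streams An [rng_streams()] object.
#' @param forced_chance Logical; bypass the action readout entirely.
#' @return List of class `turn_choice`: `direction` (`"D"` or `"E"`),
#'   `was_random`, `winner` (1 = D/left, 2 = E/right).
#' @export
select_turn <- function(act, params, streams, forced_chance = FALSE) {
  draws <- rng_eval(streams, "policy",
                    list(u_rand = stats::runif(1),
                         u_dir = stats::runif(1),
                         pol = stats::rnorm(params$n_act, 0, params$sigma_p)))
  random_turn <- forced_chance || draws$u_rand < params$p_rand
  if (random_turn) {
    winner <- if (draws$u_dir < 0.5) 1L else 2L
  } else {
    winner <- which.max(act$v + draws$pol)
  }
  act$winner <- winner
  act$clamp_counter <- params$clamp_steps
  structure(list(direction = c("D", "E")[winner],
                 was_random = random_turn, winner = winner),
            class = "turn_choice")
}

#' Batch update of the state-action weights (end of trial)
#'
#' Three-factor rule without decay:
#' `Q <- clip(Q + eta_Q * (r - r_q) * proto_Q, Q_min, Q_max)` with
#' `proto_Q[l, i] = integral of v_l(t) * e_action_i(t) dt` accumulated over
#' the trial. The baseline `r_q = 0.6` exceeds the chance reward rate, so
#' at-chance policies are on average depressed; only representations that
#' support above-baseline reward are reinforced.
#'
#' @param aw Action weights from [new_action_weights()].
#' @param proto_Q `2 x n` accumulated activity/eligibility products.
#' @param r Trial reward.
#' @param params A [sim_params()] object.
#' @return Updated action weights.
#' @export
update_action_weights <- function(aw, proto_Q, r, params) {
  Q2 <- aw$Q + params$eta_q * (r - params$r_q) * proto_Q
  Q2[Q2 < params$q_min] <- params$q_min
  Q2[Q2 > params$q_max] <- params$q_max
  if (!all(is.finite(Q2)))
    stop("non-finite action weights; aborting run", call. = FALSE)
  aw$Q <- Q2
  aw
}
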