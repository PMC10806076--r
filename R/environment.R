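#' Build the bank of positional tuning curves
#'
#' Lays out the external input channels over the maze. Channels are Gaussian
#' positional tuning curves `u_k(x) = exp(-((x - x_k)/sigma)^2)` gated by
#' their role:
#'
#' * cue-zone channels (ids `[0, cue_hi)`) are split into an A-dedicated
#'   (even ids) and a B-dedicated (odd ids) half, driven only while the agent
#'   is in the cue zone and only when their cue is the one shown;
#' * stem channels (ids `[cue_hi, stem_hi)`) are purely positional and
#'   cue-agnostic;
#' * branch channels (ids `[stem_hi, len)`) are split into a D-dedicated
#'   (even) and an E-dedicated (odd) half, driven only on the taken branch;
#' * any remaining ids are dormant reserve channels, used as the novel input
#'   lines in the cue/port remapping experiment.
#'
#' Channel ids are 0-based so that, with the identity input matrix, channel
#' id = neuron id = plateau time = tuning-curve centre.
#'
#' @param params A [sim_params()] object.
#' @param geometry A [maze_geometry()] object (defaults to the one implied by
#'   `params`).
#' @return An object of class `tuning_bank`: a data frame with columns `id`,
#'   `center`, `role`, plus attributes `sigma` and `geometry`.
#' @export
#' @examples
#' bank <- build_tuning_curves(sim_params())
#' table(bank$role)
build_tuning_curves <- function(params, geometry = maze_geometry(params)) {
  if (params$sigma_in <= 0) stop("sigma_in must be > 0")
  len <- as.integer(round(geometry$track_length))
  if (params$n_inp < len)
    stop("n_inp must be at least the number of encoded track positions")
  id <- seq_len(params$n_inp) - 1L
  center <- rep(NA_real_, params$n_inp)
  role <- rep("reserve", params$n_inp)
  cue_hi <- as.integer(geometry$cue_zone[2])
  stem_hi <- as.integer(geometry$stem[2])
  on_track <- id < len
  center[on_track] <- id[on_track]
  in_cue <- id < cue_hi
  in_stem <- id >= cue_hi & id < stem_hi
  in_branch <- id >= stem_hi & id < len
  role[in_cue] <- ifelse(id[in_cue] %% 2L == 0L, "cue_A", "cue_B")
  role[in_stem] <- "stem"
  role[in_branch] <- ifelse(id[in_branch] %% 2L == 0L, "branch_D", "branch_E")
  bank <- data.frame(id = id, center = center, role = role,
                     stringsAsFactors = FALSE)
  attr(bank, "sigma") <- params$sigma_in
  attr(bank, "geometry") <- geometry
  class(bank) <- c("tuning_bank", "data.frame")
  validate_tuning_bank(bank)
  bank
}

validate_tuning_bank <- function(bank) {
  sigma <- attr(bank, "sigma")
  if (is.null(sigma) || sigma <= 0) stop("tuning bank: sigma must be > 0")
  for (r in setdiff(unique(bank$role), "reserve")) {
    ctr <- bank$center[bank$role == r]
    if (anyNA(ctr) || any(diff(ctr) <= 0))
      stop("tuning bank: centers must be strictly increasing within role ", r)
  }
  invisible(bank)
}

#' Evaluate one tuning curve
#'
#' The raw (ungated) Gaussian `exp(-((x - center)/sigma)^2)`.
#'
#' @param bank A [build_tuning_curves()] bank.
#' @param k Channel id (0-based).
#' @param x Position(s).
#' @return Activity in `[0, 1]`.
#' @export
tuning_curve <- function(bank, k, x) {
  ctr <- bank$center[match(k, bank$id)]
  exp(-((x - ctr) / attr(bank, "sigma"))^2)
}

channel_gate <- function(bank, x, cue, turn) {
  g <- attr(bank, "geometry")
  switch_gate <- function(role) {
    switch(role,
      cue_A    = (cue == "A") && x >= g$cue_zone[1] && x < g$cue_zone[2],
      cue_B    = (cue == "B") && x >= g$cue_zone[1] && x < g$cue_zone[2],
      stem     = TRUE,
      branch_D = !is.null(turn) && turn == "D" && x >= g$branch[1] && x < g$branch[2],
      branch_E = !is.null(turn) && turn == "E" && x >= g$branch[1] && x < g$branch[2],
      reserve  = FALSE,
      FALSE)
  }
  vapply(bank$role, switch_gate, logical(1), USE.NAMES = FALSE)
}

#' External input vector
#'
#' Input activity of every channel for an agent at position `x` having seen
#' `cue`, with turn `turn` (or `NULL` before the choice). Channels dedicated
#' to the non-shown cue, to the unvisited branch, or dormant reserve channels
#' are exactly zero; stem channels depend on position only.
#'
#' @param bank A [build_tuning_curves()] bank.
#' @param x Agent position (scalar).
#' @param cue `"A"` or `"B"`.
#' @param turn `"D"`, `"E"`, or `NULL` before the choice point.
#' @return Numeric vector of length `n_inp`, entries in `[0, 1]`.
#' @export
external_input <- function(bank, x, cue, turn = NULL) {
  u <- exp(-((x - bank$center) / attr(bank, "sigma"))^2)
  u[is.na(u)] <- 0
  u * channel_gate(bank, x, cue, turn)
}

#' Precompute the input matrix for a whole trial
#'
#' Rows are timesteps `t = 0, ..., n_steps - 1` (position `x = t * dx_dt`),
#' columns are channels. Used by the trial loop; equals stacking
#' [external_input()] over the trial.
#'
#' @inheritParams external_input
#' @param params A [sim_params()] object.
#' @return `n_steps x n_inp` matrix.
#' @keywords internal
input_matrix <- function(bank, cue, turn, params) {
  g <- attr(bank, "geometry")
  tt <- seq_len(g$n_steps) - 1L
  x <- tt * params$dx_dt
  U <- exp(-outer(x, bank$center, function(a, b) ((a - b) / attr(bank, "sigma"))^2))
  U[, is.na(bank$center)] <- 0
  gate <- matrix(1, nrow = length(x), ncol = nrow(bank))
  in_cue <- x >= g$cue_zone[1] & x < g$cue_zone[2]
  in_branch <- x >= g$branch[1] & x < g$branch[2]
  gate[, bank$role == "cue_A"] <- as.numeric(in_cue & cue == "A")
  gate[, bank$role == "cue_B"] <- as.numeric(in_cue & cue == "B")
  gate[, bank$role == "branch_D"] <- as.numeric(in_branch & identical(turn, "D"))
  gate[, bank$role == "branch_E"] <- as.numeric(in_branch & identical(turn, "E"))
  gate[, bank$role == "reserve"] <- 0
  U * gate
}

#' Task specification
#'
#' @param variant `"cue_dependent"` (reward at D after cue A, at E after cue
#'   B, with certainty) or `"random_reward"` (reward with probability 0.5 at
#'   either port, regardless of cue).
#' @param reward_prob_matched Probability of reward on a matched (cue A to D /
#'   cue B to E) turn in the cue-dependent task.
#' @param reward_prob_random Per-trial reward probability in the
#'   random-reward task.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(variant = c("cue_dependent", "random_reward"),
                      reward_prob_matched = 1.0,
                      reward_prob_random = 0.5) {
  variant <- match.arg(variant)
  stopifnot(reward_prob_matched >= 0, reward_prob_matched <= 1,
            reward_prob_random >= 0, reward_prob_random <= 1)
  structure(list(variant = variant,
                 reward_prob_matched = reward_prob_matched,
                 reward_prob_random = reward_prob_random),
            class = "task_spec")
}

#' Sample the trial's cue
#'
#' Fair independent draw of `"A"` or `"B"` from the supplied RNG stream.
#'
#' @param streams An RNG stream set from [rng_streams()].
#' @param task A [task_spec()] (cues are equiprobable in both variants).
#' @return `"A"` or `"B"`.
#' @export
sample_cue <- function(streams, task) {
  u <- rng_eval(streams, "cue", stats::runif(1))
  if (u < 0.5) "A" else "B"
}

#' Deliver (or omit) reward at the end of a trial
#'
#' Cue-dependent task: reward 1 iff the turn matches the cue (A to D, B to
#' E), else 0. Random-reward task: reward 1 with probability 0.5 regardless
#' of cue and turn. A reward coin is drawn every trial in both variants so
#' that the RNG stream stays aligned across task variants.
#'
#' @param task A [task_spec()].
#' @param cue `"A"` or `"B"`.
#' @param turn `"D"` or `"E"`.
#' @param streams An RNG stream set from [rng_streams()].
#' @return Reward scalar, 1 (delivered) or 0 (omitted).
#' @export
deliver_reward <- function(task, cue, turn, streams) {
  u <- rng_eval(streams, "task", stats::runif(1))
  if (task$variant == "cue_dependent") {
    matched <- (cue == "A" && turn == "D") || (cue == "B" && turn == "E")
    if (matched && u < task$reward_prob_matched) 1 else 0
  } else {
    if (u < task$reward_prob_random) 1 else 0
  }
}

#' Agent state
#'
#' The agent runs at constant velocity, so position is `time * dx_dt`.
#'
#' @param time Timestep (0-based).
#' @param params A [sim_params()] object.
#' @param geometry A [maze_geometry()] object.
#' @param turn `"D"`, `"E"` or `NULL` (unset before the choice point).
#' @return An object of class `agent_state` with fields `time`, `position`,
#'   `segment`, `turn`.
#' @export
agent_state <- function(time, params, geometry = maze_geometry(params),
                        turn = NULL) {
  if (time >= geometry$t_choice && is.null(turn))
    stop("turn must be set at or after the choice time")
  if (time < geometry$t_choice && !is.null(turn))
    stop("turn cannot be set before the choice time")
  x <- time * params$dx_dt
  structure(list(time = as.integer(time), position = x,
                 segment = maze_segment(x, geometry, turn), turn = turn),
            class = "agent_state")
}

#' Advance the agent by one timestep
#'
#' Increments time by one step and position by `dx_dt`. Stepping from
#' `t_choice - 1` requires a turn decision (supply `turn`); stepping past the
#' end of the track returns an end-of-trial sentinel.
#'
#' @param agent An [agent_state()].
#' @param params A [sim_params()] object.
#' @param geometry A [maze_geometry()] object.
#' @param turn The turn decision, required when crossing the choice point.
#' @return The next `agent_state`, or a list with `end_of_trial = TRUE` (the
#'   agent is teleported back to the start for the next trial).
#' @export
advance_agent <- function(agent, params, geometry = maze_geometry(params),
                          turn = agent$turn) {
  t_next <- agent$time + 1L
  if (t_next * params$dx_dt >= geometry$track_length)
    return(structure(list(end_of_trial = TRUE), class = "agent_state"))
  if (t_next >= geometry$t_choice && is.null(turn))
    stop("advancing past the choice point requires a turn decision")
  agent_state(t_next, params, geometry,
              turn = if (t_next >= geometry$t_choice) turn else NULL)
}
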