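#' Model parameters
#'
#' Constructs the full parameter set for a simulation run. Defaults are the
#' reference values of the splitter-cell Y-maze model: 120 input
#' channels and 120 hippocampal (HPC) neurons, unit running velocity, a
#' 100-position track, and the learning rates, time constants, noise scales
#' and weight bounds of the reference parameter table. All times are in units
#' of the Euler step `dt = 1`; all positions in track units.
#'
#' @param n_inp Number of external input channels.
#' @param n Number of HPC neurons.
#' @param n_act Number of action neurons (left/right).
#' @param dx_dt Agent velocity (positions per timestep).
#' @param len Track length `L`; a trial lasts `len / dx_dt` timesteps.
#' @param sigma_in Width of the Gaussian positional tuning curves.
#' @param tau_e,tau_ea Time constants of the recurrent-plasticity and
#'   action-plasticity eligibility traces.
#' @param tau_a,tau_v Time constants of the apical compartment and the action
#'   neurons.
#' @param sigma_v Standard deviation of the per-timestep Gaussian noise
#'   injected into the action neurons.
#' @param sigma_p Standard deviation of the Gaussian policy noise added to
#'   each action neuron's activity at the choice point.
#' @param m_a,c_a Stretch and offset of the apical activation nonlinearity
#'   `gamma_a`.
#' @param m_beta,c_beta Stretch and offset of the weight-sum nonlinearity
#'   `gamma_beta` that sets the apical modulation factor.
#' @param t_choice Timestep at which the action network is queried for the
#'   turn.
#' @param p_rand Probability that a trial's turn is taken at random without
#'   querying the action network.
#' @param n_trials Default number of trials in an experiment.
#' @param r0,r_q Reward baselines of the recurrent and action learning rules.
#' @param t_plateau Integer vector of per-neuron plateau timesteps; defaults
#'   to `t_plateau[i] = i` (0-based neuron ids).
#' @param m_max,w_max Upper bounds of the input and recurrent weights.
#' @param q_min,q_max Bounds of the state-action weights.
#' @param eta_w,eta_q,eta_m Learning rates of the recurrent, state-action and
#'   input weights.
#' @param lambda_w Multiplicative per-trial decay of the recurrent weights.
#' @param cue_zone,stem,branch Half-open position intervals `[lo, hi)` of the
#'   cue zone, the central stem (segment C) and the two reward branches
#'   (D/E). Must be disjoint, ordered, and cover `[0, len)`, with the
#'   stem/branch boundary at `t_choice * dx_dt`.
#' @param plateau_halfwidth Half-width (timesteps) of the plateau window
#'   around `t_plateau` during which the plateau filter passes somatic
#'   activity into the proto-weights. Use `Inf` for a whole-trial window or
#'   `0` for a single timestep.
#' @param clamp_steps Number of timesteps the selected action neuron is
#'   clamped to 1 after the turn.
#' @param inhibition_timescale `"step"` (default) applies the fixed mutual
#'   inhibition `I` at full strength each step, making the difference between
#'   the two action neurons an unstable competition mode (winner-take-all):
#'   small asymmetries in the accumulated state input are amplified toward
#'   the choice point. `"tau_v"` instead applies `I` on the action time
#'   constant (per-step coefficient `0.125/tau_v`), giving a stable,
#'   recency-weighted evidence accumulator.
#' @param credit_rectify Logical (default `FALSE`): rectify the action
#'   activity (`max(v, 0)`) entering the state-action credit, so that
#'   sub-threshold activity generates no credit. With the default, the raw
#'   (signed) activity enters the learning rule, so a
#'   suppressed loser actively unlearns.
#' @param rectify_v Logical (default `FALSE`): additionally rectify the
#'   action-neuron state at zero each step. The default keeps the internal
#'   dynamics linear so that differences between the two units remain
#'   expressed at any state-action weight level; rectification is applied to
#'   the *credit* (see below) rather than the state.
#' @param action_credit_window Which timesteps contribute the
#'   activity/eligibility products of the state-action update: `"choice"`
#'   (default) accumulates only during the post-choice clamp window, so the
#'   three-factor credit is evaluated at the commitment event, mirroring the
#'   plateau gating of the recurrent rule; `"trial"` accumulates every step;
#'   `"free"` accumulates every step except the clamped winner's.
#' @param allow_self Logical; keep recurrent self-connections `W[i,i]`
#'   plastic (`TRUE`, default) or pin them at zero.
#' @param input_plasticity Logical; if `TRUE` the input weight matrix `M` is
#'   initialised `U(0, 1e-4)` and learned by plateau/input coactivation;
#'   otherwise `M` is the frozen identity.
#' @param splitness_window Trailing window (trials) of the splitness running
#'   mean.
#' @param split_threshold Fraction of a neuron's peak in-field rate that
#'   `|splitness|` must exceed to count as split.
#' @param split_persist Number of consecutive evaluable trials the split
#'   criterion must hold to fix a split onset.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [maze_geometry()], [experiment_preset()], [run_experiment()]
#' @export
#' @examples
#' p <- sim_params()
#' p$w_max
#' small <- sim_params(n_trials = 200)
sim_params <- function(n_inp = 120L,
                       n = 120L,
                       n_act = 2L,
                       dx_dt = 1,
                       len = 100,
                       sigma_in = 5,
                       tau_e = 10,
                       tau_ea = 20,
                       tau_a = 40,
                       tau_v = 10,
                       sigma_v = 0.75,
                       sigma_p = 5,
                       m_a = 1,
                       c_a = 5,
                       m_beta = 5,
                       c_beta = 1.4,
                       t_choice = 60L,
                       p_rand = 0.1,
                       n_trials = 4000L,
                       r0 = 0.5,
                       r_q = 0.6,
                       t_plateau = NULL,
                       m_max = 0.75,
                       w_max = 0.15,
                       q_min = -0.15,
                       q_max = 0.15,
                       eta_w = 6e-4,
                       eta_q = 3e-4,
                       eta_m = 0.15,
                       lambda_w = 0.025,
                       cue_zone = c(0, 20),
                       stem = c(20, 60),
                       branch = c(60, 100),
                       plateau_halfwidth = 10,
                       clamp_steps = 10L,
                       action_credit_window = c("choice", "trial", "free"),
                       inhibition_timescale = c("step", "tau_v"),
                       rectify_v = FALSE,
                       credit_rectify = FALSE,
                       allow_self = TRUE,
                       input_plasticity = FALSE,
                       splitness_window = 100L,
                       split_threshold = 0.5,
                       split_persist = 50L) {
  if (is.null(t_plateau)) t_plateau <- seq_len(n) - 1L
  p <- list(
    n_inp = as.integer(n_inp), n = as.integer(n), n_act = as.integer(n_act),
    dx_dt = dx_dt, len = len, sigma_in = sigma_in,
    tau_e = tau_e, tau_ea = tau_ea, tau_a = tau_a, tau_v = tau_v,
    sigma_v = sigma_v, sigma_p = sigma_p,
    m_a = m_a, c_a = c_a, m_beta = m_beta, c_beta = c_beta,
    t_choice = as.integer(t_choice), p_rand = p_rand,
    n_trials = as.integer(n_trials), r0 = r0, r_q = r_q,
    t_plateau = as.numeric(t_plateau),
    m_max = m_max, w_max = w_max, q_min = q_min, q_max = q_max,
    eta_w = eta_w, eta_q = eta_q, eta_m = eta_m, lambda_w = lambda_w,
    cue_zone = as.numeric(cue_zone), stem = as.numeric(stem),
    branch = as.numeric(branch),
    plateau_halfwidth = plateau_halfwidth, clamp_steps = as.integer(clamp_steps),
    action_credit_window = match.arg(action_credit_window,
                                     c("choice", "trial", "free")),
    inhibition_timescale = match.arg(inhibition_timescale, c("step", "tau_v")),
    rectify_v = isTRUE(rectify_v),
    credit_rectify = isTRUE(credit_rectify),
    allow_self = isTRUE(allow_self),
    input_plasticity = isTRUE(input_plasticity),
    splitness_window = as.integer(splitness_window),
    split_threshold = split_threshold,
    split_persist = as.integer(split_persist)
  )
  class(p) <- "sim_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of time constants and widths, ordering of weight bounds,
#' probability ranges, plateau-vector length and geometry consistency.
#' Called by [sim_params()]; exported so configurations loaded from file can
#' be re-validated.
#'
#' @param p A `sim_params` object.
#' @return `p`, invisibly, or an error describing the offending field.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  chk <- function(ok, msg) if (!ok) stop("invalid parameters: ", msg, call. = FALSE)
  chk(p$n_inp >= 1 && p$n >= 1 && p$n_act == 2L, "counts (n_inp, n >= 1, n_act == 2)")
  chk(p$sigma_in > 0, "sigma_in must be > 0")
  for (f in c("tau_e", "tau_ea", "tau_a", "tau_v"))
    chk(p[[f]] > 0, paste(f, "must be > 0"))
  chk(p$sigma_v >= 0 && p$sigma_p >= 0, "noise scales must be >= 0")
  chk(p$p_rand >= 0 && p$p_rand <= 1, "p_rand in [0, 1]")
  chk(p$q_min < p$q_max, "q_min < q_max")
  chk(p$w_max > 0 && p$m_max > 0, "w_max, m_max > 0")
  chk(p$lambda_w >= 0 && p$lambda_w < 1, "lambda_w in [0, 1)")
  chk(length(p$t_plateau) == p$n, "t_plateau must have length n")
  chk(p$n_trials >= 1, "n_trials >= 1")
  chk(p$dx_dt > 0 && p$len > 0, "dx_dt, len > 0")
  chk(p$plateau_halfwidth >= 0, "plateau_halfwidth >= 0")
  chk(p$splitness_window >= 1 && p$split_persist >= 1, "analysis windows >= 1")
  chk(p$split_threshold > 0 && p$split_threshold <= 1, "split_threshold in (0, 1]")
  # geometry: disjoint ordered intervals covering [0, len), choice at boundary
  g <- rbind(p$cue_zone, p$stem, p$branch)
  chk(all(g[, 2] > g[, 1]), "geometry intervals must be non-empty")
  chk(g[1, 1] == 0 && all(g[-1, 1] == g[-3, 2]) && g[3, 2] == p$len,
      "cue_zone, stem, branch must be ordered, disjoint and cover [0, len)")
  chk(isTRUE(all.equal(p$stem[2], p$t_choice * p$dx_dt)),
      "t_choice must map to the stem/branch boundary under the agent velocity")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Splitter-cell model parameters\n")
  cat(sprintf("  network : %d inputs -> %d HPC neurons -> %d action neurons\n",
              x$n_inp, x$n, x$n_act))
  cat(sprintf("  maze    : L = %g, cue [%g,%g), stem [%g,%g), branch [%g,%g), choice at t = %d\n",
              x$len, x$cue_zone[1], x$cue_zone[2], x$stem[1], x$stem[2],
              x$branch[1], x$branch[2], x$t_choice))
  cat(sprintf("  learning: eta_W = %g, eta_Q = %g, lambda_w = %g, W_max = %g, Q in [%g, %g]\n",
              x$eta_w, x$eta_q, x$lambda_w, x$w_max, x$q_min, x$q_max))
  cat(sprintf("  trials  : %d (p_rand = %g, r0 = %g, r_q = %g)\n",
              x$n_trials, x$p_rand, x$r0, x$r_q))
  if (x$input_plasticity) cat("  input weights plastic (eta_M =", x$eta_m, ")\n")
  invisible(x)
}

#' Maze geometry
#'
#' Extracts the Y-maze geometry implied by a parameter set: the half-open
#' cue-zone / stem / branch intervals, the track length, the trial length in
#' timesteps, and the choice time.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `maze_geometry`.
#' @export
maze_geometry <- function(params) {
  g <- list(
    track_length = params$len,
    cue_zone = params$cue_zone,
    stem = params$stem,
    branch = params$branch,
    t_choice = params$t_choice,
    n_steps = as.integer(round(params$len / params$dx_dt))
  )
  class(g) <- "maze_geometry"
  g
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat(sprintf("Y-maze: length %g | cue [%g,%g) | stem [%g,%g) | branch [%g,%g) | turn at t = %d (%d steps/trial)\n",
              x$track_length, x$cue_zone[1], x$cue_zone[2], x$stem[1], x$stem[2],
              x$branch[1], x$branch[2], x$t_choice, x$n_steps))
  invisible(x)
}

#' Which maze segment contains a position
#'
#' @param x Position (scalar or vector).
#' @param geometry A [maze_geometry()] object.
#' @param turn Optional turn ("D" or "E"); distinguishes the two branches.
#' @return Character vector among `"cue_zone"`, `"stem"`, `"branch_D"`,
#'   `"branch_E"`, `"branch"` (turn unknown).
#' @export
maze_segment <- function(x, geometry, turn = NULL) {
  seg <- ifelse(x < geometry$cue_zone[2], "cue_zone",
                ifelse(x < geometry$stem[2], "stem", "branch"))
  if (!is.null(turn)) seg[seg == "branch"] <- paste0("branch_", turn)
  seg
}
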