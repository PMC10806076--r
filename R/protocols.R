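#' Perturbation specification
#'
#' @param kind One of `"behavior_reset"` (turns forced to a fair coin from
#'   this trial on, learning continues), `"prune_B_splitters"` (incoming
#'   recurrent weights of B-preferring splitters set to zero),
#'   `"ablate_general"` / `"ablate_specific"` (somatic output of a random
#'   fraction of all / of B-type splitters clamped to zero permanently), or
#'   `"novel_cue_and_port"` (one cue's and one port's input channels are
#'   swapped to previously unused channels; requires input plasticity).
#' @param trial 1-based trial index before which the perturbation is applied.
#' @param fraction Fraction of the eligible splitter set to ablate.
#' @param freeze For pruning: keep the pruned rows clamped at zero.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("behavior_reset", "prune_B_splitters",
                                       "ablate_general", "ablate_specific",
                                       "novel_cue_and_port"),
                              trial, fraction = 0.5, freeze = TRUE) {
  kind <- match.arg(kind)
  stopifnot(trial >= 1, fraction > 0, fraction <= 1)
  structure(list(kind = kind, trial = as.integer(trial),
                 fraction = fraction, freeze = isTRUE(freeze)),
            class = "perturbation_spec")
}

#' Experiment preset
#'
#' Bundles everything one run needs: the task variant, trial count,
#' perturbation schedule, held-out neurons, input-plasticity flag and the
#' model parameters.
#'
#' @param name Identifier.
#' @param task A [task_spec()].
#' @param n_trials Number of trials.
#' @param perturbations List of [perturbation_spec()]s (strictly increasing
#'   trial indices, all `<= n_trials`).
#' @param holdouts Integer vector of 0-based neuron ids held out of learning
#'   (external inputs zeroed, never scheduled for plateaus) until
#'   `release_trial`.
#' @param release_trial 1-based trial at whose start the holdouts are
#'   released.
#' @param input_plasticity Logical; learn the input weight matrix `M`.
#' @param trace_neurons 0-based neuron ids whose full position-by-trial
#'   activity is recorded (needed for [rate_map()]).
#' @param params A [sim_params()] object (the `input_plasticity` flag is
#'   forced to match the preset).
#' @return An object of class `experiment_preset`.
#' @seealso [preset()] for the shipped presets, [run_experiment()].
#' @export
experiment_preset <- function(name, task = task_spec("cue_dependent"),
                              n_trials = params$n_trials,
                              perturbations = list(),
                              holdouts = integer(0), release_trial = NA_integer_,
                              input_plasticity = FALSE,
                              trace_neurons = integer(0),
                              params = sim_params()) {
  params$input_plasticity <- isTRUE(input_plasticity)
  params$n_trials <- as.integer(n_trials)
  validate_params(params)
  if (length(perturbations)) {
    idx <- vapply(perturbations, `[[`, integer(1), "trial")
    if (any(diff(idx) <= 0) || any(idx > n_trials))
      stop("perturbation trial indices must be strictly increasing and <= n_trials")
  }
  if (length(holdouts) && (is.na(release_trial) || release_trial < 1))
    stop("holdouts require a release_trial")
  structure(list(name = name, task = task, n_trials = as.integer(n_trials),
                 perturbations = perturbations,
                 holdouts = as.integer(holdouts),
                 release_trial = as.integer(release_trial),
                 input_plasticity = isTRUE(input_plasticity),
                 trace_neurons = as.integer(trace_neurons),
                 params = params),
            class = "experiment_preset")
}

#' @export
print.experiment_preset <- function(x, ...) {
  cat(sprintf("Experiment preset '%s': %s task, %d trials\n",
              x$name, x$task$variant, x$n_trials))
  for (pb in x$perturbations)
    cat(sprintf("  perturbation: %s at trial %d\n", pb$kind, pb$trial))
  if (length(x$holdouts))
    cat(sprintf("  holdouts: %s (released at trial %d)\n",
                paste(x$holdouts, collapse = ", "), x$release_trial))
  if (x$input_plasticity) cat("  input weights plastic\n")
  invisible(x)
}

#' Load a shipped experiment preset
#'
#' Presets are stored as YAML files under `inst/extdata/presets`. Available:
#' `cue_dependent_main`, `random_reward_main`, `behavior_reset`, `prune_B`,
#' `ablate_general`, `ablate_specific`, `holdout_fewshot`, `novel_cue_port`.
#' Fields given in `...` (e.g. `n_trials`) override the file.
#'
#' @param name Preset name (or a path to a YAML preset file).
#' @param ... Overrides of top-level preset fields or of model parameters.
#' @return An [experiment_preset()].
#' @export
#' @examples
#' p <- preset("cue_dependent_main", n_trials = 50)
preset <- function(name, ...) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "presets", paste0(name, ".yaml"),
                package = "splithpc")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown preset: ", name)
  cfg <- load_config(path, overrides = list(...))
  config_to_preset(cfg)
}

#' List the shipped presets
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  files <- list.files(system.file("extdata", "presets", package = "splithpc"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

# ---------------------------------------------------------------------------
# Simulation context: all mutable run state in one environment.

#' Create a fresh simulation context
#'
#' Initialises RNG streams, tuning curves, weights and bookkeeping for an
#' experiment. [run_experiment()] drives this; it is exported so single
#' trials can be stepped interactively with [run_trial()].
#'
#' @param preset An [experiment_preset()].
#' @param seed Integer root seed.
#' @return Environment of class `sim_context`.
#' @export
new_sim_context <- function(preset, seed) {
  ctx <- new.env(parent = emptyenv())
  ctx$preset <- preset
  ctx$params <- preset$params
  ctx$seed <- as.integer(seed)
  ctx$streams <- rng_streams(seed)
  ctx$geometry <- maze_geometry(ctx$params)
  ctx$bank <- build_tuning_curves(ctx$params, ctx$geometry)
  ctx$weights <- init_weights(ctx$params, ctx$streams)
  ctx$aw <- new_action_weights(ctx$params, ctx$streams)
  ctx$beta <- compute_beta(ctx$weights$W, ctx$params)
  n <- ctx$params$n
  ctx$input_mask <- rep(1, n)
  ctx$s_mask <- rep(1, n)
  ctx$freeze_rows <- integer(0)
  ctx$forced_chance <- FALSE
  ctx$holdouts <- preset$holdouts
  if (length(ctx$holdouts)) ctx$input_mask[ctx$holdouts + 1L] <- 0
  ctx$trial <- 0L
  refresh_input_cache(ctx)
  refresh_schedules(ctx)
  ctx
}

refresh_input_cache <- function(ctx) {
  ctx$U <- list(
    A = list(D = input_matrix(ctx$bank, "A", "D", ctx$params),
             E = input_matrix(ctx$bank, "A", "E", ctx$params)),
    B = list(D = input_matrix(ctx$bank, "B", "D", ctx$params),
             E = input_matrix(ctx$bank, "B", "E", ctx$params)))
  invisible(ctx)
}

refresh_schedules <- function(ctx) {
  n_steps <- ctx$geometry$n_steps
  ctx$sched <- lapply(c(A = "A", B = "B"), function(cue) {
    sc <- make_induction_schedule(cue, ctx$params, holdouts = ctx$holdouts)
    list(schedule = sc, windows = schedule_windows(sc, ctx$params, n_steps))
  })
  invisible(ctx)
}

#' Run one closed-loop trial
#'
#' Executes the full loop for one trial: cue presentation, network and action
#' dynamics over all timesteps, turn selection at the choice point, reward
#' delivery, and the batch weight updates (recurrent, state-action, and —
#' when enabled — input weights). The context is mutated; the trial record is
#' returned.
#'
#' @param ctx A [new_sim_context()] environment.
#' @param cue Optional forced cue; sampled fairly when `NULL`.
#' @return List of class `trial_record`: `trial`, `cue`, `turn`,
#'   `was_random`, `reward`, `correct`, `infield` (per-neuron somatic
#'   activity at its plateau position), `beta`, and `S` (timestep-by-neuron
#'   activity of the trial).
#' @export
run_trial <- function(ctx, cue = NULL) {
  p <- ctx$params
  n_steps <- ctx$geometry$n_steps
  if (is.null(cue)) cue <- sample_cue(ctx$streams, ctx$preset$task)
  sched <- ctx$sched[[cue]]
  noise <- rng_eval(ctx$streams, "noise",
                    matrix(stats::rnorm(n_steps * p$n_act, 0, p$sigma_v),
                           n_steps, p$n_act))
  st <- new_network_state(p, beta = ctx$beta,
                          input_mask = ctx$input_mask, s_mask = ctx$s_mask)
  act <- new_action_state(p)
  proto_W <- matrix(0, p$n, p$n)
  proto_Q <- matrix(0, p$n_act, p$n)
  proto_M <- if (p$input_plasticity) matrix(0, p$n, p$n_inp) else NULL
  S <- matrix(0, n_steps, p$n)
  Ucur <- ctx$U[[cue]]$D   # pre-choice rows identical for both turns
  choice <- NULL
  v_choice <- c(NA_real_, NA_real_)
  win <- sched$windows
  for (ti in seq_len(n_steps)) {
    t <- ti - 1L
    if (t == p$t_choice) {
      v_choice <- act$v
      choice <- select_turn(act, p, ctx$streams,
                            forced_chance = ctx$forced_chance)
      Ucur <- ctx$U[[cue]][[choice$direction]]
    }
    u <- Ucur[ti, ]
    step_network(st, ctx$weights, u, p)
    idx <- win[[ti]]
    if (length(idx)) {
      proto_W[idx, ] <- proto_W[idx, ] + tcrossprod(st$s[idx], st$e)
      if (p$input_plasticity)
        proto_M[idx, ] <- proto_M[idx, ] + tcrossprod(st$s[idx], u)
    }
    step_action(act, ctx$aw, st$s, p, noise[ti, ])
    in_clamp <- t >= p$t_choice && t < p$t_choice + p$clamp_steps
    cw <- p$action_credit_window
    v_cr <- if (p$credit_rectify) pmax(act$v, 0) else act$v
    if (cw == "trial" || (cw == "choice" && in_clamp)) {
      proto_Q <- proto_Q + tcrossprod(v_cr, st$e_action)
    } else if (cw == "free") {
      if (in_clamp) v_cr[act$winner] <- 0
      proto_Q <- proto_Q + tcrossprod(v_cr, st$e_action)
    }
    S[ti, ] <- st$s
  }
  r <- deliver_reward(ctx$preset$task, cue, choice$direction, ctx$streams)
  ctx$weights$W <- update_recurrent_weights(ctx$weights$W, proto_W, r, p,
                                            freeze_rows = ctx$freeze_rows)
  ctx$aw <- update_action_weights(ctx$aw, proto_Q, r, p)
  if (p$input_plasticity)
    ctx$weights$M <- update_input_weights(ctx$weights$M, proto_M, p)
  ctx$beta <- compute_beta(ctx$weights$W, p)
  ctx$trial <- ctx$trial + 1L
  tf <- ifelse(p$t_plateau >= 0 & p$t_plateau < n_steps,
               round(p$t_plateau) + 1, NA)
  infield <- ifelse(is.na(tf), NA_real_, S[cbind(tf, seq_len(p$n))])
  correct <- (cue == "A" && choice$direction == "D") ||
             (cue == "B" && choice$direction == "E")
  structure(list(trial = ctx$trial, cue = cue, turn = choice$direction,
                 was_random = choice$was_random, reward = r,
                 correct = correct, v_choice = v_choice,
                 infield = infield, beta = ctx$beta, S = S),
            class = "trial_record")
}

# ---------------------------------------------------------------------------
# Perturbations

# Splitter identification over the `window` trials preceding the current one:
# windowed mean in-field rate difference (A - B), split if |difference|
# exceeds `split_threshold` times the neuron's windowed peak in-field rate.
identify_splitters <- function(infield, cues, params, window = 100L) {
  k <- nrow(infield)
  use <- max(1L, k - window + 1L):k
  a_rows <- use[cues[use] == "A"]; b_rows <- use[cues[use] == "B"]
  if (!length(a_rows) || !length(b_rows))
    stop("cannot identify splitters: window lacks one cue type")
  ra <- colMeans(infield[a_rows, , drop = FALSE])
  rb <- colMeans(infield[b_rows, , drop = FALSE])
  d <- ra - rb
  peak <- pmax(ra, rb)
  split <- !is.na(d) & peak > 0 & abs(d) > params$split_threshold * peak
  list(split = which(split) - 1L,
       a_type = which(split & d > 0) - 1L,
       b_type = which(split & d < 0) - 1L)
}

#' Force behavior to chance (behavior-reset perturbation)
#'
#' From the next trial on, every turn is a fair coin flip flagged as random;
#' the action readout is bypassed but all plasticity continues.
#'
#' @param ctx A [new_sim_context()].
#' @return The context, invisibly.
#' @export
apply_behavior_reset <- function(ctx) {
  ctx$forced_chance <- TRUE
  invisible(ctx)
}

#' Prune the recurrent weights of B-preferring splitters
#'
#' Incoming recurrent weights of every B-type splitter are set to zero,
#' turning them back into generic place fields; with `freeze = TRUE`
#' (default) the rows stay clamped at zero under subsequent learning.
#'
#' @param ctx A [new_sim_context()].
#' @param labels Splitter labels from the analysis step (list with `b_type`);
#'   identified from the run's own log when `NULL`.
#' @param freeze Keep the pruned rows at zero.
#' @return The context, invisibly. Errors if no splitters exist yet.
#' @export
apply_representation_prune <- function(ctx, labels = NULL, freeze = TRUE) {
  if (is.null(labels)) labels <- ctx$splitter_labels
  if (is.null(labels) || !length(labels$b_type))
    stop("pruning requested before any B-type splitters exist", call. = FALSE)
  ctx$weights$W[labels$b_type + 1L, ] <- 0
  if (freeze) ctx$freeze_rows <- sort(unique(c(ctx$freeze_rows, labels$b_type)))
  ctx$beta <- compute_beta(ctx$weights$W, ctx$params)
  invisible(ctx)
}

#' Ablate splitter neurons
#'
#' Somatic output of the sampled neurons is clamped to zero permanently: they
#' stop driving apical feedback, plasticity and the action neurons. General
#' mode samples from all splitters; specific mode from B-type splitters only.
#'
#' @param ctx A [new_sim_context()].
#' @param mode `"general"` or `"specific"`.
#' @param fraction Fraction of the eligible set to ablate.
#' @param labels Splitter labels (identified from the log when `NULL`).
#' @return The context, invisibly.
#' @export
apply_ablation <- function(ctx, mode = c("general", "specific"),
                           fraction = 0.5, labels = NULL) {
  mode <- match.arg(mode)
  if (is.null(labels)) labels <- ctx$splitter_labels
  eligible <- if (mode == "general") labels$split else labels$b_type
  if (!length(eligible))
    stop("ablation requested before any eligible splitters exist", call. = FALSE)
  k <- max(1L, round(fraction * length(eligible)))
  sel <- rng_eval(ctx$streams, "perturb",
                  sample(eligible, k))
  ctx$s_mask[sel + 1L] <- 0
  ctx$ablated <- sort(unique(c(ctx$ablated, sel)))
  invisible(ctx)
}

#' Release held-out neurons into the induction schedule
#'
#' Restores the external input of the held-out neurons and re-admits them to
#' the even/odd plateau schedule from the current trial on.
#'
#' @param ctx A [new_sim_context()].
#' @return The context, invisibly.
#' @export
release_holdouts <- function(ctx) {
  if (length(ctx$holdouts)) {
    ctx$input_mask[ctx$holdouts + 1L] <- 1
    ctx$holdouts <- integer(0)
    refresh_schedules(ctx)
  }
  invisible(ctx)
}

#' Swap one cue and one reward port onto novel input channels
#'
#' Retires the B-cue and E-port input channels and assigns their spatial
#' coverage to previously dormant reserve channels. Requires input
#' plasticity: the input weights then remap the existing internal
#' representation onto the new external lines.
#'
#' @param ctx A [new_sim_context()].
#' @return The context, invisibly.
#' @export
apply_novel_cue_and_port <- function(ctx) {
  if (!ctx$params$input_plasticity)
    stop("novel cue/port remapping requires input plasticity", call. = FALSE)
  bank <- ctx$bank
  old_cue <- which(bank$role == "cue_B")
  old_port <- which(bank$role == "branch_E")
  reserves <- which(bank$role == "reserve")
  need <- 20L
  if (length(reserves) < need)
    stop("not enough reserve channels for the novel cue and port", call. = FALSE)
  g <- ctx$geometry
  bank$role[old_cue] <- "retired"
  bank$role[old_port] <- "retired"
  new_cue <- reserves[1:10]
  new_port <- reserves[11:20]
  bank$role[new_cue] <- "cue_B"
  bank$center[new_cue] <- seq(g$cue_zone[1] + 1, g$cue_zone[2] - 1,
                              length.out = 10)
  bank$role[new_port] <- "branch_E"
  bank$center[new_port] <- seq(g$branch[1] + 1, g$branch[2] - 3,
                               length.out = 10)
  ctx$bank <- bank
  refresh_input_cache(ctx)
  invisible(ctx)
}

apply_perturbation <- function(ctx, pb) {
  switch(pb$kind,
    behavior_reset = apply_behavior_reset(ctx),
    prune_B_splitters = apply_representation_prune(ctx, freeze = pb$freeze),
    ablate_general = apply_ablation(ctx, "general", pb$fraction),
    ablate_specific = apply_ablation(ctx, "specific", pb$fraction),
    novel_cue_and_port = apply_novel_cue_and_port(ctx),
    stop("unknown perturbation kind: ", pb$kind))
  invisible(ctx)
}

# ---------------------------------------------------------------------------

#' Run a full experiment
#'
#' Runs `n_trials` closed-loop trials of the preset's task, applying the
#' perturbation schedule and holdout release at their trial indices, and
#' returns an `hpc_experiment` object: the trial log, per-trial in-field
#' activity of every neuron, per-trial apical modulation, optional full rate
#' traces for selected neurons, weight checkpoints and the final state.
#'
#' Runs are fully reproducible: the same `(preset, seed)` yields a
#' bit-identical log. A finished (or checkpointed) run can be extended with
#' `resume`.
#'
#' @param preset An [experiment_preset()] or the name of a shipped preset.
#' @param seed Integer root seed.
#' @param n_trials Optional override of the preset's trial count.
#' @param trace_neurons 0-based neuron ids to record in full (trial x
#'   position); defaults to the preset's list.
#' @param checkpoint_every Interval (trials) between recurrent-weight
#'   checkpoints; `Inf` disables them.
#' @param resume A previous `hpc_experiment` from the same preset/seed whose
#'   run is to be continued up to `n_trials`. Refuses to resume if the
#'   resolved configuration hash does not match.
#' @param progress Print a progress line every 500 trials.
#' @return An object of class `hpc_experiment`.
#' @seealso [splitness()], [behavioral_performance()], [split_onset_times()],
#'   [rate_map()], [save_log()]
#' @export
#' @examples
#' pr <- preset("cue_dependent_main", n_trials = 30)
#' x <- run_experiment(pr, seed = 1)
#' summary(x)
run_experiment <- function(preset, seed = 1L,
                           n_trials = NULL,
                           trace_neurons = NULL,
                           checkpoint_every = 1000L,
                           resume = NULL, progress = FALSE) {
  if (is.character(preset)) preset <- preset(preset)
  stopifnot(inherits(preset, "experiment_preset"))
  if (!is.null(n_trials)) preset$n_trials <- as.integer(n_trials)
  if (is.null(trace_neurons)) trace_neurons <- preset$trace_neurons
  n_trials <- preset$n_trials
  p <- preset$params
  cfg_hash <- config_hash(preset, seed)

  if (is.null(resume)) {
    ctx <- new_sim_context(preset, seed)
    start <- 1L
    log0 <- NULL
  } else {
    stopifnot(inherits(resume, "hpc_experiment"))
    if (!identical(resume$config_hash, cfg_hash))
      stop("cannot resume: configuration hash mismatch (",
           resume$config_hash, " vs ", cfg_hash, ")", call. = FALSE)
    ctx <- restore_sim_context(resume, preset)
    start <- ctx$trial + 1L
    log0 <- resume
  }
  if (start > n_trials) return(resume)

  n_steps <- ctx$geometry$n_steps
  cues <- character(n_trials)
  turns <- character(n_trials)
  was_random <- logical(n_trials)
  rewards <- numeric(n_trials)
  corrects <- logical(n_trials)
  v_d <- numeric(n_trials); v_e <- numeric(n_trials)
  infield <- matrix(NA_real_, n_trials, p$n)
  betas <- matrix(NA_real_, n_trials, p$n)
  traces <- stats::setNames(
    lapply(trace_neurons, function(i) matrix(NA_real_, n_trials, n_steps)),
    as.character(trace_neurons))
  checkpoints <- list()
  events <- list()
  if (!is.null(log0)) {
    k0 <- log0$trials$trial
    cues[k0] <- log0$trials$cue; turns[k0] <- log0$trials$turn
    was_random[k0] <- log0$trials$was_random
    rewards[k0] <- log0$trials$reward; corrects[k0] <- log0$trials$correct
    v_d[k0] <- log0$trials$v_D; v_e[k0] <- log0$trials$v_E
    infield[k0, ] <- log0$infield; betas[k0, ] <- log0$betas
    for (nm in intersect(names(traces), names(log0$traces)))
      traces[[nm]][k0, ] <- log0$traces[[nm]]
    checkpoints <- log0$checkpoints
    events <- log0$events
  }

  pending <- preset$perturbations
  for (k in start:n_trials) {
    if (length(preset$holdouts) && !is.na(preset$release_trial) &&
        k == preset$release_trial && length(ctx$holdouts)) {
      release_holdouts(ctx)
      events[[length(events) + 1L]] <- list(trial = k, kind = "release_holdouts")
    }
    while (length(pending) && pending[[1]]$trial == k) {
      pb <- pending[[1]]; pending <- pending[-1]
      if (pb$kind %in% c("prune_B_splitters", "ablate_general",
                         "ablate_specific"))
        ctx$splitter_labels <- identify_splitters(
          infield[seq_len(k - 1L), , drop = FALSE], cues[seq_len(k - 1L)], p)
      apply_perturbation(ctx, pb)
      events[[length(events) + 1L]] <- list(trial = k, kind = pb$kind)
    }
    rec <- run_trial(ctx)
    cues[k] <- rec$cue; turns[k] <- rec$turn
    was_random[k] <- rec$was_random
    rewards[k] <- rec$reward; corrects[k] <- rec$correct
    v_d[k] <- rec$v_choice[1]; v_e[k] <- rec$v_choice[2]
    infield[k, ] <- rec$infield; betas[k, ] <- rec$beta
    for (nm in names(traces))
      traces[[nm]][k, ] <- rec$S[, as.integer(nm) + 1L]
    if (is.finite(checkpoint_every) && k %% checkpoint_every == 0L)
      checkpoints[[length(checkpoints) + 1L]] <-
        list(trial = k, W = ctx$weights$W)
    if (progress && k %% 500L == 0L)
      message(sprintf("trial %d/%d (perf last 100: %.2f)", k, n_trials,
                      mean(corrects[max(1, k - 99):k])))
  }

  out <- list(
    preset = preset, params = p, seed = as.integer(seed),
    config_hash = cfg_hash, schema_version = 1L,
    trials = data.frame(trial = seq_len(n_trials), cue = cues, turn = turns,
                        was_random = was_random, reward = rewards,
                        correct = corrects, v_D = v_d, v_E = v_e,
                        stringsAsFactors = FALSE),
    infield = infield, betas = betas, traces = traces,
    checkpoints = checkpoints, events = events,
    state = snapshot_sim_context(ctx))
  class(out) <- "hpc_experiment"
  out
}

snapshot_sim_context <- function(ctx) {
  list(trial = ctx$trial, W = ctx$weights$W, M = ctx$weights$M,
       identity_M = ctx$weights$identity_M, Q = ctx$aw$Q, I = ctx$aw$I,
       beta = ctx$beta, input_mask = ctx$input_mask, s_mask = ctx$s_mask,
       freeze_rows = ctx$freeze_rows, forced_chance = ctx$forced_chance,
       holdouts = ctx$holdouts, ablated = ctx$ablated,
       splitter_labels = ctx$splitter_labels,
       bank = ctx$bank, rng = rng_snapshot(ctx$streams))
}

restore_sim_context <- function(log, preset) {
  st <- log$state
  ctx <- new.env(parent = emptyenv())
  ctx$preset <- preset
  ctx$params <- preset$params
  ctx$seed <- log$seed
  ctx$streams <- rng_restore(st$rng)
  ctx$geometry <- maze_geometry(ctx$params)
  ctx$bank <- st$bank
  ctx$weights <- list(M = st$M, W = st$W, identity_M = st$identity_M)
  ctx$aw <- structure(list(Q = st$Q, I = st$I), class = "action_weights")
  ctx$beta <- st$beta
  ctx$input_mask <- st$input_mask
  ctx$s_mask <- st$s_mask
  ctx$freeze_rows <- st$freeze_rows
  ctx$forced_chance <- st$forced_chance
  ctx$holdouts <- st$holdouts
  ctx$ablated <- st$ablated
  ctx$splitter_labels <- st$splitter_labels
  ctx$trial <- st$trial
  refresh_input_cache(ctx)
  refresh_schedules(ctx)
  ctx
}
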