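# Trailing windowed per-cue means of the in-field rate matrix.
# Returns n_trials x n matrices of mean rate over the A-cue (resp. B-cue)
# trials among the `window` most recent trials; NA where the window contains
# no trial of that cue.
windowed_cue_means <- function(infield, cues, window) {
  n_trials <- nrow(infield)
  out <- list()
  for (cue in c("A", "B")) {
    m <- infield
    m[cues != cue, ] <- 0
    m[is.na(m)] <- 0
    cnt <- cumsum(cues == cue)
    cs <- apply(m, 2, cumsum)
    if (n_trials == 1) cs <- matrix(cs, nrow = 1)
    lag <- function(v) c(rep(0, window), v)[seq_len(n_trials)]
    wsum <- cs - apply(cs, 2, lag)
    wcnt <- cnt - lag(cnt)
    mean_m <- sweep(wsum, 1, wcnt, "/")
    mean_m[wcnt == 0, ] <- NA_real_
    out[[cue]] <- mean_m
  }
  out
}

#' Splitness of a neuron over learning
#'
#' Splitness is the difference between a neuron's mean in-field activity on
#' A-cue trials and on B-cue trials (positive = A-preferring), computed as a
#' trailing running mean over `window` trials. The in-field readout is the
#' somatic activity at the neuron's plateau position. Trials whose window
#' lacks one of the two cue types yield `NA`, not zero.
#'
#' @param x An `hpc_experiment` from [run_experiment()].
#' @param neuron 0-based neuron id.
#' @param window Trailing window in trials (default: the run's
#'   `splitness_window` parameter, 100).
#' @return Numeric vector (one value per trial) of class `splitness_series`,
#'   with the windowed per-cue rates and the neuron's peak windowed in-field
#'   rate stored as attributes.
#' @export
#' @seealso [split_criterion()], [split_onset_times()]
splitness <- function(x, neuron, window = x$params$splitness_window) {
  stopifnot(inherits(x, "hpc_experiment"))
  wm <- windowed_cue_means(x$infield[, neuron + 1L, drop = FALSE],
                           x$trials$cue, window)
  ra <- wm$A[, 1]; rb <- wm$B[, 1]
  s <- ra - rb
  structure(s, class = "splitness_series", neuron = neuron, window = window,
            rate_A = ra, rate_B = rb,
            peak = suppressWarnings(max(pmax(ra, rb), na.rm = TRUE)))
}

#' Per-trial split criterion
#'
#' A neuron counts as split on a trial when `|splitness|` exceeds
#' `threshold` times its peak windowed in-field rate. Trials where splitness
#' is undefined are `NA`.
#'
#' @param series A [splitness()] series.
#' @param threshold Fraction of the peak in-field rate (default 0.5).
#' @return Logical vector, one entry per trial.
#' @export
split_criterion <- function(series, threshold = 0.5) {
  stopifnot(inherits(series, "splitness_series"))
  peak <- attr(series, "peak")
  if (!is.finite(peak) || peak <= 0) return(rep(NA, length(series)))
  abs(unclass(series)) > threshold * peak
}

# First index at which `flag` (logical, NA = not evaluable) holds for
# `persist` consecutive evaluable entries; NA if never.
first_persistent <- function(flag, persist) {
  ev <- which(!is.na(flag))
  if (!length(ev)) return(NA_integer_)
  f <- flag[ev]
  run <- 0L
  for (j in seq_along(f)) {
    run <- if (isTRUE(f[j])) run + 1L else 0L
    if (run >= persist) return(ev[j - persist + 1L])
  }
  NA_integer_
}

#' Split-onset trials
#'
#' For each neuron, the first trial at which the split criterion holds and
#' keeps holding for `persist` consecutive evaluable trials. Neurons that
#' never split report `NA`. During emergent learning the onsets order
#' themselves along the stem ("zipper"): neurons nearest the cue zone split
#' first.
#'
#' @param x An `hpc_experiment`.
#' @param neurons 0-based neuron ids (default: all).
#' @param window Splitness running-mean window.
#' @param threshold Split-criterion threshold fraction.
#' @param persist Required persistence in evaluable trials.
#' @return Named integer vector of onset trials (names = neuron ids).
#' @export
split_onset_times <- function(x, neurons = seq_len(x$params$n) - 1L,
                              window = x$params$splitness_window,
                              threshold = x$params$split_threshold,
                              persist = x$params$split_persist) {
  stopifnot(inherits(x, "hpc_experiment"))
  wm <- windowed_cue_means(x$infield[, neurons + 1L, drop = FALSE],
                           x$trials$cue, window)
  onsets <- integer(length(neurons))
  for (j in seq_along(neurons)) {
    ra <- wm$A[, j]; rb <- wm$B[, j]
    d <- ra - rb
    peak <- suppressWarnings(max(pmax(ra, rb), na.rm = TRUE))
    flag <- if (!is.finite(peak) || peak <= 0) rep(NA, length(d)) else
      abs(d) > threshold * peak
    onsets[j] <- first_persistent(flag, persist)
  }
  stats::setNames(onsets, neurons)
}

#' Zipper ordering of split onsets along the stem
#'
#' Spearman rank correlation between each stem neuron's split-onset trial and
#' its field position. A positive correlation is the "zipper": splitters
#' emerge first near the cue zone and propagate toward the reward end.
#'
#' @param x An `hpc_experiment`.
#' @param ... Passed to [split_onset_times()].
#' @return List with `onsets`, the stem neuron ids, and `rho`.
#' @export
zipper_ordering <- function(x, ...) {
  ids <- stem_neurons(x$params)
  on <- split_onset_times(x, neurons = ids, ...)
  ok <- !is.na(on)
  rho <- if (sum(ok) >= 3)
    stats::cor(x$params$t_plateau[ids[ok] + 1L], on[ok], method = "spearman")
  else NA_real_
  list(onsets = on, neurons = ids, rho = rho, n_split = sum(ok))
}

#' Neuron ids whose plateau position lies in the stem
#' @param params A [sim_params()] object.
#' @return Integer vector of 0-based ids.
#' @export
stem_neurons <- function(params) {
  pos <- params$t_plateau * params$dx_dt
  which(pos >= params$stem[1] & pos < params$stem[2]) - 1L
}

#' Behavioral performance over learning
#'
#' Trailing running mean of the correct-turn indicator (cue A to port D, cue
#' B to port E), including random-turn trials. For the random-reward task
#' (where "correct" is undefined) the reported series is the fraction of
#' turns to port D, and is labelled as such.
#'
#' @param x An `hpc_experiment`.
#' @param window Trailing window in trials.
#' @param per_cue Also compute the windowed series separately on A-cue and
#'   B-cue trials.
#' @return Data frame with columns `trial`, `value` and (if `per_cue`) `A`,
#'   `B`; attribute `measure` names the indicator.
#' @export
behavioral_performance <- function(x, window = 100L, per_cue = FALSE) {
  stopifnot(inherits(x, "hpc_experiment"))
  random_task <- x$preset$task$variant == "random_reward"
  ind <- if (random_task) as.numeric(x$trials$turn == "D")
         else as.numeric(x$trials$correct)
  n <- length(ind)
  cs <- cumsum(ind)
  lagv <- function(v) c(rep(0, window), v)[seq_len(n)]
  val <- (cs - lagv(cs)) / pmin(seq_len(n), window)
  out <- data.frame(trial = seq_len(n), value = val)
  if (per_cue) {
    for (cue in c("A", "B")) {
      m <- ind * (x$trials$cue == cue)
      cnt <- cumsum(x$trials$cue == cue)
      wsum <- cumsum(m) - lagv(cumsum(m))
      wcnt <- cnt - lagv(cnt)
      out[[cue]] <- ifelse(wcnt > 0, wsum / wcnt, NA_real_)
    }
  }
  attr(out, "measure") <- if (random_task) "fraction_to_D" else "fraction_correct"
  out
}

#' Rate map of one neuron
#'
#' Trial-by-position matrix of a traced neuron's somatic activity, optionally
#' split by cue type and aligned to a reference trial (e.g. the induction
#' trial of a held-out neuron).
#'
#' @param x An `hpc_experiment` whose `trace_neurons` included `neuron`.
#' @param neuron 0-based neuron id.
#' @param cue Optional cue filter (`"A"` or `"B"`).
#' @param align_trial Optional 1-based trial whose row becomes relative
#'   trial 0.
#' @return Matrix (rows = trials, columns = track positions) with rownames
#'   giving the (relative) trial indices.
#' @export
rate_map <- function(x, neuron, cue = NULL, align_trial = NULL) {
  stopifnot(inherits(x, "hpc_experiment"))
  tr <- x$traces[[as.character(neuron)]]
  if (is.null(tr))
    stop("neuron ", neuron, " was not traced; rerun with trace_neurons",
         call. = FALSE)
  keep <- if (is.null(cue)) seq_len(nrow(tr)) else which(x$trials$cue == cue)
  m <- tr[keep, , drop = FALSE]
  rel <- if (is.null(align_trial)) keep else keep - align_trial
  rownames(m) <- rel
  m
}
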