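#' @export
print.hpc_experiment <- function(x, ...) {
  cat(sprintf("<hpc_experiment> preset '%s' (%s task), %d trials, seed %d\n",
              x$preset$name, x$preset$task$variant, nrow(x$trials), x$seed))
  last <- max(1L, nrow(x$trials) - 499L):nrow(x$trials)
  if (x$preset$task$variant == "cue_dependent")
    cat(sprintf("  correct turns, final 500 trials: %.3f\n",
                mean(x$trials$correct[last])))
  cat(sprintf("  mean reward, final 500 trials: %.3f\n",
              mean(x$trials$reward[last])))
  if (length(x$events))
    for (ev in x$events)
      cat(sprintf("  event: %s at trial %d\n", ev$kind, ev$trial))
  invisible(x)
}

#' Summary of an experiment run
#'
#' Reports end-of-run behavioral performance (overall and per cue), mean
#' delivered reward, the number of stem neurons meeting the split criterion,
#' and the zipper ordering statistic.
#'
#' @param object An `hpc_experiment`.
#' @param window Trailing window for the end-of-run averages.
#' @param ... Unused.
#' @return A list of class `summary.hpc_experiment`.
#' @export
summary.hpc_experiment <- function(object, window = 500L, ...) {
  n <- nrow(object$trials)
  last <- max(1L, n - window + 1L):n
  tr <- object$trials[last, ]
  per_cue <- c(A = mean(tr$correct[tr$cue == "A"]),
               B = mean(tr$correct[tr$cue == "B"]))
  stem <- stem_neurons(object$params)
  onsets <- tryCatch(split_onset_times(object, neurons = stem),
                     error = function(e) rep(NA_integer_, length(stem)))
  zip <- tryCatch(zipper_ordering(object), error = function(e) list(rho = NA))
  out <- list(preset = object$preset$name, task = object$preset$task$variant,
              n_trials = n, seed = object$seed, window = length(last),
              performance = mean(tr$correct), per_cue = per_cue,
              mean_reward = mean(tr$reward),
              n_stem = length(stem), n_split = sum(!is.na(onsets)),
              median_onset = stats::median(onsets, na.rm = TRUE),
              zipper_rho = zip$rho,
              events = object$events)
  class(out) <- "summary.hpc_experiment"
  out
}

#' @export
print.summary.hpc_experiment <- function(x, ...) {
  cat(sprintf("Experiment '%s' (%s), %d trials, seed %d\n",
              x$preset, x$task, x$n_trials, x$seed))
  cat(sprintf("  final %d trials: %.1f%% correct (A: %.1f%%, B: %.1f%%), mean reward %.3f\n",
              x$window, 100 * x$performance, 100 * x$per_cue["A"],
              100 * x$per_cue["B"], x$mean_reward))
  cat(sprintf("  split stem neurons: %d / %d (median onset trial %s)\n",
              x$n_split, x$n_stem,
              ifelse(is.na(x$median_onset), "none", x$median_onset)))
  if (is.finite(x$zipper_rho %||% NA))
    cat(sprintf("  zipper (Spearman onset ~ position): rho = %.2f\n",
                x$zipper_rho))
  for (ev in x$events)
    cat(sprintf("  event: %s at trial %d\n", ev$kind, ev$trial))
  invisible(x)
}

#' Final weights of a run
#'
#' @param object An `hpc_experiment`.
#' @param ... Unused.
#' @return List with the recurrent (`W`), state-action (`Q`) and input (`M`)
#'   weight matrices and the final apical modulation vector `beta`.
#' @export
coef.hpc_experiment <- function(object, ...) {
  st <- object$state
  list(W = st$W, Q = st$Q, M = st$M, beta = st$beta)
}

#' Plot an experiment run
#'
#' Three panels in the style of the model's summary figures: (1) running
#' behavioral performance (overall and per cue); (2) mean splitness of the
#' A-plateau (even) and B-plateau (odd) stem populations; (3) windowed
#' B-trial in-field activity of every stem neuron over learning (the zipper
#' plot).
#'
#' @param x An `hpc_experiment`.
#' @param which Subset of `c("performance", "splitness", "population")`.
#' @param window Running-mean window in trials.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.hpc_experiment <- function(x, which = c("performance", "splitness",
                                             "population"),
                                window = x$params$splitness_window, ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(which), 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  stem <- stem_neurons(x$params)
  if ("performance" %in% which) {
    perf <- behavioral_performance(x, window = window, per_cue = TRUE)
    graphics::plot(perf$trial, perf$value, type = "l", ylim = c(0, 1),
                   xlab = "trial", ylab = attr(perf, "measure"),
                   main = "behavior")
    graphics::lines(perf$trial, perf$A, col = "red")
    graphics::lines(perf$trial, perf$B, col = "grey30")
    graphics::abline(h = 0.5, lty = 3)
    graphics::legend("bottomright", c("all", "A trials", "B trials"),
                     col = c("black", "red", "grey30"), lty = 1, bty = "n")
  }
  wm <- windowed_cue_means(x$infield[, stem + 1L, drop = FALSE],
                           x$trials$cue, window)
  split_m <- wm$A - wm$B
  if ("splitness" %in% which) {
    even <- stem %% 2L == 0L
    sa <- rowMeans(split_m[, even, drop = FALSE], na.rm = TRUE)
    sb <- rowMeans(split_m[, !even, drop = FALSE], na.rm = TRUE)
    graphics::plot(seq_along(sa), sa, type = "l", col = "red",
                   ylim = range(c(sa, sb), na.rm = TRUE, finite = TRUE),
                   xlab = "trial", ylab = "splitness (A - B rate)",
                   main = "population splitness")
    graphics::lines(seq_along(sb), sb, col = "grey30")
    graphics::abline(h = 0, lty = 3)
  }
  if ("population" %in% which) {
    graphics::image(x = seq_len(nrow(split_m)), y = stem, z = wm$B,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "trial", ylab = "stem neuron id",
                    main = "B-trial in-field activity")
  }
  invisible(x)
}
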