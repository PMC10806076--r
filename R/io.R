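known_config_keys <- c("name", "preset", "task", "n_trials", "perturbations",
                       "holdouts", "release_trial", "input_plasticity",
                       "trace_neurons", "params", "seed")

#' Load and resolve a run configuration
#'
#' Reads a YAML configuration, applies overrides, validates every field and
#' fills all omitted model parameters with their reference defaults (an empty
#' file resolves to the pure default configuration). Unknown keys are
#' rejected with their field path.
#'
#' @param path Path to a YAML file.
#' @param overrides Named list applied on top of the file; names may be
#'   top-level config keys or [sim_params()] arguments.
#' @return A named list of class `run_config` (fully resolved).
#' @export
load_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  bad <- setdiff(names(raw), known_config_keys)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  param_names <- names(formals(sim_params))
  if (!is.null(raw$params)) {
    badp <- setdiff(names(raw$params), param_names)
    if (length(badp))
      stop("unknown config key(s): ",
           paste0("params.", badp, collapse = ", "), call. = FALSE)
  }
  for (nm in names(overrides)) {
    if (nm %in% known_config_keys) {
      raw[[nm]] <- overrides[[nm]]
      if (nm == "n_trials") raw$params$n_trials <- overrides[[nm]]
    } else if (nm %in% param_names) {
      raw$params[[nm]] <- overrides[[nm]]
    } else stop("unknown override: ", nm, call. = FALSE)
  }
  cfg <- list(
    name = raw$name %||% raw$preset %||% "custom",
    task = do.call(task_spec, raw$task %||% list()),
    perturbations = lapply(raw$perturbations %||% list(),
                           function(pb) do.call(perturbation_spec, pb)),
    holdouts = as.integer(raw$holdouts %||% integer(0)),
    release_trial = as.integer(raw$release_trial %||% NA_integer_),
    input_plasticity = isTRUE(raw$input_plasticity),
    trace_neurons = as.integer(raw$trace_neurons %||% integer(0)),
    seed = raw$seed %||% NULL,
    params = do.call(sim_params, raw$params %||% list())
  )
  cfg$n_trials <- as.integer(raw$n_trials %||% cfg$params$n_trials)
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_to_preset <- function(cfg) {
  experiment_preset(name = cfg$name, task = cfg$task, n_trials = cfg$n_trials,
                    perturbations = cfg$perturbations,
                    holdouts = cfg$holdouts,
                    release_trial = cfg$release_trial,
                    input_plasticity = cfg$input_plasticity,
                    trace_neurons = cfg$trace_neurons,
                    params = cfg$params)
}

# 32-bit FNV-1a over the canonical JSON serialisation of the resolved
# configuration; used to refuse resuming/loading under a different config.
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor with the low byte, then multiply mod 2^32 (split to keep products
    # inside the exact-double range)
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), b)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Hash of a resolved configuration
#'
#' @param preset An [experiment_preset()].
#' @param seed Root seed of the run.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(preset, seed) {
  # n_trials is deliberately excluded: extending a finished run to more
  # trials is the supported resume case and must hash identically
  params <- unclass(preset$params)
  params$n_trials <- NULL
  canon <- list(name = preset$name, task = unclass(preset$task),
                perturbations = lapply(preset$perturbations, unclass),
                holdouts = preset$holdouts,
                release_trial = preset$release_trial,
                input_plasticity = preset$input_plasticity,
                params = params, seed = as.integer(seed))
  fnv1a32(as.character(jsonlite::toJSON(canon, auto_unbox = TRUE,
                                        digits = NA, na = "null")))
}

#' Save an experiment log to a directory
#'
#' Writes the resolved configuration (JSON), the per-trial tabular log and
#' the in-field / modulation matrices as delimited text, any full neuron
#' traces as one file per neuron, and the complete run state (weights, RNG
#' stream states, checkpoints) as an R serialisation so that the run can be
#' reloaded and resumed bit-exactly.
#'
#' @param x An `hpc_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_log <- function(x, dir) {
  stopifnot(inherits(x, "hpc_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(schema_version = x$schema_version, seed = x$seed,
               config_hash = x$config_hash,
               code_version = as.character(utils::packageVersion("splithpc")),
               preset = x$preset$name,
               task = x$preset$task$variant, n_trials = x$preset$n_trials,
               params = unclass(x$params))
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.csv(x$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(x$infield, file.path(dir, "infield.csv"), row.names = FALSE)
  utils::write.csv(x$betas, file.path(dir, "betas.csv"), row.names = FALSE)
  for (nm in names(x$traces))
    utils::write.csv(x$traces[[nm]],
                     file.path(dir, sprintf("trace_%s.csv", nm)),
                     row.names = FALSE)
  saveRDS(x, file.path(dir, "experiment.rds"))
  invisible(dir)
}

#' Load an experiment log saved with [save_log()]
#'
#' Verifies the embedded schema version and the configuration hash between
#' the sidecar metadata and the serialised object; mismatches are refused
#' with a diagnostic.
#'
#' @param dir Directory written by [save_log()].
#' @return The `hpc_experiment` object.
#' @export
load_log <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"))
  x <- readRDS(file.path(dir, "experiment.rds"))
  if (!identical(as.integer(meta$schema_version), x$schema_version))
    stop("log schema version mismatch: directory has ", meta$schema_version,
         ", object has ", x$schema_version, call. = FALSE)
  if (!identical(meta$config_hash, x$config_hash))
    stop("config hash mismatch between metadata (", meta$config_hash,
         ") and log (", x$config_hash, "); refusing to load", call. = FALSE)
  x
}

#' Quick invariant self-test
#'
#' Runs a handful of fast structural checks of the installed package:
#' tuning-curve closed forms, the basal-readout limit at zero recurrent
#' weight, the decay-only closed form of the recurrent weights, and
#' determinism of a short run. Intended for the command-line `selftest` verb.
#'
#' @return `TRUE` (invisibly) if all checks pass; otherwise an error.
#' @export
run_selftest <- function() {
  p <- sim_params()
  bank <- build_tuning_curves(p)
  stopifnot(abs(tuning_curve(bank, 30, 30) - 1) < 1e-12,
            abs(tuning_curve(bank, 30, 35) - exp(-1)) < 1e-12)
  streams <- rng_streams(1)
  w <- init_weights(p, streams)
  w$W[] <- 0
  beta <- compute_beta(w$W, p)
  st <- new_network_state(p, beta = beta)
  u <- external_input(bank, 40, "A")
  step_network(st, w, u, p)
  stopifnot(max(abs(st$s - u)) < 1e-5)
  W0 <- matrix(0.01, 3, 3)
  p3 <- sim_params(n_inp = 12, n = 3, len = 12, t_choice = 8,
                   cue_zone = c(0, 4), stem = c(4, 8), branch = c(8, 12),
                   t_plateau = c(1, 2, 3))
  W1 <- update_recurrent_weights(W0, matrix(0, 3, 3), 1, p3)
  stopifnot(max(abs(W1 - W0 * (1 - p3$lambda_w))) < 1e-12)
  pr <- preset("cue_dependent_main", n_trials = 5)
  a <- run_experiment(pr, seed = 11)
  b <- run_experiment(pr, seed = 11)
  stopifnot(identical(a$trials, b$trials))
  message("selftest: all checks passed")
  invisible(TRUE)
}
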