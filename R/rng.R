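#' Named RNG substreams from one root seed
#'
#' A single root seed deterministically spawns independent named substreams
#' (cue draws, action-network noise, policy noise, reward coins, weight
#' initialisation, perturbation sampling), so that toggling one stochastic
#' component of an experiment does not shift the draws of the others. Each
#' stream holds its own `.Random.seed` state; draws are made by temporarily
#' swapping that state into the session RNG and saving it back.
#'
#' @param seed Integer root seed.
#' @param names Character vector of stream names.
#' @return An object of class `rng_streams` (an environment).
#' @export
#' @examples
#' s <- rng_streams(1)
#' a <- rng_eval(s, "cue", runif(3))
#' b <- rng_eval(s, "noise", runif(3))  # independent of the cue stream
rng_streams <- function(seed,
                        names = c("cue", "noise", "policy", "task",
                                  "init", "perturb")) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(names))
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e$states <- stats::setNames(vector("list", length(names)), names)
  for (k in seq_along(names)) {
    set.seed(sub_seeds[k], kind = "Mersenne-Twister")
    e$states[[k]] <- .Random.seed
  }
  class(e) <- "rng_streams"
  e
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate an expression under a named RNG stream
#'
#' @param streams An [rng_streams()] object.
#' @param name Stream name.
#' @param expr Expression performing random draws.
#' @return The value of `expr`. The stream state advances; the session RNG
#'   state is restored afterwards.
#' @export
rng_eval <- function(streams, name, expr) {
  stopifnot(inherits(streams, "rng_streams"))
  if (!name %in% names(streams$states)) stop("unknown RNG stream: ", name)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set_rng_state(streams$states[[name]])
  val <- expr
  streams$states[[name]] <- get(".Random.seed", envir = globalenv())
  val
}

#' Snapshot / restore stream states (for checkpointing)
#' @param streams An [rng_streams()] object.
#' @return A plain list of integer state vectors.
#' @keywords internal
rng_snapshot <- function(streams) {
  list(seed = streams$seed, states = streams$states)
}

rng_restore <- function(snapshot) {
  e <- new.env(parent = emptyenv())
  e$seed <- snapshot$seed
  e$states <- lapply(snapshot$states, as.integer)
  class(e) <- "rng_streams"
  e
}
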