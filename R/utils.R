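# Internal helpers: condition signalling and seed-threading.

# maximum crossplane half-field at isocenter for the MLCi2-like geometry (cm)
.max_crossplane_cm <- 13.5

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "arcqa_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate an expression under a local random seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's
#' `.Random.seed` afterwards, so package functions neither consume nor leak
#' global random state. All stochastic `arcqa` functions thread explicit
#' seeds through this helper.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer", "arcqa_config_error")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# format a numeric vector for messages
fmt_idx <- function(i) paste(i, collapse = ", ")
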