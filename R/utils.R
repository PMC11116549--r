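# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used by the
#' package's printed tables), as opposed to [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (may be negative).
#' @return numeric vector of the same length.
#' @examples
#' round_half_up(2.5, 0)   # 3
#' round_half_up(0.125, 2) # 0.13
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness flows through this
# single stream so that a seed fully determines every draw.
local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Stop with a labelled error class (condition-friendly contracts).
stop_drc <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "drcausal_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
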