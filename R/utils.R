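# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Mixes a master integer seed with a stage label into a new seed below
#' 2^31, so that pipeline stages are independently re-runnable yet fully
#' determined by one top-level seed.
#'
#' @param master Integer master seed.
#' @param stage Character stage label (e.g. `"simulate"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "simulate")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 17
  for (ch in utf8ToInt(stage)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  # both terms < 2^48, safe in double arithmetic
  as.integer((h * 69621 + abs(as.double(master))) %% 2147483647)
}

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Population (not sample) standard deviation.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Root mean square of a vector.
rms <- function(x) sqrt(mean(x^2))

stop_respmark <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "respmark_error")))
}
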