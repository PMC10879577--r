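# Deterministic seed derivation and schedule drawing primitives.
#
# All stochastic components of a run (travel schedules, batch shuffles, dropout
# masks, phantom noise) are driven by 31-bit seeds derived from a master seed
# plus a path of labels (cycle index, center id, local epoch, ...). The hash is
# a polynomial rolling hash modulo the Mersenne prime 2^31 - 1, computed in
# double arithmetic (31 * h + byte < 2^36 stays exact in doubles), so seeds are
# reproducible across platforms and documented enough to replay by hand.

.HASH_MOD <- 2147483647  # 2^31 - 1

#' Derive a reproducible 31-bit seed from a path of labels
#'
#' Combines a master seed and any number of string/integer components into a
#' seed in `[1, 2^31 - 2]` via a polynomial rolling hash (base 31, modulo the
#' Mersenne prime `2^31 - 1`) over the UTF-8 bytes of the components joined
#' with `"/"`. Used to give every schedule draw, batch shuffle, dropout mask
#' and phantom an independent, replayable random stream.
#'
#' @param ... seed components (coerced to character); the first is normally a
#'   master seed.
#' @return an integer seed, never 0.
#' @examples
#' derive_seed(42, "cycle", 3, "centerA")
#' @export
derive_seed <- function(...) {
  parts <- vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                  character(1))
  key <- paste(parts, collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (31 * h + b) %% .HASH_MOD
  as.integer(h %% (.HASH_MOD - 2) + 1)
}

# Fisher-Yates shuffle driven by R's RNG under a stated seed. `x` is returned
# in a permuted order that depends only on `seed` (and the order of `x`).
fisher_yates <- function(x, seed) {
  n <- length(x)
  if (n <= 1L) return(x)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  for (i in n:2) {
    j <- 1L + floor(runif(1) * i)  # uniform on 1..i
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  x
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds R's RNG with `seed`, evaluates `expr`, and restores the caller's RNG
#' state afterwards, so seeded library internals never perturb user-level
#' random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("travelnet_config_error", "error")))
}
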