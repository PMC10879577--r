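# Adam optimizer over the nested parameter list.
#
# State = first/second moment estimates with the same shapes as the
# parameters, plus the step counter t. The update (with bias correction):
#   m <- b1 m + (1-b1) g;  v <- b2 v + (1-b2) g^2
#   p <- p - lr * (m / (1-b1^t)) / (sqrt(v / (1-b2^t)) + eps)
# The state is a first-class value so it can travel with the model from
# center to center (or be reset, when that variant is requested).

map_leaves <- function(x, f) {
  if (is.list(x)) lapply(x, map_leaves, f = f) else f(x)
}

map2_leaves <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- map2_leaves(x[[i]], y[[i]], f)
    out
  } else {
    f(x, y)
  }
}

#' Fresh Adam optimizer state for a parameter list
#'
#' @param params a model parameter list (see [build_model()]).
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return list with zeroed moments `m`, `v`, step counter `t = 0`, and the
#'   hyperparameters.
#' @export
adam_state <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- map_leaves(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

#' One Adam step
#'
#' @param params parameter list.
#' @param grads gradient list with the same structure.
#' @param state Adam state from [adam_state()] or a previous step.
#' @param lr learning rate for this step.
#' @return list with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, lr) {
  t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2; eps <- state$eps
  m <- map2_leaves(state$m, grads, function(m, g) b1 * m + (1 - b1) * g)
  v <- map2_leaves(state$v, grads, function(v, g) b2 * v + (1 - b2) * g^2)
  bc1 <- 1 - b1^t
  bc2 <- 1 - b2^t
  step <- map2_leaves(m, v, function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_leaves(params, step, function(p, s) p - s)
  list(params = params, state = list(m = m, v = v, t = t,
                                     beta1 = b1, beta2 = b2, eps = eps))
}
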