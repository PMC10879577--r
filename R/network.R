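# Configurable scaled-down fully convolutional 3D classifier.
#
# Topology: n_conv_blocks of [3x3x3 conv (pad 1) -> instance norm -> ReLU ->
# 2x average pooling (floor)], dropout on the flattened features, one linear
# layer to 2 logits, softmax score for the disease class. The numerical
# forward/backward passes live in src/cnn.cpp; this file owns configuration,
# seeded initialization and prediction.

#' Network configuration
#'
#' @param grid input grid size per axis (volumes are `grid^3`).
#' @param channels integer vector, output channels of each conv block; its
#'   length is the number of blocks. Default 4 blocks of 8/16/32/32.
#' @param dropout_rate dropout probability applied to the flattened features
#'   (before the linear head), active during training only. Default 0.20.
#' @param init_seed seed for reproducible weight initialization.
#' @return object of class `model_config`.
#' @export
model_config <- function(grid = 24L, channels = c(8L, 16L, 32L, 32L),
                         dropout_rate = 0.2, init_seed = 1L) {
  grid <- as.integer(grid)
  channels <- as.integer(channels)
  if (length(channels) < 1L || any(channels < 1L)) {
    stop_config("channels must be a nonempty positive integer vector")
  }
  if (!(dropout_rate >= 0 && dropout_rate < 1)) {
    stop_config("dropout_rate must be in [0, 1)")
  }
  if (grid < 8L) stop_config("grid must be >= 8")
  d <- grid
  for (k in seq_along(channels)) {
    d <- d %/% 2L
    if (d < 1L) stop_config("grid ", grid, " collapses below 1 voxel after ",
                            k, " blocks; use fewer blocks or a larger grid")
  }
  structure(list(grid = grid, channels = channels, dropout_rate = dropout_rate,
                 n_classes = 2L, init_seed = as.integer(init_seed)),
            class = "model_config")
}

# Per-block input/output channel and grid bookkeeping.
net_shape <- function(config) {
  nb <- length(config$channels)
  c_in <- c(1L, config$channels[-nb])
  d <- config$grid
  d_out <- integer(nb)
  for (k in seq_len(nb)) {
    d <- d %/% 2L
    d_out[k] <- d
  }
  list(n_blocks = nb, c_in = c_in, c_out = config$channels,
       d_out = d_out, feat = config$channels[nb] * d_out[nb]^3)
}

#' Number of trainable parameters implied by a configuration
#'
#' Closed form: `sum_k (27 c_in[k] c_out[k] + c_out[k]) + 2 feat + 2`,
#' where `feat` is the flattened feature length after the last pooling.
#'
#' @param config a `model_config` (or a `tm_model`).
#' @return integer parameter count.
#' @export
n_params <- function(config) {
  if (inherits(config, "tm_model")) config <- config$config
  s <- net_shape(config)
  sum(27L * s$c_in * s$c_out + s$c_out) + 2L * s$feat + 2L
}

#' Build a model with seeded He initialization
#'
#' Conv kernels are drawn `N(0, 2 / (27 c_in))`, the linear head
#' `N(0, 2 / feat)`, biases zero, all from a single RNG stream seeded with
#' `config$init_seed` (blocks first, in order, then the head), so the same
#' configuration and seed always yield identical initial parameters.
#'
#' @param config a `model_config`.
#' @return object of class `tm_model` (`params`, `config`).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  s <- net_shape(config)
  with_seed(config$init_seed, {
    conv_w <- vector("list", s$n_blocks)
    conv_b <- vector("list", s$n_blocks)
    for (k in seq_len(s$n_blocks)) {
      fan_in <- 27L * s$c_in[k]
      conv_w[[k]] <- matrix(rnorm(fan_in * s$c_out[k], sd = sqrt(2 / fan_in)),
                            nrow = fan_in, ncol = s$c_out[k])
      conv_b[[k]] <- numeric(s$c_out[k])
    }
    fc_w <- matrix(rnorm(s$feat * 2L, sd = sqrt(2 / s$feat)), nrow = s$feat, ncol = 2L)
    structure(list(params = list(conv_w = conv_w, conv_b = conv_b,
                                 fc_w = fc_w, fc_b = numeric(2L)),
                   config = config),
              class = "tm_model")
  })
}

#' @export
print.tm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<tm_model> %d conv blocks (channels %s), grid %d^3, dropout %.2f, %s parameters\n",
              length(cfg$channels), paste(cfg$channels, collapse = "/"),
              cfg$grid, cfg$dropout_rate, format(n_params(cfg), big.mark = ",")))
  invisible(x)
}

# Per-volume z-scoring applied before the network; constant volumes map to 0.
normalize_volumes <- function(x) {
  mu <- colMeans(x)
  sdv <- sqrt(pmax(colMeans(x^2) - mu^2, 0))
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

#' Disease scores for a set of volumes
#'
#' Runs the network in evaluation mode (dropout disabled) and returns the
#' softmax probability of the disease class for each volume. Volumes are
#' z-scored per volume before entering the network. Deterministic, and
#' invariant to how volumes are grouped into batches.
#'
#' @param model a `tm_model`.
#' @param volumes a `volume_set` (see [render_cohort()]) or a numeric matrix
#'   with one `grid^3` volume per column.
#' @param ids for a `volume_set`, the participant ids to score (default all).
#' @return numeric vector of scores in `[0, 1]`, named by participant id when
#'   available.
#' @export
predict_scores <- function(model, volumes, ids = NULL) {
  stopifnot(inherits(model, "tm_model"))
  x <- as_volume_matrix(volumes, ids)
  scores <- cnn_batch_predict_cpp(model$params, model$config, normalize_volumes(x))
  setNames(as.numeric(scores), colnames(x))
}

as_volume_matrix <- function(volumes, ids = NULL) {
  if (inherits(volumes, "volume_set")) {
    x <- volumes$x
    if (!is.null(ids)) {
      missing <- setdiff(ids, colnames(x))
      if (length(missing) > 0L) stop("unknown participant id(s): ",
                                     paste(head(missing, 5), collapse = ", "))
      x <- x[, ids, drop = FALSE]
    }
    x
  } else if (is.matrix(volumes)) {
    volumes
  } else {
    stop("volumes must be a volume_set or a matrix (one volume per column)")
  }
}

#' Save / load a training checkpoint
#'
#' A checkpoint bundles the model (parameters + configuration) and the Adam
#' optimizer state in a single archive so a traveling run can be resumed at
#' any cycle boundary.
#'
#' @param model a `tm_model`.
#' @param opt_state an Adam state as returned by [adam_state()] / updates.
#' @param path file path for the archive.
#' @param extra optional named list of run metadata stored alongside.
#' @return `path` invisibly (for `save_checkpoint`); a list with `model`,
#'   `opt_state`, `extra` (for `load_checkpoint`).
#' @export
save_checkpoint <- function(model, opt_state, path, extra = list()) {
  saveRDS(list(model = model, opt_state = opt_state, extra = extra,
               package_version = as.character(utils::packageVersion("travelnet"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck$model, "tm_model"))
  ck[c("model", "opt_state", "extra")]
}
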