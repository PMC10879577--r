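# Traveling-model training loop and its centralized baseline.
#
# In the traveling setup a single model visits every training center once per
# cycle in a scheduled order, trains for `local_epochs` passes over the local
# data at each stop, and carries both its weights and its Adam optimizer
# state to the next center. The pooled test set is evaluated at the end of
# each cycle. The centralized baseline trains on the globally shuffled pooled
# training set (treated as a single virtual center named "pooled") with
# early stopping on the pooled test loss.
#
# Every source of randomness is a derived seed:
#   schedule, cycle i: base_seed (fixed mode) or base_seed + (i-1) (random)
#   batch shuffle:     derive_seed(data_seed, "shuffle", cycle, center_id, epoch)
#   dropout, batch j:  derive_seed(shuffle_seed, "dropout", j)
# so runs are bit-reproducible, and a traveling run over a single center
# named "pooled" replays exactly the centralized update sequence.

.POOLED_CENTER <- "pooled"

#' Travel-schedule policy
#'
#' `fixed` mode draws one permutation with `base_seed` and reuses it every
#' cycle; `random` mode redraws the permutation each cycle with seed
#' `base_seed + (cycle - 1)` — cycle 1 uses the base seed itself, emulating
#' the batch-shuffling of centralized training at the center level.
#'
#' @param mode `"fixed"` or `"random"`.
#' @param base_seed initial schedule seed (default 42).
#' @return object of class `schedule_policy`.
#' @export
schedule_policy <- function(mode = c("random", "fixed"), base_seed = 42L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, base_seed = as.integer(base_seed)),
            class = "schedule_policy")
}

#' Center visiting order for one cycle
#'
#' Returns a permutation of `center_ids` drawn by a Fisher-Yates shuffle of
#' the lexicographically sorted center ids, under the policy's seed rule.
#' Fixed mode yields the same permutation for every cycle; random mode yields
#' a reproducible per-cycle permutation (seeds `base, base+1, base+2, ...`).
#'
#' @param center_ids character vector of training centers.
#' @param policy a `schedule_policy`.
#' @param cycle_index 1-based cycle number.
#' @return permutation of `center_ids`.
#' @export
make_travel_schedule <- function(center_ids, policy, cycle_index = 1L) {
  if (length(center_ids) == 0L) stop("no centers to schedule")
  stopifnot(inherits(policy, "schedule_policy"), cycle_index >= 1L)
  seed <- if (policy$mode == "fixed") policy$base_seed
          else policy$base_seed + (as.integer(cycle_index) - 1L)
  fisher_yates(sort(center_ids), seed)
}

#' Partition a center's records into training batches
#'
#' Effective batch size is `min(batch_size_cap, n)` — a center with fewer
#' samples than the cap contributes a single smaller batch. Records are
#' shuffled with `shuffle_seed` (Fisher-Yates) and chunked in order; the
#' final partial batch is kept, so every record appears in exactly one batch.
#'
#' @param record_ids vector of participant ids at the center.
#' @param batch_size_cap maximal batch size (default 5).
#' @param shuffle_seed seed for the shuffle.
#' @return list of id vectors.
#' @export
make_batches <- function(record_ids, batch_size_cap = 5L, shuffle_seed = 1L) {
  n <- length(record_ids)
  if (n == 0L) stop("empty record list")
  eff <- min(batch_size_cap, n)
  shuffled <- fisher_yates(record_ids, shuffle_seed)
  split(shuffled, ceiling(seq_len(n) / eff))
}

#' Training configuration
#'
#' @param paradigm `"traveling"` or `"centralized"`.
#' @param initial_lr initial Adam learning rate; defaults to 0.0001 for the
#'   traveling paradigm (small centers need small steps) and 0.001 for the
#'   centralized baseline.
#' @param lr_decay_factor per-cycle (traveling) / per-epoch (centralized)
#'   exponential decay of the learning rate.
#' @param batch_size_cap per-center batch size cap (default 5).
#' @param local_epochs passes over a center's data per visit (traveling only).
#' @param max_cycles maximum cycles/epochs (default 30).
#' @param early_stopping_patience centralized only: stop when the pooled test
#'   loss has not improved for this many epochs (default 10); `Inf` disables.
#' @param schedule a [schedule_policy()] (traveling only).
#' @param data_seed seed driving all batch shuffles and dropout masks.
#' @param reset_optimizer_per_center if `TRUE`, the Adam moments are zeroed at
#'   every center boundary instead of traveling with the model (a deliberately
#'   different algorithm, off by default).
#' @return object of class `train_config`.
#' @export
train_config <- function(paradigm = c("traveling", "centralized"),
                         initial_lr = NULL, lr_decay_factor = 0.97,
                         batch_size_cap = 5L, local_epochs = 1L,
                         max_cycles = 30L, early_stopping_patience = 10L,
                         schedule = schedule_policy("random"),
                         data_seed = 1L, reset_optimizer_per_center = FALSE) {
  paradigm <- match.arg(paradigm)
  initial_lr <- initial_lr %||% if (paradigm == "traveling") 1e-4 else 1e-3
  if (!(lr_decay_factor > 0 && lr_decay_factor <= 1)) {
    stop_config("lr_decay_factor must be in (0, 1]")
  }
  if (local_epochs < 1L) stop_config("local_epochs must be >= 1")
  if (max_cycles < 0L) stop_config("max_cycles must be >= 0")
  structure(list(paradigm = paradigm, initial_lr = initial_lr,
                 lr_decay_factor = lr_decay_factor,
                 batch_size_cap = as.integer(batch_size_cap),
                 local_epochs = as.integer(local_epochs),
                 max_cycles = as.integer(max_cycles),
                 early_stopping_patience = early_stopping_patience,
                 schedule = schedule, data_seed = as.integer(data_seed),
                 reset_optimizer_per_center = isTRUE(reset_optimizer_per_center)),
            class = "train_config")
}

#' Train a model on one center's data for its local visit
#'
#' Performs `local_epochs` passes over the center's records with Adam at the
#' given learning rate. Each pass shuffles the records with its own seed from
#' `epoch_seeds` and chunks them into batches of at most `batch_size_cap`;
#' dropout masks are derived per batch. The optimizer state persists into the
#' returned state, so calling this twice with `local_epochs = 1` and carried
#' state equals one call with `local_epochs = 2` when the per-epoch seeds
#' match.
#'
#' @param model a `tm_model`.
#' @param opt_state Adam state.
#' @param volumes a `volume_set` containing (at least) the center's records.
#' @param record_ids participant ids at the center.
#' @param local_epochs passes over the local data.
#' @param lr learning rate used for every step of this visit.
#' @param batch_size_cap maximal batch size.
#' @param epoch_seeds integer vector of length `local_epochs`, one shuffle
#'   seed per pass.
#' @param exposure optional environment with a named `counts` vector,
#'   incremented once per record per pass (data-exposure instrumentation).
#' @return list: `model`, `opt_state`, `mean_loss` (mean training loss over
#'   all samples of the visit).
#' @export
local_update <- function(model, opt_state, volumes, record_ids, local_epochs,
                         lr, batch_size_cap = 5L,
                         epoch_seeds = seq_len(local_epochs),
                         exposure = NULL) {
  if (length(record_ids) == 0L) stop("empty center: no records to train on")
  stopifnot(length(epoch_seeds) == local_epochs)
  labels <- volume_labels(volumes)
  loss_sum <- 0
  n_seen <- 0L
  params <- model$params
  for (e in seq_len(local_epochs)) {
    batches <- make_batches(record_ids, batch_size_cap, epoch_seeds[e])
    for (j in seq_along(batches)) {
      ids <- batches[[j]]
      x <- normalize_volumes(as_volume_matrix(volumes, ids))
      out <- cnn_batch_grad_cpp(params, model$config, x,
                                as.integer(labels[ids]),
                                model$config$dropout_rate,
                                derive_seed(epoch_seeds[e], "dropout", j))
      if (!is.finite(out$loss)) {
        stop("non-finite training loss at batch ", j, " (lr = ", lr,
             "); aborting")
      }
      stepped <- adam_step(params, out$grads, opt_state, lr)
      params <- stepped$params
      opt_state <- stepped$state
      loss_sum <- loss_sum + out$loss * length(ids)
      n_seen <- n_seen + length(ids)
      if (!is.null(exposure)) {
        exposure$counts[ids] <- exposure$counts[ids] + 1L
      }
    }
  }
  model$params <- params
  list(model = model, opt_state = opt_state, mean_loss = loss_sum / n_seen)
}

train_center_ids <- function(split_cohort) {
  groups <- center_groups(split_cohort$train)
  names(groups)[lengths(groups) > 0L]
}

# Per-cycle AUROC needs both classes in the pooled test set; fail before any
# compute with a message pointing at the cohort/split seeds.
check_test_pool <- function(volumes, test_ids) {
  labels <- volume_labels(volumes)[test_ids]
  if (length(test_ids) == 0L || length(unique(labels)) < 2L) {
    stop("pooled test set contains a single class (", sum(labels == 1),
         " positive / ", sum(labels == 0), " negative); per-cycle AUROC ",
         "would be undefined - adjust the cohort or split seed")
  }
  invisible(TRUE)
}

history_row <- function(cycle, eval, train_loss, lr, schedule) {
  data.frame(cycle = cycle, auroc = eval$auroc, test_loss = eval$mean_loss,
             train_loss = train_loss, lr = lr,
             schedule = paste(schedule, collapse = "|"),
             stringsAsFactors = FALSE)
}

finish_history <- function(rows, model, opt_state, exposure, best = NA_integer_) {
  h <- if (length(rows) == 0L) {
    data.frame(cycle = integer(), auroc = numeric(), test_loss = numeric(),
               train_loss = numeric(), lr = numeric(), schedule = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  structure(h, model = model, opt_state = opt_state,
            exposure = exposure$counts, best_cycle = best,
            class = c("tm_history", "data.frame"))
}

#' Traveling-model training
#'
#' Runs up to `config$max_cycles` cycles. Each cycle draws the travel
#' schedule from the policy, visits every training center in that order via
#' [local_update()] — model and optimizer state carried from center to center
#' and across cycles — then evaluates the pooled test set. The learning rate
#' decays exponentially once per full cycle (the traveling analog of an
#' epoch).
#'
#' @param initial_model a `tm_model`.
#' @param split_cohort a `split_cohort`.
#' @param volumes a `volume_set` covering all train and test participants.
#' @param config a `train_config` with `paradigm = "traveling"`.
#' @param checkpoint_dir optional directory for per-cycle checkpoints.
#' @param verbose print a line per cycle.
#' @return a `tm_history` data.frame (one row per cycle: `cycle`, `auroc`,
#'   `test_loss`, `train_loss`, `lr`, `schedule`) with the final model,
#'   optimizer state and per-sample exposure counts as attributes.
#' @export
run_traveling <- function(initial_model, split_cohort, volumes, config,
                          checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (config$paradigm != "traveling") stop("config paradigm is not 'traveling'")
  centers <- train_center_ids(split_cohort)
  if (length(centers) == 0L) stop("no training centers")
  groups <- center_groups(split_cohort$train)
  test_ids <- split_cohort$test$participant_id
  if (config$max_cycles > 0L) check_test_pool(volumes, test_ids)
  exposure <- new.env(parent = emptyenv())
  exposure$counts <- setNames(integer(nrow(split_cohort$train)),
                              split_cohort$train$participant_id)
  model <- initial_model
  opt_state <- adam_state(model$params)
  rows <- list()
  for (cycle in seq_len(config$max_cycles)) {
    lr <- config$initial_lr * config$lr_decay_factor^(cycle - 1)
    sched <- make_travel_schedule(centers, config$schedule, cycle)
    loss_sum <- 0
    n_seen <- 0L
    for (cid in sched) {
      ids <- split_cohort$train$participant_id[groups[[cid]]]
      if (config$reset_optimizer_per_center) opt_state <- adam_state(model$params)
      seeds <- vapply(seq_len(config$local_epochs), function(e) {
        derive_seed(config$data_seed, "shuffle", cycle, cid, e)
      }, integer(1))
      upd <- local_update(model, opt_state, volumes, ids, config$local_epochs,
                          lr, config$batch_size_cap, seeds, exposure)
      model <- upd$model
      opt_state <- upd$opt_state
      loss_sum <- loss_sum + upd$mean_loss * length(ids) * config$local_epochs
      n_seen <- n_seen + length(ids) * config$local_epochs
    }
    ev <- eval_model(model, volumes, ids = test_ids)
    rows[[cycle]] <- history_row(cycle, ev, loss_sum / n_seen, lr, sched)
    if (verbose) {
      message(sprintf("cycle %2d: AUROC %.4f test loss %.4f lr %.2e",
                      cycle, ev$auroc, ev$mean_loss, lr))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(model, opt_state,
                      file.path(checkpoint_dir, sprintf("cycle_%03d.rds", cycle)),
                      extra = list(cycle = cycle))
    }
  }
  finish_history(rows, model, opt_state, exposure)
}

#' Centralized baseline training
#'
#' Trains on the pooled, globally shuffled training set (one virtual center
#' named `"pooled"`), evaluating the pooled test set after every epoch, with
#' exponential learning-rate decay per epoch and early stopping: training
#' halts once the test loss has not improved for
#' `config$early_stopping_patience` epochs (or at `max_cycles`). The epoch
#' with the lowest test loss is recorded as the best.
#'
#' @inheritParams run_traveling
#' @param config a `train_config` with `paradigm = "centralized"`.
#' @param eval_fn evaluation hook called as `eval_fn(model, volumes, ids)`
#'   after every epoch; defaults to [eval_model()]. Exposed so the stopping
#'   rule can be exercised against a scripted loss sequence.
#' @return a `tm_history` (one row per completed epoch) whose `best_cycle`
#'   attribute marks the lowest-test-loss epoch.
#' @export
run_centralized <- function(initial_model, split_cohort, volumes, config,
                            checkpoint_dir = NULL, verbose = FALSE,
                            eval_fn = eval_model) {
  stopifnot(inherits(config, "train_config"))
  if (config$paradigm != "centralized") stop("config paradigm is not 'centralized'")
  train_ids <- split_cohort$train$participant_id
  if (length(train_ids) == 0L) stop("empty training pool")
  test_ids <- split_cohort$test$participant_id
  if (config$max_cycles > 0L && identical(eval_fn, eval_model)) {
    check_test_pool(volumes, test_ids)
  }
  exposure <- new.env(parent = emptyenv())
  exposure$counts <- setNames(integer(length(train_ids)), train_ids)
  model <- initial_model
  opt_state <- adam_state(model$params)
  patience <- config$early_stopping_patience
  best_loss <- Inf
  best_epoch <- 0L
  rows <- list()
  for (epoch in seq_len(config$max_cycles)) {
    lr <- config$initial_lr * config$lr_decay_factor^(epoch - 1)
    seed <- derive_seed(config$data_seed, "shuffle", epoch, .POOLED_CENTER, 1L)
    upd <- local_update(model, opt_state, volumes, train_ids, 1L, lr,
                        config$batch_size_cap, seed, exposure)
    model <- upd$model
    opt_state <- upd$opt_state
    ev <- eval_fn(model, volumes, test_ids)
    rows[[epoch]] <- history_row(epoch, ev, upd$mean_loss, lr, .POOLED_CENTER)
    if (verbose) {
      message(sprintf("epoch %2d: AUROC %.4f test loss %.4f lr %.2e",
                      epoch, ev$auroc, ev$mean_loss, lr))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(model, opt_state,
                      file.path(checkpoint_dir, sprintf("epoch_%03d.rds", epoch)),
                      extra = list(epoch = epoch))
    }
    if (ev$mean_loss < best_loss) {
      best_loss <- ev$mean_loss
      best_epoch <- epoch
    }
    if (is.finite(patience) && (epoch - best_epoch) >= patience) break
  }
  finish_history(rows, model, opt_state, exposure, best = best_epoch)
}

#' @export
print.tm_history <- function(x, ...) {
  cat(sprintf("<tm_history> %d cycles", nrow(x)))
  if (nrow(x) > 0L) {
    b <- best_cycle(x)
    cat(sprintf("; final AUROC %.4f, best cycle %d (AUROC %.4f, loss %.4f)",
                x$auroc[nrow(x)], b$cycle, b$auroc, b$test_loss))
  }
  cat("\n")
  invisible(x)
}

#' Write / read a training history CSV
#'
#' Columns: `cycle,auroc,test_loss,train_loss,lr,schedule` (schedule is the
#' `|`-joined center visit order of the cycle).
#'
#' @param history a `tm_history`.
#' @param path CSV path.
#' @return `path` invisibly / a `tm_history` without model attributes.
#' @export
write_history <- function(history, path) {
  utils::write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  h <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cycle", "auroc", "test_loss", "lr", "schedule")
  missing <- setdiff(needed, names(h))
  if (length(missing) > 0L) {
    stop("malformed history CSV '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  }
  class(h) <- c("tm_history", "data.frame")
  h
}
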