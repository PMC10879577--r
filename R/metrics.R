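# Threshold-independent evaluation: AUROC (Mann-Whitney rank form), pooled
# loss, cycle-stability index, and best-cycle selection.

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' Computes the probability that a randomly chosen positive case receives a
#' higher score than a randomly chosen negative case, with ties counted 1/2 —
#' the threshold-independent separability of the two classes. Implemented via
#' midranks: `AUROC = (sum of positive ranks - n_pos(n_pos+1)/2) / (n_pos n_neg)`.
#'
#' @param scores numeric vector of classifier scores (higher = more positive).
#' @param labels binary vector (0 = negative/healthy, 1 = positive/disease).
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))  # 1: perfect separation
#' auroc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length")
  }
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels contain NA")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop(errorCondition("AUROC undefined: need at least one positive and one negative label",
                        class = c("travelnet_auroc_undefined", "error")))
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cycle-to-cycle instability index of an AUROC series
#'
#' Standard deviation of the successive differences of the last `window`
#' values of a per-cycle metric series. Zero for a constant series; grows with
#' the cycle-to-cycle "wobble" that distinguishes an unstable traveling run
#' from a smooth one. Homogeneous of degree 1: scaling the series by `c`
#' scales the index by `|c|`.
#'
#' @param auroc_series numeric vector, one value per cycle (length >= 2).
#' @param window number of trailing values to use; default the full series.
#' @return nonnegative scalar (0 when only one difference is available).
#' @export
instability_index <- function(auroc_series, window = length(auroc_series)) {
  n <- length(auroc_series)
  if (n < 2L) stop("need a series of length >= 2")
  if (window > n) stop("window exceeds series length")
  if (window < 2L) stop("window must be >= 2")
  d <- diff(tail(auroc_series, window))
  if (length(d) == 1L) return(0)
  stats::sd(d)
}

#' Cycle with the lowest pooled test loss
#'
#' Selects the checkpoint a practitioner would keep: the cycle (or epoch)
#' whose pooled test loss is minimal, earliest cycle on ties.
#'
#' @param history a `tm_history` (or any data.frame with `cycle`, `test_loss`,
#'   `auroc` columns).
#' @return list with `cycle`, `test_loss`, `auroc` at the argmin.
#' @export
best_cycle <- function(history) {
  h <- as.data.frame(history)
  if (nrow(h) == 0L) stop("empty history")
  i <- which.min(h$test_loss)  # which.min takes the earliest on ties
  list(cycle = h$cycle[i], test_loss = h$test_loss[i], auroc = h$auroc[i])
}

#' Evaluate a model on a labeled volume set
#'
#' Runs the network in evaluation mode (dropout off) on all volumes and
#' returns pooled AUROC, mean cross-entropy loss, and class counts.
#'
#' @param model a `tm_model`.
#' @param volumes a `volume_set` (see [render_cohort()]).
#' @param ids participant ids to evaluate (default: all in `volumes`).
#' @return list of class `eval_result`: `auroc`, `mean_loss`, `n_pos`, `n_neg`.
#' @export
eval_model <- function(model, volumes, ids = NULL) {
  ids <- ids %||% volume_ids(volumes)
  labels <- volume_labels(volumes)[ids]
  scores <- predict_scores(model, volumes, ids = ids)
  p <- pmin(pmax(ifelse(labels == 1, scores, 1 - scores), 1e-12), 1)
  structure(
    list(auroc = auroc(scores, labels),
         mean_loss = mean(-log(p)),
         n_pos = sum(labels == 1), n_neg = sum(labels == 0)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("AUROC %.4f | mean loss %.4f | %d pos / %d neg\n",
              x$auroc, x$mean_loss, x$n_pos, x$n_neg))
  invisible(x)
}
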