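# Shared fixtures: small cohorts, volume sets and model configs built in code.

# A cohort with fixed per-center sizes and a constant disease fraction.
fixture_cohort <- function(sizes = c(10L, 6L), label_fraction = 0.5, seed = 11L) {
  build_cohort(cohort_spec(
    center_size_profile = list(list(name = "fx", n_centers = length(sizes),
                                    size_sampler = function(n) sizes)),
    label_fraction_sampler = function(n) rep(label_fraction, n),
    master_seed = seed
  ))
}

# Render a cohort at a small grid with mild noise (fast, learnable).
fixture_volumes <- function(cohort, grid = 16L, seed = 5L, ...) {
  render_cohort(cohort, phantom_spec(grid_size = grid, master_seed = seed, ...))
}

fixture_model <- function(grid = 16L, channels = c(4L, 8L), seed = 1L,
                          dropout = 0.2) {
  build_model(model_config(grid = grid, channels = channels,
                           dropout_rate = dropout, init_seed = seed))
}

# Hand-rolled pairwise AUROC oracle: P(score_pos > score_neg) + 0.5 P(tie).
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Independent Fisher-Yates replay used as the schedule oracle.
fisher_yates_oracle <- function(x, seed) {
  set.seed(seed)
  n <- length(x)
  if (n <= 1) return(x)
  for (i in n:2) {
    j <- 1 + floor(runif(1) * i)
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  x
}
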