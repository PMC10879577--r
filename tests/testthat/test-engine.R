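# Helper: a cohort whose single center is literally the pooled virtual center,
# so the traveling loop and the centralized loop derive identical seeds.
make_pooled_split <- function(n = 8L, seed = 3L) {
  with_seed(seed, {
    rec <- data.frame(
      participant_id = sprintf("p%02d", 1:n), center_id = "pooled",
      label = rep(c(0L, 1L), length.out = n), sex = sample(c("M", "F"), n, TRUE),
      age_years = round(runif(n, 40, 85), 1), vendor = "Siemens",
      field_strength_tesla = 3.0, split = rep(c("train", "test"),
                                              c(n - 2L, 2L)),
      stringsAsFactors = FALSE
    )
  })
  travelnet:::make_split_cohort(as_cohort(rec))
}

test_that("fixed schedules repeat one seeded permutation; random schedules follow 42,43,...", {
  ids <- c("ctr_b", "ctr_a", "ctr_d", "ctr_c")
  fx <- schedule_policy("fixed", base_seed = 42L)
  rd <- schedule_policy("random", base_seed = 42L)

  s1 <- make_travel_schedule(ids, fx, 1L)
  expect_identical(s1, make_travel_schedule(ids, fx, 7L))
  expect_identical(s1, fisher_yates_oracle(sort(ids), 42L))

  for (cyc in c(1L, 2L, 5L)) {
    expect_identical(make_travel_schedule(ids, rd, cyc),
                     fisher_yates_oracle(sort(ids), 42L + cyc - 1L))
  }
  # reproducible: re-drawing the same cycles yields the same pair
  expect_identical(lapply(1:2, function(c) make_travel_schedule(ids, rd, c)),
                   lapply(1:2, function(c) make_travel_schedule(ids, rd, c)))
  # legality: always a permutation of all centers
  set.seed(1)
  for (i in 1:20) {
    k <- sample(1:30, 1)
    cids <- paste0("c", sample(1e6, k))
    expect_setequal(make_travel_schedule(cids, rd, sample(30, 1)), cids)
  }
  expect_identical(make_travel_schedule("solo", rd, 3L), "solo")
  expect_error(make_travel_schedule(character(0), rd, 1L), "no centers")
})

test_that("batching caps at min(cap, n), keeps the partial batch, and covers every record once", {
  b <- make_batches(paste0("r", 1:3), batch_size_cap = 5L, shuffle_seed = 1L)
  expect_length(b, 1L)
  expect_length(b[[1]], 3L)

  b2 <- make_batches(paste0("r", 1:12), batch_size_cap = 5L, shuffle_seed = 2L)
  expect_equal(unname(lengths(b2)), c(5L, 5L, 2L))

  set.seed(9)
  for (i in 1:100) {
    n <- sample(1:40, 1)
    ids <- paste0("x", sample(1e6, n))
    bb <- make_batches(ids, 5L, i)
    expect_setequal(unlist(bb), ids)
    expect_equal(length(unlist(bb)), n)  # no duplicates
  }
})

test_that("two single-epoch visits with carried state equal one two-epoch visit", {
  m <- fixture_model(grid = 16L, channels = c(2L, 4L))
  co <- fixture_cohort(sizes = 7L, seed = 2L)
  vs <- fixture_volumes(co)
  ids <- volume_ids(vs)
  st <- adam_state(m$params)
  once <- local_update(m, st, vs, ids, local_epochs = 2L, lr = 1e-3,
                       epoch_seeds = c(101L, 202L))
  step1 <- local_update(m, st, vs, ids, local_epochs = 1L, lr = 1e-3,
                        epoch_seeds = 101L)
  step2 <- local_update(step1$model, step1$opt_state, vs, ids, local_epochs = 1L,
                        lr = 1e-3, epoch_seeds = 202L)
  expect_identical(once$model$params, step2$model$params)
  expect_identical(once$opt_state, step2$opt_state)
})

test_that("traveling over one center reproduces centralized training bit-for-bit", {
  tiny_configs <- list(
    list(channels = c(2L, 2L), n = 6L, seed = 11L, lr = 1e-3),
    list(channels = c(3L, 4L), n = 9L, seed = 12L, lr = 5e-4),
    list(channels = c(2L, 4L), n = 12L, seed = 13L, lr = 1e-3)
  )
  for (tc in tiny_configs) {
    sp <- make_pooled_split(n = tc$n, seed = tc$seed)
    full <- as_cohort(rbind(as.data.frame(sp$train), as.data.frame(sp$test)))
    vs <- render_cohort(full, phantom_spec(grid_size = 16L, master_seed = tc$seed))
    m0 <- fixture_model(grid = 16L, channels = tc$channels, seed = tc$seed)
    trav <- run_traveling(m0, sp, vs, train_config(
      "traveling", initial_lr = tc$lr, max_cycles = 3L, local_epochs = 1L,
      schedule = schedule_policy("fixed"), data_seed = tc$seed))
    cent <- run_centralized(m0, sp, vs, train_config(
      "centralized", initial_lr = tc$lr, max_cycles = 3L,
      early_stopping_patience = Inf, data_seed = tc$seed))
    expect_identical(attr(trav, "model")$params, attr(cent, "model")$params)
    expect_identical(trav$auroc, cent$auroc)
    expect_identical(trav$test_loss, cent$test_loss)
  }
})

test_that("zero cycles returns an empty history and an unchanged model", {
  sp <- make_pooled_split()
  vs <- render_cohort(as_cohort(rbind(as.data.frame(sp$train), as.data.frame(sp$test))),
                      phantom_spec(grid_size = 16L))
  m0 <- fixture_model(grid = 16L, channels = c(2L, 2L))
  h <- run_traveling(m0, sp, vs, train_config("traveling", max_cycles = 0L))
  expect_equal(nrow(h), 0L)
  expect_identical(attr(h, "model")$params, m0$params)
})

test_that("every training sample is consumed exactly cycles x local_epochs times", {
  co <- fixture_cohort(sizes = c(12L, 10L), seed = 21L)
  sp <- split_cohort(co, small_center_threshold = 3L, seed = 1L)
  vs <- fixture_volumes(as_cohort(rbind(as.data.frame(sp$train),
                                        as.data.frame(sp$test))))
  m0 <- fixture_model(grid = 16L, channels = c(2L, 2L))
  for (le in c(1L, 2L)) {
    h <- run_traveling(m0, sp, vs, train_config(
      "traveling", max_cycles = 3L, local_epochs = le, data_seed = 2L))
    counts <- attr(h, "exposure")
    expect_setequal(names(counts), sp$train$participant_id)
    expect_true(all(counts == 3L * le))
  }
  hc <- run_centralized(m0, sp, vs, train_config(
    "centralized", max_cycles = 4L, early_stopping_patience = Inf, data_seed = 2L))
  expect_true(all(attr(hc, "exposure") == 4L))
})

test_that("runs are bit-reproducible and decay the learning rate exponentially", {
  sp <- make_pooled_split(n = 10L, seed = 6L)
  vs <- render_cohort(as_cohort(rbind(as.data.frame(sp$train), as.data.frame(sp$test))),
                      phantom_spec(grid_size = 16L, master_seed = 6L))
  m0 <- fixture_model(grid = 16L, channels = c(2L, 2L))
  cfg <- train_config("centralized", max_cycles = 4L,
                      early_stopping_patience = Inf, data_seed = 5L)
  h1 <- run_centralized(m0, sp, vs, cfg)
  h2 <- run_centralized(m0, sp, vs, cfg)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  expect_equal(h1$lr, cfg$initial_lr * cfg$lr_decay_factor^(h1$cycle - 1))

  # history CSV round trip
  p <- tempfile(fileext = ".csv")
  write_history(h1, p)
  expect_equal(read_history(p)$auroc, h1$auroc)
})
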