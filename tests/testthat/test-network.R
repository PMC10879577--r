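test_that("initialization is reproducible and parameter count matches the closed form", {
  cfg <- model_config(grid = 8L, channels = c(2L, 3L), init_seed = 5L)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)

  # hand count: conv1 27*1*2+2 = 56, conv2 27*2*3+3 = 165,
  # grid 8 -> 4 -> 2, feat = 3*2^3 = 24, head 24*2+2 = 50
  expect_equal(n_params(cfg), 56L + 165L + 50L)
  expect_equal(n_params(m1),
               sum(vapply(m1$params$conv_w, length, numeric(1))) +
                 sum(vapply(m1$params$conv_b, length, numeric(1))) +
                 length(m1$params$fc_w) + length(m1$params$fc_b))
  expect_error(model_config(grid = 8L, channels = c(2L, 3L), dropout_rate = 1),
               class = "travelnet_config_error")
  expect_error(model_config(grid = 8L, channels = rep(2L, 5)),
               class = "travelnet_config_error")
})

test_that("evaluation forward is deterministic, batch-invariant, and finite on degenerate input", {
  m <- fixture_model()
  co <- fixture_cohort(sizes = 6L, seed = 2L)
  vs <- fixture_volumes(co)
  s_all <- predict_scores(m, vs)
  expect_identical(s_all, predict_scores(m, vs))
  one <- predict_scores(m, vs, ids = volume_ids(vs)[3])
  expect_equal(unname(one), unname(s_all[3]), tolerance = 1e-12)
  expect_true(all(s_all >= 0 & s_all <= 1))

  zero <- matrix(0, nrow = 16^3, ncol = 1)
  expect_true(is.finite(predict_scores(m, zero)))
})

test_that("training loss with dropout 0 agrees with evaluation probabilities", {
  cfg <- model_config(grid = 16L, channels = c(4L, 8L), dropout_rate = 0,
                      init_seed = 3L)
  m <- build_model(cfg)
  co <- fixture_cohort(sizes = 5L, seed = 2L)
  vs <- fixture_volumes(co)
  labels <- as.integer(volume_labels(vs))
  xz <- travelnet:::normalize_volumes(vs$x)
  out <- travelnet:::cnn_batch_grad_cpp(m$params, cfg, xz, labels, 0, 1L)
  p <- predict_scores(m, vs)
  expect_equal(out$loss, mean(-log(ifelse(labels == 1, p, 1 - p))),
               tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(grid = 8L, channels = c(2L, 3L), dropout_rate = 0.3,
                      init_seed = 2L)
  m <- build_model(cfg)
  set.seed(5)
  x <- matrix(rnorm(8^3 * 3), ncol = 3)
  y <- c(0L, 1L, 1L)
  seed <- 123L
  g <- travelnet:::cnn_batch_grad_cpp(m$params, cfg, x, y, 0.3, seed)$grads
  eps <- 1e-6
  perturbed_loss <- function(params) {
    travelnet:::cnn_batch_grad_cpp(params, cfg, x, y, 0.3, seed)$loss
  }
  check_leaf <- function(getter, setter, grad_arr) {
    idx <- sample(length(grad_arr), min(6, length(grad_arr)))
    for (i in idx) {
      pp <- setter(m$params, i, +eps)
      pm <- setter(m$params, i, -eps)
      num <- (perturbed_loss(pp) - perturbed_loss(pm)) / (2 * eps)
      expect_equal(grad_arr[i], num, tolerance = 1e-5)
    }
  }
  check_leaf(NULL, function(p, i, e) { p$conv_w[[1]][i] <- p$conv_w[[1]][i] + e; p },
             g$conv_w[[1]])
  check_leaf(NULL, function(p, i, e) { p$conv_w[[2]][i] <- p$conv_w[[2]][i] + e; p },
             g$conv_w[[2]])
  check_leaf(NULL, function(p, i, e) { p$fc_w[i] <- p$fc_w[i] + e; p }, g$fc_w)
  check_leaf(NULL, function(p, i, e) { p$fc_b[i] <- p$fc_b[i] + e; p }, g$fc_b)
})

test_that("a briefly trained model separates large-effect phantoms (AUROC > 0.9)", {
  co <- fixture_cohort(sizes = rep(10L, 6), label_fraction = 0.5, seed = 14L)
  sp <- split_cohort(co, small_center_threshold = 5L, seed = 1L)
  full <- as_cohort(rbind(as.data.frame(sp$train), as.data.frame(sp$test)))
  vs <- render_cohort(full, phantom_spec(
    grid_size = 16L, class_effect_size = 0.5, center_gain_sd = 0.02,
    bias_field_amplitude = 0.1,
    noise_sd_by_vendor = c(Siemens = 0.05, GE = 0.05, Philips = 0.05),
    master_seed = 15L))
  m0 <- fixture_model(seed = 16L)
  h <- run_centralized(m0, sp, vs,
                       train_config("centralized", max_cycles = 6L,
                                    early_stopping_patience = Inf, data_seed = 4L))
  expect_gt(h$auroc[nrow(h)], 0.9)
  expect_true(all(is.finite(h$train_loss)))
})

test_that("checkpoints round-trip model and optimizer state", {
  m <- fixture_model()
  st <- adam_state(m$params)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, st, path, extra = list(cycle = 3L))
  ck <- load_checkpoint(path)
  expect_identical(ck$model$params, m$params)
  expect_identical(ck$opt_state, st)
  expect_equal(ck$extra$cycle, 3L)
})
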