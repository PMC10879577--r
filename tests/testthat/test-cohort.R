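test_that("build_cohort is deterministic and draws exactly what the spec says", {
  spec <- cohort_spec(
    center_size_profile = list(list(name = "a", n_centers = 3L,
                                    size_sampler = function(n) rep(4L, n))),
    label_fraction_sampler = function(n) rep(0.5, n),
    master_seed = 7L
  )
  co <- build_cohort(spec)
  expect_equal(nrow(co), 12L)
  expect_equal(unname(lengths(center_groups(co))), rep(4L, 3))

  # replay the documented draw order by hand with the same seed
  vw <- c(Siemens = 0.6, GE = 0.25, Philips = 0.15)
  set.seed(7)
  for (k in 1:3) {
    sf <- rbeta(1, 8, 6)
    labels <- rbinom(4, 1, 0.5)
    sexes <- ifelse(rbinom(4, 1, sf) == 1, "M", "F")
    ages <- round(pmin(pmax(rnorm(4, 64, 9), 35), 90), 1)
    vendors <- sample(names(vw), 4, replace = TRUE, prob = vw / sum(vw))
    fields <- sample(c(1.5, 3.0), 4, replace = TRUE, prob = c(0.3, 0.7))
    rows <- co[co$center_id == sprintf("a_c%02d", k), ]
    expect_equal(rows$label, labels)
    expect_equal(rows$sex, sexes)
    expect_equal(rows$age_years, ages)
    expect_equal(rows$vendor, vendors)
  }

  # byte-identical manifests across two builds
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_manifest(build_cohort(spec), p1)
  write_manifest(build_cohort(spec), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("degenerate specs are rejected", {
  expect_error(build_cohort(cohort_spec(
    list(list(name = "z", n_centers = 2L, size_sampler = function(n) c(3L, 0L))),
    master_seed = 1)), class = "travelnet_config_error")
  expect_error(cohort_spec(list(list(name = "z", n_centers = 1L,
                                     size_sampler = function(n) 5L)),
                           vendor_weights = c(Siemens = -1, GE = 2)),
               class = "travelnet_config_error")
  expect_error(cohort_spec(list(list(name = "z", n_centers = 1L,
                                     size_sampler = function(n) 5L)),
                           vendor_weights = c(Toshiba = 1)),
               class = "travelnet_config_error")
})

test_that("default profile declares 83 centers and builds a long-tailed cohort", {
  spec <- reference_cohort_spec(master_seed = 42L)
  expect_equal(spec_n_centers(spec), 83L)
  expect_equal(sum(study_table()$n_centers), 83L)
  co <- build_cohort(spec)
  sizes <- lengths(center_groups(co))
  expect_equal(length(sizes), 83L)
  expect_equal(nrow(co), 1817L)
  expect_gt(sum(sizes < 5), 0)    # singleton-ish centers exist
  expect_gt(max(sizes), 100)      # and large single-center studies
})

test_that("per-center split uses round-half-up and keeps the partition invariant", {
  co <- fixture_cohort(sizes = c(100L, 30L), seed = 2L)
  sp <- split_cohort(co, train_fraction = 0.8, small_center_threshold = 25L)
  rep <- sp$split_report$per_center
  expect_equal(rep$n_train[rep$n == 100], 80L)
  expect_equal(rep$n_test[rep$n == 100], 20L)
  expect_equal(rep$n_train[rep$n == 30], 24L)

  # partition property across fractions and cohorts
  for (fr in c(0.5, 0.7, 0.8)) {
    sp2 <- split_cohort(co, train_fraction = fr, small_center_threshold = 10L)
    ids_train <- sp2$train$participant_id
    ids_test <- sp2$test$participant_id
    expect_length(intersect(ids_train, ids_test), 0)
    expect_setequal(c(ids_train, ids_test), co$participant_id)
  }
  expect_error(split_cohort(co[0, ]), "cohort")
})

test_that("a single record below the threshold goes to train (empty deficit state)", {
  co <- fixture_cohort(sizes = 1L, seed = 4L)
  sp <- split_cohort(co, small_center_threshold = 25L)
  expect_equal(nrow(sp$train), 1L)
  expect_equal(nrow(sp$test), 0L)
})

test_that("greedy small-center rule balances sex at least as well as random assignment", {
  co <- fixture_cohort(sizes = rep(c(3L, 5L, 8L, 12L), 5), seed = 9L)
  gap <- function(train_idx) {
    test_idx <- setdiff(seq_len(nrow(co)), train_idx)
    abs(mean(co$sex[train_idx] == "M") - mean(co$sex[test_idx] == "M"))
  }
  greedy_gaps <- random_gaps <- numeric(20)
  for (s in 1:20) {
    sp <- split_cohort(co, small_center_threshold = 25L, seed = s)
    greedy_gaps[s] <- abs(sp$split_report$global["train", "male_fraction"] -
                            sp$split_report$global["test", "male_fraction"])
    n_test <- nrow(sp$test)
    set.seed(s)
    test_idx <- sample(nrow(co), n_test)
    random_gaps[s] <- gap(setdiff(seq_len(nrow(co)), test_idx))
  }
  expect_lte(mean(greedy_gaps), mean(random_gaps))
  # the cap: at most 20% of the small-center pool is tested
  sp <- split_cohort(co, small_center_threshold = 25L, seed = 1L)
  expect_lte(nrow(sp$test), floor(0.2 * nrow(co)))
})

test_that("manifest round-trips field-for-field and rejects malformed inputs", {
  co <- fixture_cohort(sizes = 5L, seed = 3L)
  path <- tempfile(fileext = ".csv")
  write_manifest(co, path)
  expect_identical(as.data.frame(load_manifest(path)), as.data.frame(co))

  df <- read.csv(path, stringsAsFactors = FALSE)
  p2 <- tempfile(fileext = ".csv")
  write.csv(df[, setdiff(names(df), "center_id")], p2, row.names = FALSE)
  expect_error(load_manifest(p2), "center_id", class = "travelnet_schema_error")

  df_dup <- rbind(df, df[1, ])
  write.csv(df_dup, p2, row.names = FALSE)
  expect_error(load_manifest(p2), "duplicated", class = "travelnet_validation_error")

  df_bad <- df; df_bad$vendor[2] <- "Toshiba"
  write.csv(df_bad, p2, row.names = FALSE)
  expect_error(load_manifest(p2), "Toshiba", class = "travelnet_validation_error")
})

test_that("demographics summary uses a strict <60 age band and recounts records", {
  co <- fixture_cohort(sizes = 2L, seed = 6L)
  co$age_years <- c(59, 60)
  sm <- summarize_cohort(co)
  all_row <- sm[sm$center_id == "ALL", ]
  expect_equal(all_row$age_lt60, 1L)
  expect_equal(all_row$age_ge60, 1L)

  co2 <- build_cohort(reference_cohort_spec(master_seed = 1L, scale = 0.1))
  sm2 <- summarize_cohort(co2)
  g <- sm2[sm2$center_id == "ALL", ]
  expect_equal(g$n, nrow(co2))
  expect_equal(g$n_disease, sum(co2$label == 1))
  expect_equal(g$n_disease + g$n_healthy, g$n)
  expect_equal(g$n_male + g$n_female, g$n)
  # per-center rows cover exactly the centers present
  expect_setequal(setdiff(sm2$center_id, "ALL"), unique(co2$center_id))
})
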