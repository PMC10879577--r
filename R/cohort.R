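# Multi-center cohort representation, synthetic generation, and the
# per-center train/test split.
#
# A cohort is a data.frame of participant records (one row each):
#   participant_id, center_id, label (1 = disease-positive, 0 = healthy),
#   sex (M/F), age_years, vendor (Siemens/GE/Philips),
#   field_strength_tesla (1.5/3.0), split (train/test/unassigned).

.VENDORS <- c("Siemens", "GE", "Philips")
.MANIFEST_COLS <- c("participant_id", "center_id", "label", "sex", "age_years",
                    "vendor", "field_strength_tesla", "split")

#' Specification of a synthetic multi-center cohort
#'
#' Declares how centers and their participants are drawn. The center-size
#' profile is a list of groups (studies); each group contributes `n_centers`
#' centers whose sizes are drawn by its `size_sampler`. Per-center disease and
#' sex fractions, ages, scanner vendor and field strength are drawn from the
#' group-level samplers (falling back to the spec-level defaults). All draws
#' come from a single RNG stream seeded once with `master_seed`, in a fixed
#' documented order (per group: center sizes; per center: label fraction, sex
#' fraction; per participant: labels, sexes, ages, vendors, field strengths),
#' so two builds of the same spec are byte-identical.
#'
#' @param center_size_profile list of groups, each
#'   `list(name, n_centers, size_sampler, label_fraction_sampler = NULL,
#'   sex_fraction_sampler = NULL, vendor_weights = NULL)`; samplers are
#'   functions of `n` returning `n` draws from the current RNG stream.
#' @param label_fraction_sampler default per-center disease fraction sampler.
#' @param sex_fraction_sampler default per-center male fraction sampler.
#' @param age_sampler function of `n` returning ages in years.
#' @param vendor_weights named nonnegative weights over
#'   `Siemens`, `GE`, `Philips` (need not sum to 1; must sum to > 0).
#' @param field_strength_probs probabilities of `c(1.5, 3.0)` Tesla.
#' @param stratify_labels if `TRUE`, each center receives exactly
#'   `round(fraction * n)` disease labels in a seeded random order instead of
#'   independent Bernoulli draws (guarantees mixed classes in small demo
#'   cohorts; changes the draw order for labels only).
#' @param master_seed integer seed making the build deterministic.
#' @return object of class `cohort_spec`.
#' @seealso [build_cohort()], [reference_cohort_spec()]
#' @export
cohort_spec <- function(center_size_profile,
                        label_fraction_sampler = function(n) stats::rbeta(n, 4, 4),
                        sex_fraction_sampler = function(n) stats::rbeta(n, 8, 6),
                        age_sampler = function(n) pmin(pmax(stats::rnorm(n, 64, 9), 35), 90),
                        vendor_weights = c(Siemens = 0.6, GE = 0.25, Philips = 0.15),
                        field_strength_probs = c(0.3, 0.7),
                        stratify_labels = FALSE,
                        master_seed = 1L) {
  if (!is.list(center_size_profile) || length(center_size_profile) == 0L) {
    stop_config("center_size_profile must be a nonempty list of groups")
  }
  check_vendor_weights(vendor_weights)
  for (g in center_size_profile) {
    if (is.null(g$n_centers) || g$n_centers < 1) {
      stop_config("each profile group needs n_centers >= 1")
    }
    if (!is.function(g$size_sampler)) stop_config("each profile group needs a size_sampler function")
    if (!is.null(g$vendor_weights)) check_vendor_weights(g$vendor_weights)
  }
  structure(
    list(center_size_profile = center_size_profile,
         label_fraction_sampler = label_fraction_sampler,
         sex_fraction_sampler = sex_fraction_sampler,
         age_sampler = age_sampler,
         vendor_weights = vendor_weights,
         field_strength_probs = field_strength_probs,
         stratify_labels = isTRUE(stratify_labels),
         master_seed = as.integer(master_seed)),
    class = "cohort_spec"
  )
}

check_vendor_weights <- function(w) {
  if (is.null(names(w)) || !all(names(w) %in% .VENDORS) ||
      any(w < 0) || sum(w) <= 0 || anyNA(w)) {
    stop_config("vendor_weights must be named nonnegative weights over ",
                paste(.VENDORS, collapse = "/"), " with positive sum")
  }
  invisible(TRUE)
}

#' Total number of centers declared by a cohort spec
#' @param spec a `cohort_spec`.
#' @export
spec_n_centers <- function(spec) {
  sum(vapply(spec$center_size_profile, function(g) as.integer(g$n_centers), integer(1)))
}

#' Build a synthetic multi-center cohort
#'
#' Draws centers and participant records from a [cohort_spec()] using a single
#' RNG stream seeded with `spec$master_seed` (see the spec's documentation for
#' the draw order). Center ids are `"<group>_c<k>"`, participant ids
#' `"<center>_p<j>"`. All records start with `split = "unassigned"`.
#'
#' @param spec a `cohort_spec`.
#' @return object of class `cohort` (a data.frame of participant records).
#' @export
build_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$master_seed, {
    rows <- list()
    for (g in spec$center_size_profile) {
      nc <- as.integer(g$n_centers)
      sizes <- as.integer(round(g$size_sampler(nc)))
      if (length(sizes) != nc) stop_config("size_sampler returned wrong length")
      if (any(sizes < 1L)) stop_config("center of size 0 in group '", g$name %||% "?",
                                       "': every center must have >= 1 participant")
      lf_sampler <- g$label_fraction_sampler %||% spec$label_fraction_sampler
      sf_sampler <- g$sex_fraction_sampler %||% spec$sex_fraction_sampler
      vw <- g$vendor_weights %||% spec$vendor_weights
      gname <- g$name %||% "ctr"
      for (k in seq_len(nc)) {
        n <- sizes[k]
        center_id <- sprintf("%s_c%02d", gname, k)
        lf <- lf_sampler(1)
        sf <- sf_sampler(1)
        labels <- if (spec$stratify_labels) {
          n_pos <- round(lf * n)
          sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
        } else {
          stats::rbinom(n, 1L, lf)
        }
        sexes <- ifelse(stats::rbinom(n, 1L, sf) == 1L, "M", "F")
        ages <- round(spec$age_sampler(n), 1)
        vendors <- sample(names(vw), n, replace = TRUE, prob = vw / sum(vw))
        fields <- sample(c(1.5, 3.0), n, replace = TRUE, prob = spec$field_strength_probs)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = sprintf("%s_p%03d", center_id, seq_len(n)),
          center_id = center_id, label = labels, sex = sexes, age_years = ages,
          vendor = vendors, field_strength_tesla = fields, split = "unassigned",
          stringsAsFactors = FALSE
        )
      }
    }
    as_cohort(do.call(rbind, rows))
  })
}

#' Coerce a record data.frame to a cohort, validating its invariants
#'
#' @param records data.frame with the manifest columns (see [write_manifest()]).
#' @return a `cohort`.
#' @export
as_cohort <- function(records) {
  missing <- setdiff(.MANIFEST_COLS, names(records))
  if (length(missing) > 0L) {
    stop(errorCondition(paste0("missing required column(s): ",
                               paste(missing, collapse = ", ")),
                        class = c("travelnet_schema_error", "error")))
  }
  records <- as.data.frame(records)[, .MANIFEST_COLS]
  dup <- records$participant_id[duplicated(records$participant_id)]
  if (length(dup) > 0L) {
    stop(errorCondition(paste0("duplicated participant_id: ",
                               paste(unique(dup), collapse = ", ")),
                        class = c("travelnet_validation_error", "error")))
  }
  bad_vendor <- setdiff(unique(records$vendor), .VENDORS)
  if (length(bad_vendor) > 0L) {
    stop(errorCondition(paste0("unknown vendor value(s): ",
                               paste(bad_vendor, collapse = ", ")),
                        class = c("travelnet_validation_error", "error")))
  }
  if (!all(records$label %in% c(0L, 1L))) stop("label must be 0/1")
  if (!all(records$sex %in% c("M", "F"))) stop("sex must be M/F")
  if (any(records$age_years < 0)) stop("age_years must be nonnegative")
  if (!all(records$field_strength_tesla %in% c(1.5, 3.0))) {
    stop("field_strength_tesla must be 1.5 or 3.0")
  }
  if (!all(records$split %in% c("train", "test", "unassigned"))) {
    stop("split must be train/test/unassigned")
  }
  rownames(records) <- NULL
  class(records) <- c("cohort", "data.frame")
  records
}

#' Group a cohort's row indices by center
#' @param cohort a `cohort`.
#' @return named list `center_id -> integer row indices`.
#' @export
center_groups <- function(cohort) {
  split(seq_len(nrow(cohort)), cohort$center_id)
}

#' @export
print.cohort <- function(x, ...) {
  cs <- table(x$center_id)
  cat(sprintf("<cohort> %d participants across %d centers (%d disease / %d healthy)\n",
              nrow(x), length(cs), sum(x$label == 1), sum(x$label == 0)))
  cat(sprintf("  center sizes: min %d, median %d, max %d; split: %s\n",
              min(cs), as.integer(stats::median(cs)), max(cs),
              paste(names(table(x$split)), table(x$split), sep = "=", collapse = " ")))
  invisible(x)
}

age_band <- function(age) ifelse(age < 60, "<60", "60+")

#' Split a cohort per-center into train and test sets
#'
#' Centers with at least `small_center_threshold` participants are split
#' per-center: the train count is `floor(train_fraction * n + 0.5)`
#' (round-half-up), the remainder goes to test, with membership drawn by a
#' seeded per-center shuffle. Smaller centers are pooled and assigned by a
#' deterministic greedy rule aiming at a globally balanced sex / age-band
#' representation across train and test: small centers are processed in
#' descending size order (ties broken by center id), records within a center
#' in a seed-shuffled order, and each record goes to train unless its
#' (sex, age-band) cell's running test deficit exceeds the train deficit —
#' capped so at most `1 - train_fraction` of the small-center pool is tested.
#'
#' @param cohort a `cohort`.
#' @param train_fraction fraction of each (large) center assigned to train
#'   (default 0.8).
#' @param small_center_threshold centers below this size use the greedy
#'   balancing rule (default 25).
#' @param seed split seed driving the per-center shuffles.
#' @return object of class `split_cohort`: list with `train` and `test`
#'   cohorts and a `split_report` (per-center counts plus global sex/age
#'   balance).
#' @export
split_cohort <- function(cohort, train_fraction = 0.8,
                         small_center_threshold = 25L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort) == 0L) stop("empty cohort")
  if (!(train_fraction > 0 && train_fraction < 1)) stop("train_fraction must be in (0,1)")
  if (small_center_threshold < 1L) stop("small_center_threshold must be >= 1")

  groups <- center_groups(cohort)
  sizes <- lengths(groups)
  split <- rep("unassigned", nrow(cohort))

  # Large centers: per-center round-half-up split.
  for (cid in names(groups)[sizes >= small_center_threshold]) {
    idx <- groups[[cid]]
    n <- length(idx)
    n_train <- floor(train_fraction * n + 0.5)
    ord <- fisher_yates(idx, derive_seed(seed, "split", cid))
    split[ord[seq_len(n_train)]] <- "train"
    if (n_train < n) split[ord[(n_train + 1L):n]] <- "test"
  }

  # Small centers: greedy global sex/age-band balancing.
  small_ids <- names(groups)[sizes < small_center_threshold]
  if (length(small_ids) > 0L) {
    small_ids <- small_ids[order(-sizes[small_ids], small_ids)]
    pool_n <- sum(sizes[small_ids])
    test_cap <- floor((1 - train_fraction) * pool_n)
    cells <- c("M.<60", "M.60+", "F.<60", "F.60+")
    n_train_cell <- setNames(numeric(4), cells)
    n_test_cell <- setNames(numeric(4), cells)
    tests_assigned <- 0L
    for (cid in small_ids) {
      idx <- fisher_yates(groups[[cid]], derive_seed(seed, "split-small", cid))
      for (i in idx) {
        cell <- paste(cohort$sex[i], age_band(cohort$age_years[i]), sep = ".")
        n_cell <- n_train_cell[cell] + n_test_cell[cell] + 1
        test_deficit <- (1 - train_fraction) * n_cell - n_test_cell[cell]
        train_deficit <- train_fraction * n_cell - n_train_cell[cell]
        if (test_deficit > train_deficit && tests_assigned < test_cap) {
          split[i] <- "test"
          n_test_cell[cell] <- n_test_cell[cell] + 1
          tests_assigned <- tests_assigned + 1L
        } else {
          split[i] <- "train"
          n_train_cell[cell] <- n_train_cell[cell] + 1
        }
      }
    }
  }

  cohort$split <- split
  make_split_cohort(cohort)
}

# Assemble a split_cohort from a cohort whose split column is fully assigned.
make_split_cohort <- function(cohort) {
  stopifnot(all(cohort$split %in% c("train", "test")))
  train <- as_cohort(cohort[cohort$split == "train", ])
  test <- as_cohort(cohort[cohort$split == "test", ])
  per_center <- do.call(rbind, lapply(split(cohort, cohort$center_id), function(d) {
    data.frame(center_id = d$center_id[1], n = nrow(d),
               n_train = sum(d$split == "train"), n_test = sum(d$split == "test"),
               stringsAsFactors = FALSE)
  }))
  rownames(per_center) <- NULL
  balance <- function(d) {
    c(male_fraction = mean(d$sex == "M"), ge60_fraction = mean(d$age_years >= 60))
  }
  structure(
    list(train = train, test = test,
         split_report = list(per_center = per_center,
                             global = rbind(train = balance(train), test = balance(test)))),
    class = "split_cohort"
  )
}

#' @export
print.split_cohort <- function(x, ...) {
  cat(sprintf("<split_cohort> %d train / %d test across %d centers\n",
              nrow(x$train), nrow(x$test), nrow(x$split_report$per_center)))
  g <- x$split_report$global
  cat(sprintf("  male fraction train %.3f / test %.3f; age 60+ train %.3f / test %.3f\n",
              g["train", "male_fraction"], g["test", "male_fraction"],
              g["train", "ge60_fraction"], g["test", "ge60_fraction"]))
  invisible(x)
}

#' Write a cohort manifest CSV
#'
#' Plain UTF-8 CSV with header
#' `participant_id,center_id,label,sex,age_years,vendor,field_strength_tesla,split`.
#' `load_manifest(write_manifest(c, path))` reproduces the cohort
#' field-for-field.
#'
#' @param cohort a `cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort manifest CSV
#'
#' Validates the schema (missing columns raise a schema error naming the
#' column), vendor values, label/sex domains and participant-id uniqueness.
#'
#' @param path manifest CSV path.
#' @return a `cohort`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character")
  missing <- setdiff(.MANIFEST_COLS, names(df))
  if (length(missing) > 0L) {
    stop(errorCondition(paste0("manifest missing required column(s): ",
                               paste(missing, collapse = ", ")),
                        class = c("travelnet_schema_error", "error")))
  }
  df$label <- as.integer(df$label)
  df$age_years <- as.numeric(df$age_years)
  df$field_strength_tesla <- as.numeric(df$field_strength_tesla)
  as_cohort(df)
}

#' Demographics summary by center and globally
#'
#' Counts participants by disease label, sex, and age band (strictly `<60`
#' vs `60+`) per center, with a pooled `ALL` row first.
#'
#' @param cohort a `cohort`.
#' @return data.frame of class `cohort_summary` with columns `center_id, n,
#'   n_disease, n_healthy, n_male, n_female, age_lt60, age_ge60`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort) == 0L) stop("empty cohort")
  count_block <- function(d, id) {
    data.frame(center_id = id, n = nrow(d),
               n_disease = sum(d$label == 1), n_healthy = sum(d$label == 0),
               n_male = sum(d$sex == "M"), n_female = sum(d$sex == "F"),
               age_lt60 = sum(d$age_years < 60), age_ge60 = sum(d$age_years >= 60),
               stringsAsFactors = FALSE)
  }
  per_center <- do.call(rbind, lapply(split(cohort, cohort$center_id),
                                      function(d) count_block(d, d$center_id[1])))
  out <- rbind(count_block(cohort, "ALL"), per_center)
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}
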