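# Config-driven experiment runner: the traveling configurations
# (fixed/random order x 1/2/5 local epochs) plus the centralized baseline,
# on synthetic phantoms (or user-supplied NIfTI volumes), with reproducibility
# manifests. A YAML file or a preset fully determines a run suite.

#' Assemble an experiment configuration
#'
#' @param cohort list describing the cohort: either
#'   `list(preset = "reference", scale = ...)`, `list(preset = "benchmark")`,
#'   `list(manifest = "path.csv")`, or a full `cohort_spec`.
#' @param phantom list of [phantom_spec()] arguments, or
#'   `list(volume_dir = "...")` to load NIfTI volumes instead of rendering.
#' @param model list of [model_config()] arguments (`grid` is taken from the
#'   phantom spec).
#' @param runs list of run descriptors:
#'   `list(name, paradigm, order = "random"/"fixed", local_epochs, max_cycles)`.
#' @param out_dir output directory for histories, summary and provenance.
#' @param seed global experiment seed; every internal seed derives from it.
#' @param split list of [split_cohort()] arguments (fraction, threshold).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(cohort, phantom = list(), model = list(),
                              runs, out_dir = "travelnet_runs", seed = 1L,
                              split = list()) {
  if (length(runs) == 0L) stop_config("at least one run is required")
  for (r in runs) {
    if (is.null(r$name) || is.null(r$paradigm)) {
      stop_config("each run needs a name and a paradigm")
    }
    if (!r$paradigm %in% c("traveling", "centralized")) {
      stop_config("unknown paradigm: ", r$paradigm)
    }
  }
  if (anyDuplicated(vapply(runs, `[[`, character(1), "name"))) {
    stop_config("run names must be unique")
  }
  structure(list(cohort = cohort, phantom = phantom, model = model,
                 runs = runs, out_dir = out_dir, seed = as.integer(seed),
                 split = split),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' The YAML mirrors the [experiment_config()] arguments
#' (`cohort:`, `phantom:`, `model:`, `runs:`, `out_dir:`, `seed:`).
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(experiment_config, y)
}

#' Long-tailed 12-center benchmark cohort specification
#'
#' A desk-scale heterogeneous benchmark: 12 centers with fixed sizes
#' 75/45/35/25/25/20/18/15/12/10/8/4 (292 participants, about 240 of them
#' training after the 80/20 split), per-center disease fractions drawn
#' Beta(5, 5), mixed vendors — small enough to train in minutes, center-skewed
#' enough to stress the traveling model.
#'
#' @param master_seed build seed.
#' @return a `cohort_spec` with 12 centers.
#' @export
benchmark_cohort_spec <- function(master_seed = 1L) {
  sizes <- c(75L, 45L, 35L, 25L, 25L, 20L, 18L, 15L, 12L, 10L, 8L, 4L)
  cohort_spec(
    center_size_profile = list(list(name = "bench", n_centers = length(sizes),
                                    size_sampler = function(n) sizes)),
    label_fraction_sampler = function(n) stats::rbeta(n, 5, 5),
    master_seed = master_seed
  )
}

resolve_cohort_spec <- function(cohort, seed) {
  if (inherits(cohort, "cohort_spec")) return(cohort)
  ms <- cohort$master_seed %||% derive_seed(seed, "cohort")
  if (!is.null(cohort$preset)) {
    switch(cohort$preset,
      reference = reference_cohort_spec(master_seed = ms, scale = cohort$scale %||% 1),
      benchmark = benchmark_cohort_spec(master_seed = ms),
      stop_config("unknown cohort preset: ", cohort$preset))
  } else if (!is.null(cohort$manifest)) {
    NULL  # loaded, not generated
  } else {
    stop_config("cohort must give a preset, a manifest path, or a cohort_spec")
  }
}

run_one <- function(run, model0, split, volumes, seed, out_dir) {
  cfg <- train_config(
    paradigm = run$paradigm,
    initial_lr = run$initial_lr %||% NULL,
    lr_decay_factor = run$lr_decay_factor %||% 0.97,
    batch_size_cap = run$batch_size_cap %||% 5L,
    local_epochs = run$local_epochs %||% 1L,
    max_cycles = run$max_cycles %||% 30L,
    early_stopping_patience = run$early_stopping_patience %||% 10L,
    schedule = schedule_policy(run$order %||% "random",
                               base_seed = run$schedule_seed %||% 42L),
    data_seed = derive_seed(seed, "data")
  )
  h <- if (run$paradigm == "traveling") {
    run_traveling(model0, split, volumes, cfg)
  } else {
    run_centralized(model0, split, volumes, cfg)
  }
  if (!is.null(out_dir)) {
    write_history(h, file.path(out_dir, paste0("history_", run$name, ".csv")))
  }
  h
}

summary_row <- function(name, run, h) {
  b <- best_cycle(h)
  data.frame(
    run = name, paradigm = run$paradigm,
    order = if (run$paradigm == "traveling") run$order %||% "random" else "-",
    local_epochs = if (run$paradigm == "traveling") run$local_epochs %||% 1L else 1L,
    cycles = nrow(h), final_auroc = h$auroc[nrow(h)],
    best_cycle = b$cycle, best_auroc = b$auroc,
    instability = if (nrow(h) >= 2L) instability_index(h$auroc) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Run a full experiment
#'
#' Builds (or loads) the cohort, splits it, renders (or loads) the volumes,
#' then executes every configured run from a common initial model. Writes,
#' under `out_dir`: the cohort manifest, one history CSV per run, a summary
#' CSV (final/best-cycle AUROC and instability per run), a resolved config
#' YAML and a provenance JSON (all seeds, config digest, software versions).
#'
#' @param config an `experiment_config`.
#' @param write_outputs write artifacts to `config$out_dir` (default TRUE;
#'   FALSE returns results only).
#' @return list with `histories` (named list of `tm_history`), `summary`
#'   (data.frame), `split`, and `out_dir`.
#' @export
run_experiment <- function(config, write_outputs = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  out_dir <- if (write_outputs) config$out_dir else NULL
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  spec <- resolve_cohort_spec(config$cohort, seed)
  cohort <- if (is.null(spec)) load_manifest(config$cohort$manifest) else build_cohort(spec)
  split <- do.call(split_cohort, c(list(cohort = cohort,
                                        seed = derive_seed(seed, "split")),
                                   config$split))
  full <- as_cohort(rbind(as.data.frame(split$train), as.data.frame(split$test)))
  if (!is.null(out_dir)) write_manifest(full, file.path(out_dir, "manifest.csv"))

  if (!is.null(config$phantom$volume_dir)) {
    volumes <- read_volumes_nifti(full, config$phantom$volume_dir)
  } else {
    ph_args <- config$phantom
    ph_args$master_seed <- ph_args$master_seed %||% derive_seed(seed, "phantom")
    pspec <- do.call(phantom_spec, ph_args)
    volumes <- render_cohort(full, pspec)
  }

  m_args <- config$model
  m_args$grid <- volumes$grid
  m_args$init_seed <- m_args$init_seed %||% derive_seed(seed, "init")
  model0 <- build_model(do.call(model_config, m_args))

  histories <- list()
  summaries <- list()
  for (run in config$runs) {
    h <- run_one(run, model0, split, volumes, seed, out_dir)
    histories[[run$name]] <- h
    summaries[[run$name]] <- summary_row(run$name, run, h)
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL

  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    write.csv(summarize_cohort(full), file.path(out_dir, "demographics.csv"),
              row.names = FALSE)
    resolved <- config
    class(resolved) <- NULL
    yaml::write_yaml(resolved, file.path(out_dir, "config.resolved.yaml"))
    prov <- list(
      seed = seed,
      derived_seeds = list(cohort = derive_seed(seed, "cohort"),
                           split = derive_seed(seed, "split"),
                           phantom = derive_seed(seed, "phantom"),
                           init = derive_seed(seed, "init"),
                           data = derive_seed(seed, "data")),
      config_digest = derive_seed(paste(deparse(resolved), collapse = "")),
      r_version = R.version.string,
      package_version = as.character(utils::packageVersion("travelnet"))
    )
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(histories = histories, summary = summary, split = split,
       out_dir = out_dir)
}

#' Preset experiment configurations
#'
#' * `reference`: the 83-center profile (scaled to ~260 participants), all six
#'   traveling configurations (fixed/random order x 1/2/5 local epochs) plus
#'   the centralized baseline, 30 cycles — 7 runs.
#' * `mini`: the 12-center benchmark cohort with a narrower 3-block network on
#'   a 16^3 grid, same 7 runs at 30 cycles — finishes in minutes.
#' * `benchmark`: the desk-scale qualitative-reproduction suite — the same
#'   12-center cohort and network as `mini` but only the 5 runs the
#'   phenomenology comparison needs (centralized baseline, random/fixed order
#'   at 1 local epoch, random order at 2 and 5 local epochs).
#' * `smoke`: 2 tiny centers, 2 cycles, 3 runs (centralized, fixed, random) —
#'   a seconds-long end-to-end check.
#'
#' @param name preset name.
#' @param seed global seed.
#' @param out_dir output directory.
#' @return an `experiment_config`.
#' @export
experiment_preset <- function(name = c("reference", "mini", "benchmark", "smoke"),
                              seed = 1L,
                              out_dir = file.path("travelnet_runs", name)) {
  name <- match.arg(name)
  travel_runs <- function(max_cycles) {
    runs <- list()
    for (ord in c("random", "fixed")) {
      for (le in c(1L, 2L, 5L)) {
        runs[[length(runs) + 1L]] <- list(
          name = sprintf("traveling_%s_e%d", ord, le), paradigm = "traveling",
          order = ord, local_epochs = le, max_cycles = max_cycles)
      }
    }
    runs
  }
  switch(name,
    reference = experiment_config(
      cohort = list(preset = "reference", scale = 1 / 7),
      phantom = list(grid_size = 24L),
      model = list(channels = c(8L, 16L, 32L, 32L)),
      runs = c(list(list(name = "centralized", paradigm = "centralized",
                         max_cycles = 30L)),
               travel_runs(30L)),
      out_dir = out_dir, seed = seed),
    mini = experiment_config(
      cohort = list(preset = "benchmark"),
      phantom = list(grid_size = 16L),
      model = list(channels = c(4L, 8L, 8L)),
      runs = c(list(list(name = "centralized", paradigm = "centralized",
                         max_cycles = 30L)),
               travel_runs(30L)),
      out_dir = out_dir, seed = seed),
    benchmark = experiment_config(
      cohort = list(preset = "benchmark"),
      phantom = list(grid_size = 16L),
      model = list(channels = c(4L, 8L, 8L)),
      runs = list(
        list(name = "centralized", paradigm = "centralized", max_cycles = 30L),
        list(name = "traveling_random_e1", paradigm = "traveling",
             order = "random", local_epochs = 1L, max_cycles = 30L),
        list(name = "traveling_fixed_e1", paradigm = "traveling",
             order = "fixed", local_epochs = 1L, max_cycles = 30L),
        list(name = "traveling_random_e2", paradigm = "traveling",
             order = "random", local_epochs = 2L, max_cycles = 30L),
        list(name = "traveling_random_e5", paradigm = "traveling",
             order = "random", local_epochs = 5L, max_cycles = 30L)),
      out_dir = out_dir, seed = seed),
    smoke = experiment_config(
      cohort = cohort_spec(
        center_size_profile = list(list(name = "smoke", n_centers = 2L,
                                        size_sampler = function(n) c(20L, 12L))),
        label_fraction_sampler = function(n) rep(0.5, n),
        stratify_labels = TRUE,
        master_seed = derive_seed(seed, "cohort")),
      phantom = list(grid_size = 16L),
      model = list(channels = c(4L, 8L)),
      runs = list(
        list(name = "centralized", paradigm = "centralized", max_cycles = 2L,
             early_stopping_patience = Inf),
        list(name = "traveling_fixed_e1", paradigm = "traveling",
             order = "fixed", local_epochs = 1L, max_cycles = 2L),
        list(name = "traveling_random_e1", paradigm = "traveling",
             order = "random", local_epochs = 1L, max_cycles = 2L)),
      out_dir = out_dir, seed = seed,
      split = list(small_center_threshold = 2L))
  )
}

#' Rank completed runs by final AUROC
#'
#' @param histories named list of `tm_history` objects, or a character vector
#'   of history CSV paths.
#' @return data.frame ranked by final-cycle AUROC (descending), with best
#'   cycle and instability annotation.
#' @export
compare_runs <- function(histories) {
  if (is.character(histories)) {
    paths <- histories
    histories <- lapply(paths, read_history)
    names(histories) <- sub("\\.csv$", "", sub("^history_", "", basename(paths)))
  }
  if (length(histories) == 0L) stop("need at least one history")
  rows <- lapply(names(histories), function(nm) {
    h <- histories[[nm]]
    if (nrow(h) == 0L) stop("history '", nm, "' is empty")
    b <- best_cycle(h)
    data.frame(run = nm, cycles = nrow(h), final_auroc = h$auroc[nrow(h)],
               best_cycle = b$cycle, best_auroc = b$auroc,
               instability = if (nrow(h) >= 2L) instability_index(h$auroc) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$final_auroc, out$run), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
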