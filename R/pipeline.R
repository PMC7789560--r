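# Orchestration: experiment configuration, the five-phase protocol per
# synthetic subject (familiarization [no data] -> acquisition -> training ->
# two counterbalanced hybrid test phases -> natural baseline), recording
# I/O, metrics/synergy/stats aggregation and report generation. All RNG
# streams are seeded and namespaced per subject and phase, making a full
# run deterministic from its configuration.

#' Experiment configuration
#'
#' @param n_subjects Number of synthetic subjects (counterbalanced: odd
#'   subject indices test C+ first).
#' @param geometry An [arm_geometry()].
#' @param grid A [grid_config()].
#' @param subjects Optional list of [subject_params()]; by default
#'   `n_subjects` subjects with seeds derived from `master_seed`.
#' @param min_whole,min_subset Minimum target-order lengths (study values
#'   200 and 100).
#' @param max_whole,max_subset Optional order truncations for scaled-down
#'   runs (the study draws run to a dead end).
#' @param hyper A [predictor_hyper()].
#' @param context_coupling Context-coupling value given to default-built
#'   subjects.
#' @param master_seed Master seed from which all per-subject, per-phase
#'   seeds are derived.
#' @param out_dir Output directory for recordings and the report (`NULL`
#'   keeps everything in memory).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 2L,
                              geometry = arm_geometry(),
                              grid = grid_config(),
                              subjects = NULL,
                              min_whole = 200L, min_subset = 100L,
                              max_whole = Inf, max_subset = Inf,
                              hyper = predictor_hyper(),
                              context_coupling = 1.0,
                              master_seed = 1L,
                              out_dir = NULL) {
  if (is.null(subjects)) {
    subjects <- lapply(seq_len(n_subjects), function(i) {
      subject_params(context_coupling = context_coupling,
                     seed = derive_seed(master_seed, "subject", i))
    })
  }
  structure(list(geometry = geometry, grid = grid, subjects = subjects,
                 min_whole = as.integer(min_whole),
                 min_subset = as.integer(min_subset),
                 max_whole = max_whole, max_subset = max_subset,
                 hyper = hyper, master_seed = as.integer(master_seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Recognised keys: `n_subjects`, `context_coupling`, `master_seed`,
#' `min_whole`, `min_subset`, `out_dir`, `arm.lengths.{upper,fore,hand}`,
#' `arm.comfort_posture`, `grid.{spacing,anterior_offset,center_rise}`,
#' `predictor.{learning_rate,batch_size,max_epochs,patience}`.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  geometry <- arm_geometry(
    upper_arm_length = y$arm$lengths$upper %||% 0.30,
    forearm_length = y$arm$lengths$fore %||% 0.25,
    hand_length = y$arm$lengths$hand %||% 0.08)
  grid <- grid_config(
    spacing = y$grid$spacing %||% 0.08,
    anterior_offset = y$grid$anterior_offset %||% 0.24,
    center_rise = y$grid$center_rise %||% 0.08)
  hyper <- do.call(predictor_hyper, as.list(y$predictor %||% list()))
  experiment_config(
    n_subjects = y$n_subjects %||% 2L,
    geometry = geometry, grid = grid,
    min_whole = y$min_whole %||% 200L,
    min_subset = y$min_subset %||% 100L,
    max_whole = y$max_whole %||% Inf,
    max_subset = y$max_subset %||% Inf,
    hyper = hyper,
    context_coupling = y$context_coupling %||% 1.0,
    master_seed = y$master_seed %||% 1L,
    out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a motion recording as CSV (+ JSON sidecar)
#'
#' The per-sample table goes to `<path>`, the per-trial table to
#' `<path base>_trials.csv`, and a JSON sidecar `<path base>.json` stores
#' the phase label, rate and schema version. Reading is header-driven
#' (column order free); a file missing the `in_zone` column triggers the
#' recompute path (which requires a tolerance).
#'
#' @param recording A `motion_recording`.
#' @param path CSV path for the per-sample table.
#' @return `write_recording`: the path, invisibly. `read_recording`: a
#'   `motion_recording`.
#' @export
write_recording <- function(recording, path) {
  base <- sub("\\.csv$", "", path)
  utils::write.csv(recording$data, path, row.names = FALSE)
  utils::write.csv(recording$trials, paste0(base, "_trials.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(schema = 1L, phase = recording$phase,
                            subject_id = recording$subject_id,
                            rate = recording$rate),
                       paste0(base, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @param tol A [tolerance()], needed only when the stored file lacks the
#'   `in_zone` column and the flags must be recomputed.
#' @param geometry An [arm_geometry()], for the recompute path.
#' @export
read_recording <- function(path, tol = NULL, geometry = arm_geometry()) {
  base <- sub("\\.csv$", "", path)
  side <- paste0(base, ".json")
  if (!file.exists(side)) stop("missing recording sidecar: ", side)
  meta <- jsonlite::read_json(side)
  if (is.null(meta$schema) || meta$schema != 1L) {
    stop("unknown recording schema version")
  }
  d <- utils::read.csv(path)
  needed <- c("t", "trial_id", DOF_NAMES, "shx", "shy", "shz")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols)) {
    stop("recording file lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  trials <- utils::read.csv(paste0(base, "_trials.csv"))
  rec <- make_recording(d, trials, meta$phase,
                        meta$subject_id %||% 1L, meta$rate %||% 90)
  if (!"in_zone" %in% names(d)) {
    if (is.null(tol)) {
      stop("stored recording lacks in_zone flags; supply `tol` to recompute")
    }
    message("recomputing in_zone flags from poses and targets")
    rec$data$in_zone <- recompute_in_zone(rec, tol, geometry)
  }
  rec
}

# counterbalancing rule: odd subject indices test C+ first, even C- first,
# so any even-sized cohort is split half and half
counterbalance_order <- function(i) {
  if (i %% 2 == 1) c("C+", "C-") else c("C-", "C+")
}

subject_protocol <- function(config, i) {
  subj <- config$subjects[[i]]
  geometry <- config$geometry
  ms <- config$master_seed
  grid <- build_target_grid(geometry, config$grid)
  whole <- build_target_set(grid, "whole")
  subset <- build_target_set(grid, "subset")
  order_acq <- generate_target_order(whole, config$min_whole,
                                     derive_seed(ms, "order-acq", i),
                                     max_length = config$max_whole %||% Inf)
  order_test <- generate_target_order(subset, config$min_subset,
                                      derive_seed(ms, "order-test", i),
                                      max_length = config$max_subset %||%
                                        Inf)
  # acquisition: natural control, whole set, strict tolerance
  acq <- simulate_phase_natural(order_acq, tolerance_acquisition(), subj,
                                geometry, phase = "acquisition",
                                seed = derive_seed(ms, "acq", i))
  ds_cplus <- build_dataset(acq, "C+")
  ds_cminus <- build_dataset(acq, "C-")
  mod_cplus <- train_predictor(ds_cplus, config$hyper,
                               seed = derive_seed(ms, "train-C+", i),
                               limits = geometry$limits)
  mod_cminus <- train_predictor(ds_cminus, config$hyper,
                                seed = derive_seed(ms, "train-C-", i),
                                limits = geometry$limits)
  # two hybrid test phases over the same subset order, counterbalanced
  run_test <- function(model, label) {
    simulate_phase_hybrid(order_test, model, tolerance_test(), subj,
                          geometry, phase = paste0("test", label),
                          seed = derive_seed(ms, "test", label, i))
  }
  phase_order <- counterbalance_order(i)
  if (phase_order[1] == "C+") {
    test_cplus <- run_test(mod_cplus, "C+")
    test_cminus <- run_test(mod_cminus, "C-")
  } else {
    test_cminus <- run_test(mod_cminus, "C-")
    test_cplus <- run_test(mod_cplus, "C+")
  }
  # baseline: natural control, subset order, test tolerances
  baseline <- simulate_phase_natural(order_test, tolerance_test(), subj,
                                     geometry, phase = "baseline",
                                     seed = derive_seed(ms, "base", i))
  ds_base_cplus <- build_dataset(baseline, "C+")
  ds_base_cminus <- build_dataset(baseline, "C-")
  rmse <- list(
    train_cplus = offline_rmse(mod_cplus, ds_cplus)$pooled,
    train_cminus = offline_rmse(mod_cminus, ds_cminus)$pooled,
    baseline_cplus = offline_rmse(mod_cplus, ds_base_cplus)$pooled,
    baseline_cminus = offline_rmse(mod_cminus, ds_base_cminus)$pooled)
  list(subject = i, phase_order = phase_order,
       recordings = list(acquisition = acq, `testC+` = test_cplus,
                         `testC-` = test_cminus, baseline = baseline),
       models = list(`C+` = mod_cplus, `C-` = mod_cminus),
       rmse = rmse)
}

subject_analysis <- function(sp) {
  mets <- list(N = phase_metrics(sp$recordings$baseline),
               `C+` = phase_metrics(sp$recordings$`testC+`),
               `C-` = phase_metrics(sp$recordings$`testC-`))
  postures <- list(
    N = average_reaching_postures(sp$recordings$baseline, "N"),
    `C+` = average_reaching_postures(sp$recordings$`testC+`, "C+"),
    `C-` = average_reaching_postures(sp$recordings$`testC-`, "C-"),
    `MC+` = average_reaching_postures(sp$recordings$`testC+`, "MC+",
                                      mimicked = TRUE),
    `MC-` = average_reaching_postures(sp$recordings$`testC-`, "MC-",
                                      mimicked = TRUE))
  pca <- lapply(postures, run_pca)
  sds <- lapply(postures, posture_sd)
  dist_to_n <- vapply(c("C+", "C-", "MC+", "MC-"), function(g) {
    subspace_distance(pca[[g]], pca$N, 3)
  }, numeric(1))
  list(metrics = mets, postures = postures, pca = pca, posture_sds = sds,
       dist_to_n = dist_to_n,
       cum_ev3 = vapply(pca, cumulative_ev, numeric(1), n = 3))
}

#' Run the full experiment
#'
#' For each synthetic subject: acquisition recording (whole-set order,
#' tolerance 2 cm / 5 deg), dataset construction, C+/C- training, two
#' counterbalanced hybrid test phases (subset order, 4 cm / 10 deg),
#' natural baseline over the same subset order, then per-subject metrics,
#' synergy analyses, cross-subject statistics (when at least 3 subjects)
#' and the tabular report.
#'
#' @param config An [experiment_config()].
#' @return A list of class `run_manifest`: `config_hash`, per-subject
#'   `subjects` (protocol outputs + analyses), aggregated `results`
#'   tables, cross-subject `stats`, `results_hash` (hash of all numeric
#'   results; identical configs give identical hashes), and `report_dir`
#'   when `config$out_dir` is set.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  n <- length(config$subjects)
  subjects <- vector("list", n)
  analyses <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- subject_protocol(config, i)
    analyses[[i]] <- subject_analysis(subjects[[i]])
  }
  rmse_table <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- subjects[[i]]$rmse
    data.frame(subject = i,
               network = rep(c("C+", "C-"), 2),
               dataset = rep(c("training", "baseline"), each = 2),
               rmse = c(r$train_cplus, r$train_cminus,
                        r$baseline_cplus, r$baseline_cminus))
  }))
  online_table <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- analyses[[i]]$metrics
    do.call(rbind, lapply(names(m), function(g) {
      data.frame(subject = i, condition = g,
                 mean_at = m[[g]]$mean_at, mean_as = m[[g]]$mean_as,
                 sv_cm3 = m[[g]]$sv$volume_cm3,
                 success_rate = m[[g]]$success_rate)
    }))
  }))
  variability_table <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- analyses[[i]]$posture_sds
    do.call(rbind, lapply(names(s), function(g) {
      data.frame(subject = i, group = g, dof = DOF_NAMES,
                 sd = unname(s[[g]]))
    }))
  }))
  subspace_table <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject = i, pair = paste0(names(analyses[[i]]$dist_to_n),
                                          " vs N"),
               n = 3, angle = unname(analyses[[i]]$dist_to_n))
  }))
  results <- list(rmse_table = rmse_table, online_table = online_table,
                  variability_table = variability_table,
                  subspace_table = subspace_table)
  stats <- NULL
  if (n >= 3) {
    by_cond <- function(col) {
      lapply(stats::setNames(c("N", "C+", "C-"), c("N", "C+", "C-")),
             function(g) online_table[[col]][online_table$condition == g])
    }
    stats <- list(
      rmse_training = paired_rmse_test(
        rmse_table$rmse[rmse_table$network == "C+" &
                          rmse_table$dataset == "training"],
        rmse_table$rmse[rmse_table$network == "C-" &
                          rmse_table$dataset == "training"]),
      at = compare_conditions(by_cond("mean_at")),
      as_ = compare_conditions(by_cond("mean_as")),
      sv = compare_conditions(by_cond("sv_cm3")))
  }
  hash_src <- list(rmse = round(rmse_table$rmse, 9),
                   online = round(as.matrix(online_table[, 3:6]), 9),
                   variability = round(variability_table$sd, 9),
                   subspace = round(subspace_table$angle, 9))
  manifest <- structure(list(
    config_hash = rlang::hash(config),
    n_subjects = n,
    phase_order = lapply(subjects, `[[`, "phase_order"),
    subjects = subjects, analyses = analyses,
    results = results, stats = stats,
    results_hash = rlang::hash(hash_src)),
    class = "run_manifest")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      for (ph in names(subjects[[i]]$recordings)) {
        write_recording(subjects[[i]]$recordings[[ph]],
                        file.path(config$out_dir,
                                  sprintf("s%02d_%s.csv", i,
                                          gsub("[+]", "plus",
                                               gsub("[-]", "minus", ph)))))
      }
    }
    render_report(results, file.path(config$out_dir, "report"))
    manifest$report_dir <- file.path(config$out_dir, "report")
  }
  manifest
}
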