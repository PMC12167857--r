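#' Validate and complete a run configuration
#'
#' Fills unspecified fields with the pipeline defaults — a 110-km
#' background buffer, 1,000 pseudo-absences in 10 replicates, envelope
#' quantile 0.025, correlation threshold 0.7 with VIF ceiling 10 and a
#' 5,000-row sampling limit, 70:30 splits repeated 3 times, the full
#' six-algorithm roster, and ensemble membership at TSS >= 0.7 — and
#' reports every violation at once.
#'
#' @param raw A named list, or path to a YAML file with the same keys.
#'   Required: `occurrences` (data frame or CSV path) and `stacks` (named
#'   list of [env_stack()] objects or stack directories, containing
#'   `"current"`).
#' @return A validated `run_config` list.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1) raw <- yaml::read_yaml(raw)
  assert_that(is.list(raw), "config must be a list or a YAML path")
  defaults <- list(
    out_dir = NULL,
    thin_dist_km = 5, thin_tries = 10,
    envelope_q = 0.025,
    buffer_km = 110, pa_n = 1000, pa_reps = 10,
    r_threshold = 0.7, vif_threshold = 10, sample_limit = 5000,
    algorithms = ALGORITHM_ROSTER, train_frac = 0.7, cv_runs = 3,
    tune = FALSE, tss_min = 0.7,
    importance_shuffles = 3,
    cell_area_km2 = NULL,
    seed = 1
  )
  cfg <- utils::modifyList(defaults, raw)

  errs <- character()
  bad <- function(msg) errs <<- c(errs, msg)
  if (is.null(cfg$occurrences)) bad("missing field: occurrences")
  else if (is.character(cfg$occurrences) && !file.exists(cfg$occurrences))
    bad(paste0("occurrences path not found: ", cfg$occurrences))
  if (is.null(cfg$stacks) || !length(cfg$stacks)) bad("missing field: stacks")
  else if (!"current" %in% names(cfg$stacks))
    bad("stacks must contain a 'current' entry")
  if (!is_scalar_number(cfg$train_frac) || cfg$train_frac <= 0 || cfg$train_frac >= 1)
    bad("train_frac must be in (0, 1)")
  if (!is_scalar_number(cfg$envelope_q) || cfg$envelope_q < 0 || cfg$envelope_q >= 0.5)
    bad("envelope_q must be in [0, 0.5)")
  if (!is_scalar_number(cfg$r_threshold) || cfg$r_threshold <= 0 || cfg$r_threshold >= 1)
    bad("r_threshold must be in (0, 1)")
  if (!is_scalar_number(cfg$vif_threshold) || cfg$vif_threshold <= 1)
    bad("vif_threshold must be > 1")
  if (!is_scalar_number(cfg$tss_min) || cfg$tss_min < 0 || cfg$tss_min > 1)
    bad("tss_min must be in [0, 1]")
  if (!is_scalar_number(cfg$pa_n) || cfg$pa_n < 1) bad("pa_n must be >= 1")
  if (!is_scalar_number(cfg$pa_reps) || cfg$pa_reps < 1) bad("pa_reps must be >= 1")
  if (!is_scalar_number(cfg$cv_runs) || cfg$cv_runs < 1) bad("cv_runs must be >= 1")
  if (!is_scalar_number(cfg$buffer_km) || cfg$buffer_km <= 0) bad("buffer_km must be > 0")
  if (!all(cfg$algorithms %in% ALGORITHM_ROSTER))
    bad(paste0("unknown algorithm(s): ",
               paste(setdiff(cfg$algorithms, ALGORITHM_ROSTER), collapse = ", ")))
  if (length(errs))
    stop("validation error:\n  - ", paste(errs, collapse = "\n  - "), call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Fit and evaluate the single-model battery
#'
#' The full cross of CV runs x pseudo-absence replicates x algorithms: for
#' each PA replicate the presence/PA design matrix is split `n_runs` times
#' 70:30 (stratified), each algorithm is fitted on the training partition
#' and scored on the held-out partition with TSS (at the max-TSS threshold)
#' and ROC AUC.
#'
#' @param presence_table Design-matrix rows for presences (`label` = 1).
#' @param pa_tables List of design-matrix tibbles, one per PA replicate
#'   (`label` = 0).
#' @param algorithms Character vector from the roster, or list of
#'   [algorithm_spec()]s.
#' @param train_frac,n_runs Split design (defaults 0.7 and 3).
#' @param tune Run [tune_hyperparameters()] per algorithm on the first
#'   replicate's first training partition (default FALSE).
#' @param seed Master seed.
#' @return A scoreboard tibble: `run_id`, `pa_replicate_id`, `algorithm`,
#'   `tss`, `auc`, `threshold`, and list columns `model`, `split`.
#' @export
run_model_battery <- function(presence_table, pa_tables, algorithms,
                              train_frac = 0.7, n_runs = 3, tune = FALSE,
                              seed = 1) {
  specs <- lapply(algorithms, function(a)
    if (inherits(a, "algorithm_spec")) a else algorithm_spec(a))
  rows <- list()
  for (r in seq_along(pa_tables)) {
    tbl <- dplyr::bind_rows(presence_table, pa_tables[[r]])
    splits <- make_cv_splits(tbl, train_frac, n_runs,
                             seed = derive_seed(seed, 97L * r))
    if (tune && r == 1) {
      train1 <- tbl[splits[[1]]$train, ]
      specs <- lapply(specs, function(sp)
        tune_hyperparameters(sp, train1, seed = derive_seed(seed, 7L)))
    }
    for (s in splits) {
      for (sp in specs) {
        fit_seed <- derive_seed(seed, 1000L * r + 10L * s$run_id +
                                  match(sp$algorithm_id, ALGORITHM_ROSTER))
        m <- fit_single_model(sp, tbl[s$train, ], seed = fit_seed)
        m$run_id <- s$run_id
        m$pa_replicate_id <- r
        ev <- evaluate_model(m, tbl[s$test, ])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          run_id = s$run_id, pa_replicate_id = r,
          algorithm = sp$algorithm_id,
          tss = ev$tss, auc = ev$auc, threshold = ev$optimal_threshold,
          model = list(m), split = list(s), table = list(tbl))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full ensemble SDM pipeline
#'
#' Executes clean -> rarefy -> thin -> envelope -> pseudo-absences ->
#' extraction -> correlation/VIF selection -> model battery -> TSS-weighted
#' ensemble -> projection (current and every scenario) -> permutation
#' importance -> CV uncertainty -> max-TSS binarization -> range-shift
#' accounting, from one validated configuration and one master seed (stage
#' seeds are derived by stage name, so stages are independently
#' reproducible).
#'
#' @param config A [validate_config()] result (raw lists are validated
#'   first).
#' @return An `sdm_run`: list with `manifest` (counts, seeds, artifacts),
#'   `selection`, `scoreboard`, `ensemble`, `ensemble_evaluation`,
#'   `suitability_maps`, `binary_maps`, `cv_maps`, `importance`,
#'   `range_change`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  seed <- config$seed
  stacks <- lapply(config$stacks, function(s)
    if (inherits(s, "env_stack")) s else read_env_stack(s))
  current <- stacks[["current"]]
  scenarios <- stacks[names(stacks) != "current"]
  grid <- current$grid

  raw <- config$occurrences
  if (is.character(raw)) raw <- utils::read.csv(raw)

  msg <- function(...) message("[sdmflow] ", ...)
  msg("cleaning occurrences")
  occ <- clean_occurrences(raw, grid)
  occ <- rarefy_to_grid(occ)
  if (config$thin_dist_km > 0)
    occ <- spatial_thin(occ, config$thin_dist_km, config$thin_tries,
                        seed = stage_seed(seed, "thin"))

  msg(nrow(occ), " presences after cleaning/rarefaction/thinning")
  presence_full <- extract_at_cells(current, occ$cell, rep(1L, nrow(occ)))
  envelope <- build_sre_envelope(presence_full, q = config$envelope_q)

  msg("sampling ", config$pa_reps, " x ", config$pa_n, " pseudo-absences")
  pa_sets <- sample_pseudo_absences(current, occ, envelope,
                                    buffer_km = config$buffer_km,
                                    n = config$pa_n, n_reps = config$pa_reps,
                                    seed = stage_seed(seed, "pa"))
  pa_full <- lapply(pa_sets, function(p)
    extract_at_cells(current, p$cell, rep(0L, nrow(p))))

  msg("selecting predictors (vifcor)")
  selection <- vifcor_select(dplyr::bind_rows(presence_full, pa_full[[1]]),
                             r_threshold = config$r_threshold,
                             vif_threshold = config$vif_threshold,
                             sample_limit = config$sample_limit,
                             seed = stage_seed(seed, "vif"))
  vars <- c(selection$kept, selection$passthrough)
  keep_cols <- function(tbl) tbl[, c("label", "cell", vars)]
  presence_tbl <- keep_cols(presence_full)
  pa_tbls <- lapply(pa_full, keep_cols)

  msg("fitting battery: ", config$cv_runs, " runs x ", config$pa_reps,
      " PA sets x ", length(config$algorithms), " algorithms")
  scoreboard <- run_model_battery(presence_tbl, pa_tbls, config$algorithms,
                                  train_frac = config$train_frac,
                                  n_runs = config$cv_runs,
                                  tune = config$tune,
                                  seed = stage_seed(seed, "battery"))

  msg("building ensemble (TSS >= ", config$tss_min, ")")
  ensemble <- select_ensemble_members(scoreboard, tss_min = config$tss_min)

  # Pooled held-out evaluation: the union of every (run, PA) evaluation
  # partition scores the ensemble on the same rows its members were scored on.
  holdout <- dplyr::bind_rows(purrr::map2(
    scoreboard$table[!duplicated(paste(scoreboard$run_id, scoreboard$pa_replicate_id))],
    scoreboard$split[!duplicated(paste(scoreboard$run_id, scoreboard$pa_replicate_id))],
    function(tbl, s) tbl[s$test, ]))
  ensemble_eval <- evaluate_model(ensemble, holdout)
  threshold <- ensemble_eval$optimal_threshold

  msg("projecting ensemble and members")
  all_stacks <- c(list(current = current), scenarios)
  suitability_maps <- lapply(all_stacks, function(s) project_map(ensemble, s))
  cv_maps <- if (length(ensemble$members) >= 2)
    lapply(all_stacks, function(s)
      uncertainty_map(lapply(ensemble$members, project_map, stack = s)))
  else NULL  # CV over a single member is undefined
  binary_maps <- lapply(suitability_maps, binarize_map, threshold = threshold)

  msg("permutation importance")
  importance <- permutation_importance(ensemble, holdout,
                                       n_shuffles = config$importance_shuffles,
                                       seed = stage_seed(seed, "importance"))

  cell_area <- config$cell_area_km2 %||%
    (if (is_geographic(grid)) geographic_cell_areas(grid) else grid$cell_size^2)
  changes <- lapply(names(scenarios), function(nm)
    range_change(binary_maps[["current"]], binary_maps[[nm]], cell_area))
  names(changes) <- names(scenarios)
  range_changes <- if (length(changes)) dplyr::bind_rows(changes) else NULL

  artifacts <- character()
  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(occ), file.path(out, "occurrences.csv"),
                     row.names = FALSE)
    utils::write.csv(dplyr::bind_rows(pa_sets), file.path(out, "pa_sets.csv"),
                     row.names = FALSE)
    utils::write.csv(scoreboard[, c("run_id", "pa_replicate_id", "algorithm",
                                    "tss", "auc", "threshold")],
                     file.path(out, "scoreboard.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(kept = selection$kept, passthrough = selection$passthrough,
           drops = selection$drops, final_vif = as.list(selection$final_vif),
           final_max_r = selection$final_max_r),
      file.path(out, "selection.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(importance), file.path(out, "importance.csv"),
                     row.names = FALSE)
    if (!is.null(range_changes))
      utils::write.csv(as.data.frame(range_changes),
                       file.path(out, "range_change.csv"), row.names = FALSE)
    for (nm in names(suitability_maps)) {
      write_ascii_grid(suitability_maps[[nm]]$values, grid,
                       file.path(out, paste0("suitability_", nm, ".asc")))
      write_ascii_grid(binary_maps[[nm]]$values, grid,
                       file.path(out, paste0("binary_", nm, ".asc")))
      if (!is.null(cv_maps))
        write_ascii_grid(cv_maps[[nm]]$values, grid,
                         file.path(out, paste0("cv_", nm, ".asc")))
    }
    artifacts <- setdiff(list.files(out, full.names = TRUE),
                         file.path(out, "manifest.json"))
  }

  manifest <- list(
    seed = seed,
    counts = list(
      occurrences_raw = nrow(raw),
      presences = nrow(occ),
      removals = as.list(attr(occ, "removals")),
      pa_per_replicate = config$pa_n,
      pa_replicates = config$pa_reps,
      eligible_pa_cells = attr(pa_sets[[1]], "n_eligible"),
      variables_kept = length(selection$kept),
      variables_passthrough = length(selection$passthrough),
      single_model_fits = nrow(scoreboard),
      ensemble_members = length(ensemble$members),
      map_cells = sum(!current$nodata)
    ),
    ensemble = list(threshold = threshold, tss = ensemble_eval$tss,
                    auc = ensemble_eval$auc),
    stage_seeds = list(thin = stage_seed(seed, "thin"),
                       pa = stage_seed(seed, "pa"),
                       vif = stage_seed(seed, "vif"),
                       battery = stage_seed(seed, "battery"),
                       importance = stage_seed(seed, "importance")),
    artifacts = if (length(artifacts))
      lapply(stats::setNames(artifacts, basename(artifacts)),
             function(p) list(path = p, md5 = unname(tools::md5sum(p))))
      else list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(config$out_dir))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

  structure(list(manifest = manifest, config = config, occurrences = occ,
                 selection = selection, scoreboard = scoreboard,
                 ensemble = ensemble, ensemble_evaluation = ensemble_eval,
                 suitability_maps = suitability_maps,
                 binary_maps = binary_maps, cv_maps = cv_maps,
                 importance = importance, range_change = range_changes),
            class = "sdm_run")
}

#' @export
print.sdm_run <- function(x, ...) {
  cnt <- x$manifest$counts
  cat(sprintf(paste0(
    "<sdm_run> %d presences, %d x %d pseudo-absences\n",
    "  %d single models fitted, %d ensemble members (TSS >= %g)\n",
    "  ensemble: TSS %.3f, AUC %.3f, threshold %.3f\n"),
    cnt$presences, cnt$pa_replicates, cnt$pa_per_replicate,
    cnt$single_model_fits, cnt$ensemble_members, x$config$tss_min,
    x$manifest$ensemble$tss, x$manifest$ensemble$auc,
    x$manifest$ensemble$threshold))
  invisible(x)
}

#' @export
glance.sdm_run <- function(x, ...) {
  cnt <- x$manifest$counts
  tibble::tibble(presences = cnt$presences,
                 single_model_fits = cnt$single_model_fits,
                 ensemble_members = cnt$ensemble_members,
                 ensemble_tss = x$manifest$ensemble$tss,
                 ensemble_auc = x$manifest$ensemble$auc,
                 threshold = x$manifest$ensemble$threshold)
}
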