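default_run_config <- function() {
  list(
    input = list(molecules = NULL, pka_exp = NULL),
    energy = list(backend = "surrogate"),
    conformer = list(seed = 1L, energy_window_kcal = 3.0,
                     rmsd_threshold_A = 0.5, max_conformers = 20L),
    calibration = list(threshold = 5.0, max_iter = 10L, exclude_pka_ge = 35),
    descriptor = list(radius = 6L, provider = "surrogate", seed = 1L),
    ml = list(tolerance = 1, budget = 20L, seed = 1L, window = 0),
    output = list(dir = NULL)
  )
}

#' Load a run configuration
#'
#' Reads a YAML file and merges it over the package defaults; every setting
#' of the workflow (backend and provider names, conformer thresholds,
#' calibration rules, descriptor radius, ML tolerance/budget/seeds) lives in
#' one serializable structure that is written next to a run's outputs.
#'
#' @param path YAML path, or NULL for defaults.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' Compute calibrated pKa values for every C-H site
#'
#' The full energy-based workflow: enumerate sites, run the conformer/energy
#' pipeline against the backend, take per-molecule minimum deprotonation
#' energies, fit (or reuse) the linear calibration against experimental pKa
#' values, and convert every site's deprotonation energy to a predicted pKa.
#'
#' @param molecules Molecule table from [read_molecules()].
#' @param backend A `chpka_backend`.
#' @param calibration Either a fitted `chpka_calibration`, or a tibble with
#'   `id`, `pka_exp` giving per-molecule experimental values to fit against.
#' @param seed Conformer seed.
#' @param energy_window_kcal,rmsd_threshold_A,max_conformers Ensemble settings.
#' @param outlier_threshold,max_iter,exclude_pka_ge Calibration settings.
#' @return Tibble: `parent_id`, `atom_index`, `anion_smiles`, `delta_g`,
#'   `pka_pred`, `status`; the fitted calibration is attached as attribute
#'   `"calibration"`.
#' @export
compute_site_pka <- function(molecules, backend, calibration, seed = 1L,
                             energy_window_kcal = 3.0, rmsd_threshold_A = 0.5,
                             max_conformers = 20L, outlier_threshold = 5.0,
                             max_iter = 10L, exclude_pka_ge = 35) {
  sites <- ch_sites(molecules)
  energies <- run_site_energies(molecules, sites, backend, seed = seed,
                                energy_window_kcal = energy_window_kcal,
                                rmsd_threshold_A = rmsd_threshold_A,
                                max_conformers = max_conformers)
  ok <- filter(energies, .data$status != "failed")
  if (inherits(calibration, "chpka_calibration")) {
    fit <- calibration
  } else {
    dgmin <- min_delta_g(filter(ok, !is.na(.data$delta_g)))
    cal_data <- dplyr::inner_join(
      dplyr::rename(dgmin, id = "parent_id"),
      calibration[, c("id", "pka_exp")], by = "id")
    fit <- fit_pka_calibration(
      tibble(id = cal_data$id, delta_g_min = cal_data$delta_g_min,
             pka_exp = cal_data$pka_exp),
      threshold = outlier_threshold, max_iter = max_iter,
      exclude_pka_ge = exclude_pka_ge)
  }
  out <- energies %>%
    mutate(pka_pred = predict_pka(.data$delta_g, fit)) %>%
    select("parent_id", "atom_index", "anion_smiles", "delta_g", "pka_pred",
           "status")
  attr(out, "calibration") <- fit
  out
}

site_aromatic_mask <- function(molecules, sites) {
  mol_of <- setNames(molecules$mol, molecules$id)
  vapply(seq_len(nrow(sites)), function(k) {
    mol_of[[sites$parent_id[k]]]$atoms$aromatic[sites$atom_index[k] + 1L]
  }, logical(1))
}

#' Predict site pKa values with a trained model
#'
#' The fast path: sorted-charge descriptors of every C-H site fed to a
#' trained regressor, plus per-molecule site flags within a pKa window of
#' the predicted minimum. Borylation mode (`aromatic_only = TRUE`,
#' `window = 1.5`) restricts candidates to aromatic C-H sites before taking
#' the window.
#'
#' @param molecules Molecule table.
#' @param model A regressor `chpka_model` carrying its feature schema.
#' @param provider Charge provider matching the model's schema.
#' @param window pKa window for site flags (default 0: minima only).
#' @param aromatic_only Restrict flags to aromatic C-H sites.
#' @param seed Charge seed (overridden by the model schema's seed if set).
#' @return Tibble: `parent_id`, `atom_index`, `anion_smiles`, `pka_pred`,
#'   `flag`.
#' @export
predict_site_pka <- function(molecules, model, provider = surrogate_charge_provider(),
                             window = 0, aromatic_only = FALSE, seed = 1L) {
  stopifnot(inherits(model, "chpka_model"))
  sites <- ch_sites(molecules)
  if (!nrow(sites)) {
    return(tibble(parent_id = character(), atom_index = integer(),
                  anion_smiles = character(), pka_pred = numeric(),
                  flag = integer()))
  }
  schema <- model$schema
  if (!is.null(schema)) {
    if (!identical(provider$name, schema$provider)) {
      abort(paste0("Schema mismatch: model trained with provider '",
                   schema$provider, "', got '", provider$name, "'"),
            class = "chpka_schema_error")
    }
    fm <- build_feature_matrix(sites, molecules, provider,
                               radius = schema$radius, seed = schema$seed,
                               slot_widths = schema$slot_widths)
  } else {
    fm <- build_feature_matrix(sites, molecules, provider, seed = seed)
  }
  feats <- fm$features
  pka <- stats::predict(model$booster, xgboost::xgb.DMatrix(
    feature_matrix_of(feats, model$feature_names)))
  out <- feats %>%
    select("parent_id", "atom_index") %>%
    mutate(pka_pred = pka) %>%
    dplyr::left_join(sites[, c("parent_id", "atom_index", "anion_smiles")],
                     by = c("parent_id", "atom_index"))
  out$mask <- if (aromatic_only) site_aromatic_mask(molecules, out) else TRUE
  out <- site_window(out, window)
  select(out, "parent_id", "atom_index", "anion_smiles", "pka_pred", "flag")
}

write_run_artifacts <- function(out_dir, config, log_lines) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
}

#' File-driven energy workflow run
#'
#' Reads molecules (and per-molecule experimental pKa values) from the paths
#' in `config`, runs [compute_site_pka()] with the configured backend, and
#' writes the site table, the calibration report, the resolved configuration
#' and a timing log to the output directory.
#'
#' @param config Configuration from [read_run_config()].
#' @param backend Optional backend object; by default looked up by name in
#'   the backend registry.
#' @return The site pKa tibble, invisibly.
#' @export
cmd_compute <- function(config, backend = NULL) {
  t0 <- Sys.time()
  backend <- backend %||% get_energy_backend(config$energy$backend)
  molecules <- read_molecules(config$input$molecules)
  pka_exp <- utils::read.csv(config$input$pka_exp, stringsAsFactors = FALSE)
  log_lines <- sprintf("[%s] loaded %d molecules", format(Sys.time()),
                       nrow(molecules))
  res <- compute_site_pka(
    molecules, backend, as_tibble(pka_exp),
    seed = config$conformer$seed,
    energy_window_kcal = config$conformer$energy_window_kcal,
    rmsd_threshold_A = config$conformer$rmsd_threshold_A,
    max_conformers = config$conformer$max_conformers,
    outlier_threshold = config$calibration$threshold,
    max_iter = config$calibration$max_iter,
    exclude_pka_ge = config$calibration$exclude_pka_ge)
  out_dir <- config$output$dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(res), file.path(out_dir, "site_pka.csv"),
                   row.names = FALSE)
  write_calibration_report(attr(res, "calibration"),
                           json_path = file.path(out_dir, "calibration.json"),
                           csv_path = file.path(out_dir, "calibration_residuals.csv"))
  n_im <- sum(res$status == "imaginary_freq")
  if (n_im) {
    log_lines <- c(log_lines, sprintf("WARNING: %d record(s) flagged imaginary_freq", n_im))
  }
  log_lines <- c(log_lines, sprintf(
    "[%s] computed %d site records in %.1f s", format(Sys.time()), nrow(res),
    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  write_run_artifacts(out_dir, config, log_lines)
  invisible(res)
}

#' File-driven model prediction run
#'
#' @param config Configuration from [read_run_config()].
#' @param bundle_dir Model bundle directory ([save_model_bundle()]).
#' @param aromatic_only Borylation mode: restrict flags to aromatic sites.
#' @return The prediction tibble, invisibly.
#' @export
cmd_predict <- function(config, bundle_dir, aromatic_only = FALSE) {
  t0 <- Sys.time()
  model <- load_model_bundle(bundle_dir)
  molecules <- read_molecules(config$input$molecules)
  res <- predict_site_pka(molecules, model,
                          provider = surrogate_charge_provider(),
                          window = config$ml$window,
                          aromatic_only = aromatic_only,
                          seed = config$descriptor$seed)
  out_dir <- config$output$dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(res), file.path(out_dir, "site_predictions.csv"),
                   row.names = FALSE)
  write_run_artifacts(out_dir, config, sprintf(
    "[%s] predicted %d sites in %.1f s", format(Sys.time()), nrow(res),
    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(res)
}
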