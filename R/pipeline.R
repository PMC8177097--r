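# Stage orchestration: validated configuration, deterministic seeded
# execution, JSON reports that embed the seed, a config hash and the
# package version so every output is traceable to its inputs.

PIPELINE_STAGES <- c("simulate", "calibrate", "fit_abs", "fit_fluor",
                     "mass_id", "contacts", "superpose")

#' Pipeline configuration
#'
#' Validates and freezes the settings of a pipeline run. Unknown stage
#' names and missing input files are rejected here, before any output is
#' written.
#'
#' @param stages Character vector of stages to run, in order; subset of
#'   `simulate`, `calibrate`, `fit_abs`, `fit_fluor`, `mass_id`,
#'   `contacts`, `superpose`.
#' @param out_dir Output directory (created if needed at run time).
#' @param seed Integer seed; all stochastic stages derive from it.
#' @param simulate,calibrate,fit_abs,fit_fluor,mass_id,contacts,superpose
#'   Per-stage parameter lists; see the corresponding stage functions.
#'   File-reading stages take `csv` / `path` entries; when `fit_abs` /
#'   `fit_fluor` / `calibrate` have no input file they consume the
#'   `simulate` stage's in-memory output.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(stages, out_dir, seed = 1L,
                            simulate = list(), calibrate = list(),
                            fit_abs = list(), fit_fluor = list(),
                            mass_id = list(), contacts = list(),
                            superpose = list(), log_level = "info") {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop_validation("unknown stage(s): ", paste(unknown, collapse = ", "))
  if (!length(stages)) stop_validation("no stages requested")
  cfg <- list(stages = stages, out_dir = out_dir, seed = as.integer(seed),
              simulate = simulate, calibrate = calibrate,
              fit_abs = fit_abs, fit_fluor = fit_fluor, mass_id = mass_id,
              contacts = contacts, superpose = superpose,
              log_level = match.arg(log_level, c("info", "quiet")))
  # referenced input paths must exist now
  paths <- c(calibrate$csv, fit_abs$csv, fit_fluor$csv, contacts$path,
             superpose$reference, superpose$mobile)
  for (p in paths) if (!is.null(p) && !file.exists(p))
    stop_validation("input file does not exist: ", p)
  if ("fit_abs" %in% stages && !"simulate" %in% stages &&
      is.null(fit_abs$csv))
    stop_validation("fit_abs needs a csv input when simulate is not run")
  if ("fit_fluor" %in% stages && !"simulate" %in% stages &&
      is.null(fit_fluor$csv))
    stop_validation("fit_fluor needs a csv input when simulate is not run")
  structure(cfg, class = "pipeline_config")
}

stop_validation <- function(...) {
  stop(structure(class = c("hemebind_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

# Hash of the scientific configuration: output location and log verbosity
# do not change results, so they are excluded.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$log_level <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

log_msg <- function(config, ...) {
  if (identical(config$log_level, "info"))
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), ...)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in canonical order (simulate, calibrate,
#' fit_abs, fit_fluor, mass_id, contacts, superpose), writing one JSON
#' report per stage plus a run report into `out_dir`. Every report embeds
#' the seed, a hash of the full configuration and the package version.
#' Given the same configuration and seed the written reports are
#' byte-identical across runs (logs go to stderr and carry timestamps;
#' reports do not).
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly; side effect: JSON files in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = config$seed, config_hash = config_hash(config),
               package_version =
                 as.character(utils::packageVersion("hemebind")))
  state <- new.env(parent = emptyenv())
  reports <- list()
  for (stage in PIPELINE_STAGES) {
    if (!stage %in% config$stages) next
    log_msg(config, "stage ", stage)
    rep <- switch(stage,
      simulate = stage_simulate(config, state),
      calibrate = stage_calibrate(config, state),
      fit_abs = stage_fit(config, state, "fit_abs"),
      fit_fluor = stage_fit(config, state, "fit_fluor"),
      mass_id = stage_mass_id(config),
      contacts = stage_contacts(config),
      superpose = stage_superpose(config))
    rep <- c(rep, meta)
    jsonlite::write_json(rep, file.path(config$out_dir,
                                        paste0(stage, ".json")),
                         auto_unbox = TRUE, digits = NA)
    reports[[stage]] <- rep
  }
  run_report <- c(list(stages = config$stages), meta)
  jsonlite::write_json(run_report, file.path(config$out_dir,
                                             "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(reports = reports, meta = meta))
}

simulate_params <- function(config) {
  p <- config$simulate
  do.call(synthetic_config, c(
    list(true_kd = p$true_kd %||% 1.4,
         protein_conc = p$protein_conc %||% 5,
         ligand_concs = p$ligand_concs %||% c(0.5, 1:11),
         seed = config$seed),
    p[setdiff(names(p), c("true_kd", "protein_conc", "ligand_concs",
                          "mode", "seed"))]))
}

stage_simulate <- function(config, state) {
  mode <- config$simulate$mode %||% "absorbance"
  cfg <- simulate_params(config)
  sim <- if (mode == "absorbance") simulate_absorbance_titration(cfg)
         else simulate_fluorescence_titration(cfg)
  state$series <- sim$series
  state$sim_config <- cfg
  csv <- file.path(config$out_dir, "titration.csv")
  write_titration_csv(sim$series, csv)
  write_ground_truth(sim$truth, file.path(config$out_dir,
                                          "ground_truth.json"))
  list(stage = "simulate", mode = mode, true_kd = cfg$true_kd,
       n_points = nrow(sim$series$data), csv = basename(csv))
}

stage_calibrate <- function(config, state) {
  p <- config$calibrate
  if (!is.null(p$csv)) {
    tab <- utils::read.csv(p$csv)
    conc <- tab[[p$conc_col %||% "conc"]]
    absorbance <- tab[[p$abs_col %||% "absorbance"]]
  } else {
    if (is.null(state$sim_config))
      stop_validation("calibrate needs a csv input when simulate is not run")
    cal_cfg <- state$sim_config
    cal_cfg$noise_sd <- 0; cal_cfg$noise_rel <- 0
    tab <- simulate_free_ligand_absorbance(cal_cfg)
    conc <- tab$conc; absorbance <- tab$absorbance
  }
  m <- fit_extinction(conc, absorbance, family = p$family,
                      degree = p$degree %||% 2, ligand = p$ligand,
                      wavelength_nm = p$wavelength_nm %||% 411)
  state$ext_model <- m
  list(stage = "calibrate", family = m$family,
       coefficients = m$coefficients, rss = m$rss, n = m$n_points)
}

stage_fit <- function(config, state, which) {
  p <- config[[which]]
  series <- if (!is.null(p$csv)) {
    read_titration_csv(p$csv, protein_init = p$protein_conc)
  } else state$series
  if (is.null(series)) stop_validation(which, ": no input series")
  fit <- if (which == "fit_abs") {
    if (is.null(state$ext_model))
      stop_validation("fit_abs requires a calibrate stage or model")
    fit_kd_absorbance(series, state$ext_model,
                      free_conc_mode = p$free_conc_mode %||% "free")
  } else {
    fit_kd_fluorescence(series, i_protein = p$i_protein)
  }
  unc <- tryCatch(
    estimate_uncertainty(fit, series,
                         method = p$uncertainty %||% "replicate_sd",
                         B = p$B %||% 200L, seed = config$seed),
    error = function(e) list(kd_sd = NA_real_, method = "unavailable"))
  list(stage = which, kd = fit$kd_hat, kd_sd = unc$kd_sd,
       unit = fit$unit, coefficients = list(
         complex = fit$complex_coefficient,
         protein = fit$protein_coefficient),
       rss = fit$rss, n = fit$n_points, converged = fit$converged,
       method = fit$method, warnings = fit$warnings)
}

stage_mass_id <- function(config) {
  p <- config$mass_id
  if (is.null(p$observed_mz)) stop_validation("mass_id needs observed_mz")
  cands <- lapply(p$candidates %||% list(
    list(formula = "C34H32FeN4O4", charge = 1, added_protons = 0),
    list(formula = "C34H32FeN4O4", charge = 1, added_protons = 1)),
    function(x) do.call(ion_spec, x))
  m <- match_precursor(p$observed_mz, cands, tol_ppm = p$tol_ppm %||% 5)
  pattern <- isotopologue_pattern(
    cands[[if (is.na(m$matched)) 1L else m$matched]]$formula,
    max_peaks = p$max_peaks %||% 6)
  list(stage = "mass_id", observed_mz = p$observed_mz,
       matched = !is.na(m$matched),
       best = if (is.na(m$matched)) NULL else m$best$label,
       report = m$report, pattern = as.data.frame(pattern))
}

stage_contacts <- function(config) {
  p <- config$contacts
  if (is.null(p$path)) stop_validation("contacts needs a structure path")
  model <- parse_structure(p$path, format = p$format)
  rep <- contact_residues(model, p$ligand %||% ":HEM:",
                          cutoff = p$cutoff %||% 4.0)
  hb <- detect_hbonds(model, p$ligand %||% ":HEM:")
  st <- detect_pi_stacking(model, p$ligand %||% ":HEM:")
  list(stage = "contacts", cutoff = rep$cutoff,
       n_residues = nrow(rep$residues), residues = rep$residues,
       waters = rep$waters, others = rep$others,
       hbonds = hb, stacking = st)
}

stage_superpose <- function(config) {
  p <- config$superpose
  if (is.null(p$reference) || is.null(p$mobile))
    stop_validation("superpose needs reference and mobile paths")
  ref <- parse_structure(p$reference, format = p$format)
  mob <- parse_structure(p$mobile, format = p$format)
  sp <- superpose_ca(ref, mob, pairing = p$pairing %||% "by_resnum",
                     chain_ref = p$chain_ref, chain_mobile = p$chain_mobile)
  list(stage = "superpose", rmsd = sp$rmsd, n_atoms = sp$n_atoms,
       pairing = sp$pairing)
}
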