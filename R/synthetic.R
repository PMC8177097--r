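#' Configuration for the synthetic titration generator
#'
#' Bundles the ground-truth parameters from which synthetic absorbance and
#' fluorescence titrations are simulated: the true dissociation constant,
#' the fixed protein concentration, the ligand schedule, the observable
#' coefficients, the free-ligand absorbance law, and the noise model.
#'
#' The defaults emulate a Soret-band spectrophotometric heme titration at
#' 5 uM protein (complex extinction 0.1 AU/uM at 411 nm, curved free-heme
#' law 0.05 c - 0.001 c^2) and a tryptophan-quenching fluorescence readout
#' (free-protein emission 100 counts per concentration unit at 354 nm,
#' quenched complex at 20% of that). They are plausible stand-ins at the
#' scale of published titration figures, not measured constants.
#'
#' @param true_kd True dissociation constant (same unit as concentrations).
#' @param protein_conc Fixed total protein concentration.
#' @param ligand_concs Strictly increasing vector of total ligand
#'   concentrations (the schedule). A zero point may be included.
#' @param conc_unit Concentration unit label, `"uM"` or `"nM"`.
#' @param eps_complex Complex extinction coefficient at the readout
#'   wavelength (AU per concentration unit, 1 cm path).
#' @param free_ligand_law Either a numeric vector of zero-intercept
#'   polynomial coefficients (powers 1, 2, ...) for the free-ligand
#'   absorbance, or a list `list(mode = "monomer_dimer", eps_monomer,
#'   eps_dimer, k_dimer)` for a mechanistic monomer-dimer law where
#'   `k_dimer` is the dimer dissociation constant ([M]^2/[D]).
#' @param i_protein,i_complex Free-protein and complex emission coefficients
#'   at 354 nm (counts per concentration unit); quenching requires
#'   `i_protein > i_complex >= 0`.
#' @param noise_sd Additive Gaussian noise SD, in observable units.
#' @param noise_rel Multiplicative Gaussian noise scale (fraction of the
#'   noiseless value; default 0).
#' @param n_replicates Number of replicate traces (default 3).
#' @param seed Integer RNG seed; a fixed seed makes output bit-reproducible.
#' @return A `synthetic_config` list.
#' @examples
#' cfg <- synthetic_config(true_kd = 1.4, protein_conc = 5,
#'                         ligand_concs = c(0.5, 1:11), noise_sd = 0.003)
#' @export
synthetic_config <- function(true_kd, protein_conc, ligand_concs,
                             conc_unit = "uM",
                             eps_complex = 0.1,
                             free_ligand_law = c(0.05, -0.001),
                             i_protein = 100, i_complex = 20,
                             noise_sd = 0, noise_rel = 0,
                             n_replicates = 3L, seed = 1L) {
  check_conc(true_kd, "true_kd"); check_conc(protein_conc, "protein_conc")
  check_conc(ligand_concs, "ligand_concs")
  if (length(ligand_concs) == 0L)
    stop("'ligand_concs' must be non-empty", call. = FALSE)
  if (any(diff(ligand_concs) <= 0))
    stop("'ligand_concs' must be strictly increasing", call. = FALSE)
  if (noise_sd < 0 || noise_rel < 0)
    stop("noise scales must be >= 0", call. = FALSE)
  if (n_replicates < 1L)
    stop("'n_replicates' must be a positive integer", call. = FALSE)
  if (i_complex < 0 || i_protein < i_complex)
    stop("quenching model requires i_protein > i_complex >= 0", call. = FALSE)
  if (is.list(free_ligand_law)) {
    needed <- c("eps_monomer", "eps_dimer", "k_dimer")
    if (!identical(free_ligand_law$mode, "monomer_dimer") ||
        !all(needed %in% names(free_ligand_law)))
      stop("mechanistic 'free_ligand_law' needs mode = 'monomer_dimer' and ",
           paste(needed, collapse = ", "), call. = FALSE)
  }
  structure(
    list(true_kd = true_kd, protein_conc = protein_conc,
         ligand_concs = ligand_concs, conc_unit = match.arg(conc_unit, c("uM", "nM")),
         eps_complex = eps_complex, free_ligand_law = free_ligand_law,
         i_protein = i_protein, i_complex = i_complex,
         noise_sd = noise_sd, noise_rel = noise_rel,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "synthetic_config")
}

# True free-ligand absorbance at concentration(s) c under the generator's law.
free_absorbance_law <- function(law, conc) {
  if (is.numeric(law)) return(polyval0(law, conc))
  # monomer-dimer: 2[D] + [M] = c, [M]^2 = k_dimer [D]
  k <- law$k_dimer
  m <- (-k + sqrt(k^2 + 8 * k * conc)) / 4
  d <- (conc - m) / 2
  law$eps_monomer * m + law$eps_dimer * d
}

add_noise <- function(values, config) {
  if (config$noise_sd == 0 && config$noise_rel == 0) return(values)
  values +
    stats::rnorm(length(values), 0, config$noise_sd) +
    values * stats::rnorm(length(values), 0, config$noise_rel)
}

#' Simulate a free-ligand calibration table
#'
#' Evaluates the generator's true free-ligand absorbance law at the requested
#' concentrations (default: the config schedule), adding seeded Gaussian
#' noise if configured. `A_free(0) = 0` always.
#'
#' @param config A [synthetic_config()].
#' @param concs Concentrations to evaluate (default `config$ligand_concs`).
#' @return A data.frame with columns `conc`, `absorbance`.
#' @export
simulate_free_ligand_absorbance <- function(config, concs = config$ligand_concs) {
  stopifnot(inherits(config, "synthetic_config"))
  check_conc(concs, "concs")
  a <- free_absorbance_law(config$free_ligand_law, concs)
  a <- with_seed(config$seed, add_noise(a, config))
  data.frame(conc = concs, absorbance = a)
}

# Shared machinery: noiseless observable -> replicated noisy series.
build_series <- function(config, noiseless, observable_kind, seed_offset) {
  n <- length(config$ligand_concs)
  reps <- config$n_replicates
  obs <- with_seed(config$seed + seed_offset,
                   add_noise(rep(noiseless, reps), config))
  data <- data.frame(
    replicate = rep(seq_len(reps), each = n),
    ligand_conc = rep(config$ligand_concs, reps),
    conc_unit = config$conc_unit,
    observable = obs,
    observable_kind = observable_kind,
    stringsAsFactors = FALSE)
  structure(
    list(protein_init = config$protein_conc, conc_unit = config$conc_unit,
         observable_kind = observable_kind, data = data),
    class = "titration_series")
}

#' Simulate a Soret-band absorbance titration
#'
#' For each point of the ligand schedule the equilibrium complex
#' concentration is computed from the true Kd with
#' [complex_concentration()], the noiseless absorbance is assembled as
#' `A = [PL] * eps_complex + A_free([L]_init - [PL])` using the generator's
#' true free-ligand law, and seeded Gaussian noise is added per replicate.
#'
#' @param config A [synthetic_config()].
#' @return A list with `series` (a `titration_series` of kind `"A411"`) and
#'   `truth` (class `ground_truth`: `true_kd`, per-point `pl_eq` and the
#'   noiseless observable).
#' @examples
#' cfg <- synthetic_config(1.4, 5, c(0.5, 1:11), noise_sd = 0.003)
#' sim <- simulate_absorbance_titration(cfg)
#' head(sim$series$data)
#' @export
simulate_absorbance_titration <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  eq <- complex_concentration(config$ligand_concs, config$protein_conc,
                              config$true_kd)
  noiseless <- eq$pl_eq * config$eps_complex +
    free_absorbance_law(config$free_ligand_law, eq$free_ligand)
  series <- build_series(config, noiseless, "A411", seed_offset = 1L)
  truth <- structure(list(true_kd = config$true_kd, pl_eq = eq$pl_eq,
                          noiseless = noiseless),
                     class = "ground_truth")
  list(series = series, truth = truth)
}

#' Simulate a tryptophan-quenching fluorescence titration
#'
#' Noiseless intensity per point is
#' `I = [PL] * i_complex + ([P]_init - [PL]) * i_protein` (quenched complex
#' plus residual free-protein emission at 354 nm, excitation 290 nm);
#' seeded noise is added per replicate.
#'
#' @inheritParams simulate_absorbance_titration
#' @return As [simulate_absorbance_titration()], with observable kind
#'   `"I354"`.
#' @export
simulate_fluorescence_titration <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$protein_conc == 0 && config$i_protein > 0)
    stop("degenerate simulation: zero protein with non-zero emission",
         call. = FALSE)
  eq <- complex_concentration(config$ligand_concs, config$protein_conc,
                              config$true_kd)
  noiseless <- eq$pl_eq * config$i_complex +
    (config$protein_conc - eq$pl_eq) * config$i_protein
  series <- build_series(config, noiseless, "I354", seed_offset = 2L)
  truth <- structure(list(true_kd = config$true_kd, pl_eq = eq$pl_eq,
                          noiseless = noiseless),
                     class = "ground_truth")
  list(series = series, truth = truth)
}

#' Write / read the titration CSV dialect
#'
#' The on-disk format has the exact header
#' `replicate,ligand_conc,conc_unit,observable,observable_kind` with
#' `observable_kind` in `{A411, I354}`. The protein concentration is not
#' part of the table and must be supplied when reading.
#'
#' @param series A `titration_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  utils::write.csv(series$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @param protein_init Total protein concentration of the titration.
#' @export
read_titration_csv <- function(path, protein_init) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("replicate", "ligand_conc", "conc_unit", "observable",
                "observable_kind")
  if (!identical(names(data), expected))
    stop("titration CSV must have header ", paste(expected, collapse = ","),
         call. = FALSE)
  kind <- unique(data$observable_kind)
  unit <- unique(data$conc_unit)
  if (length(kind) != 1L || length(unit) != 1L)
    stop("mixed observable kinds or units in one titration CSV", call. = FALSE)
  structure(list(protein_init = protein_init, conc_unit = unit,
                 observable_kind = kind, data = data),
            class = "titration_series")
}

#' Write the ground truth of a simulation as JSON
#'
#' @param truth A `ground_truth` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series (%s): protein %g %s, %d points x %d replicate(s)\n",
              x$observable_kind, x$protein_init, x$conc_unit,
              length(unique(x$data$ligand_conc)),
              max(x$data$replicate)))
  invisible(x)
}
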