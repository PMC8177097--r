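#' Predicted absorbance of a titration point
#'
#' Total absorbance at the readout wavelength of a protein-ligand mixture in
#' equilibrium: complex contribution plus free-ligand contribution,
#' \deqn{A = [PL] \epsilon_{PL} + A_{free},}
#' where \eqn{[PL]} comes from the depletion-corrected quadratic
#' ([complex_concentration()]) and the free-ligand term is evaluated through
#' a calibrated [fit_extinction()] law. The free-ligand extinction is
#' concentration dependent for aggregating chromophores; by default it is
#' evaluated at the \emph{free} equilibrium concentration
#' (`A_free([L]_init - [PL])`), with `free_conc_mode = "init"` applying the
#' per-concentration coefficient at the initial ligand concentration instead
#' (`([L]_init - [PL]) * A_free([L]_init)/[L]_init`).
#'
#' @param kd Dissociation constant.
#' @param eps_complex Complex extinction coefficient (AU per concentration
#'   unit).
#' @param ext_model Calibrated free-ligand [fit_extinction()] model.
#' @param l_init Ligand schedule (vector).
#' @param p_init Total protein concentration.
#' @param free_conc_mode `"free"` (default) or `"init"`; see Details.
#' @param quiet Suppress extrapolation warnings from the extinction model.
#' @return Predicted absorbance per schedule point (AU).
#' @export
predict_absorbance <- function(kd, eps_complex, ext_model, l_init, p_init,
                               free_conc_mode = c("free", "init"),
                               quiet = FALSE) {
  free_conc_mode <- match.arg(free_conc_mode)
  eq <- complex_concentration(l_init, p_init, kd)
  free_term <- if (free_conc_mode == "free") {
    evaluate_free_contribution(ext_model, eq$free_ligand, quiet = quiet)
  } else {
    eps_at_init <- ifelse(
      l_init > 0,
      evaluate_free_contribution(ext_model, l_init, quiet = quiet) / l_init,
      0)
    eq$free_ligand * eps_at_init
  }
  eq$pl_eq * eps_complex + free_term
}

#' Predicted fluorescence of a titration point
#'
#' Total tryptophan emission at the readout wavelength:
#' \deqn{I = [PL] I_{PL} + ([P]_{init} - [PL]) I_P,}
#' the quenched complex plus residual free-protein emission.
#'
#' @param kd Dissociation constant.
#' @param i_complex,i_protein Complex and free-protein emission coefficients
#'   (counts per concentration unit), both >= 0.
#' @param l_init Ligand schedule (vector).
#' @param p_init Total protein concentration.
#' @return Predicted intensity per schedule point.
#' @export
predict_fluorescence <- function(kd, i_complex, i_protein, l_init, p_init) {
  if (i_complex < 0 || i_protein < 0)
    stop("emission coefficients must be >= 0", call. = FALSE)
  eq <- complex_concentration(l_init, p_init, kd)
  eq$pl_eq * i_complex + (p_init - eq$pl_eq) * i_protein
}

# ---- shared least-squares machinery ------------------------------------

# Multi-start Levenberg-Marquardt on (log kd, linear coefficients).
# residual_fn(par) returns the residual vector; par[1] is log(kd).
# start_grid: matrix, one start per row. Returns the best nls.lm fit,
# tie-broken by lowest RSS then lowest kd.
lm_multistart <- function(residual_fn, start_grid) {
  control <- minpack.lm::nls.lm.control(ftol = 1e-10, maxfev = 10000,
                                        maxiter = 1000)
  best <- NULL
  for (i in seq_len(nrow(start_grid))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start_grid[i, ], fn = residual_fn,
                         control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-14 ||
        (abs(rss - best$rss) <= 1e-14 && fit$par[1] < best$fit$par[1])) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("least-squares fit failed from every start",
                          call. = FALSE)
  best$fit
}

kd_starts <- function(l_init, p_init) {
  scale <- stats::median(l_init[l_init > 0])
  log(c(scale / 20, scale, pmax(scale, p_init) * 20))
}

new_binding_fit <- function(kd_hat, complex_coefficient, protein_coefficient,
                            residuals, fitted, rss, converged, n_points,
                            unit, observable_kind, method, warnings, refit) {
  structure(
    list(kd_hat = kd_hat, kd_sd = NA_real_,
         complex_coefficient = complex_coefficient,
         protein_coefficient = protein_coefficient,
         residuals = residuals, fitted = fitted, rss = rss,
         converged = converged, n_points = n_points, unit = unit,
         observable_kind = observable_kind, method = method,
         warnings = warnings, refit = refit),
    class = "binding_fit")
}

check_series_for_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  d <- series$data
  if (length(unique(d$ligand_conc)) < 3L)
    stop("need at least 3 distinct ligand concentrations to fit",
         call. = FALSE)
  if (all(d$observable == 0))
    stop("all-zero observable: nothing to fit", call. = FALSE)
  d
}

#' Fit the dissociation constant from an absorbance titration
#'
#' Least-squares estimation of (Kd, eps_complex) from a Soret-band
#' absorbance titration under ligand depletion. The model per point is
#' [predict_absorbance()]; the objective is the sum of squared residuals
#' over all points and replicates, minimized by Levenberg-Marquardt over
#' (log Kd, eps_complex) — the log parameterization enforces Kd > 0 — with
#' three starts spanning the concentration schedule, tie-broken by lowest
#' RSS then lowest Kd.
#'
#' @param series A `titration_series` with observable kind `"A411"`.
#' @param ext_model Calibrated free-ligand extinction model whose wavelength
#'   should match the readout.
#' @param free_conc_mode Passed to [predict_absorbance()].
#' @return A `binding_fit`: `kd_hat` (in the series unit), fitted
#'   `complex_coefficient` (eps_complex), residuals, `rss`, `converged`,
#'   `n_points`, method metadata, and accumulated warnings. Use
#'   [estimate_uncertainty()] for `kd_sd`.
#' @examples
#' cfg <- synthetic_config(1.4, 5, c(0.5, 1:11), noise_sd = 0)
#' sim <- simulate_absorbance_titration(cfg)
#' calib <- fit_extinction(seq(0.5, 11, length.out = 12),
#'   simulate_free_ligand_absorbance(cfg, seq(0.5, 11, length.out = 12))$absorbance)
#' fit_kd_absorbance(sim$series, calib)
#' @export
fit_kd_absorbance <- function(series, ext_model,
                              free_conc_mode = c("free", "init")) {
  free_conc_mode <- match.arg(free_conc_mode)
  stopifnot(inherits(ext_model, "extinction_model"))
  d <- check_series_for_fit(series)
  if (!identical(series$observable_kind, "A411"))
    warning("fitting the absorbance model to observable kind '",
            series$observable_kind, "'", call. = FALSE)
  l <- d$ligand_conc; a <- d$observable; p <- series$protein_init
  warn <- character()
  if (any(l > ext_model$valid_range[2] * (1 + 1e-9)))
    warn <- c(warn, "schedule exceeds the calibrated extinction range; extrapolating")

  residual_fn <- function(par) {
    predict_absorbance(exp(par[1]), par[2], ext_model, l, p,
                       free_conc_mode = free_conc_mode, quiet = TRUE) - a
  }
  starts <- kd_starts(l, p)
  start_grid <- t(vapply(starts, function(lk) {
    pl <- complex_concentration(l, p, exp(lk))$pl_eq
    free <- predict_absorbance(exp(lk), 0, ext_model, l, p,
                               free_conc_mode = free_conc_mode, quiet = TRUE)
    eps0 <- sum(pl * (a - free)) / max(sum(pl^2), .Machine$double.eps)
    c(lk, max(eps0, 1e-6))
  }, numeric(2)))
  fit <- lm_multistart(residual_fn, start_grid)

  # refits (replicates, bootstrap) start from the full solution: one start
  # at the optimum is enough for perturbed copies of the same data
  refit <- function(obs) {
    f <- function(par) {
      predict_absorbance(exp(par[1]), par[2], ext_model, l, p,
                         free_conc_mode = free_conc_mode, quiet = TRUE) - obs
    }
    exp(lm_multistart(f, rbind(fit$par))$par[1])
  }
  kd_hat <- exp(fit$par[1])
  for (w in warn) warning(w, call. = FALSE)
  new_binding_fit(
    kd_hat = kd_hat, complex_coefficient = fit$par[2],
    protein_coefficient = NA_real_,
    residuals = -fit$fvec, fitted = a + fit$fvec,
    rss = sum(fit$fvec^2),
    converged = fit$info %in% 1:4, n_points = length(a),
    unit = series$conc_unit, observable_kind = series$observable_kind,
    method = list(model = "absorbance", free_conc_mode = free_conc_mode,
                  optimizer = "nls.lm multi-start on log(Kd)"),
    warnings = warn, refit = refit)
}

#' Fit the dissociation constant from a fluorescence-quenching titration
#'
#' Least-squares estimation of (Kd, I_complex) from a tryptophan-quenching
#' titration. The free-protein emission coefficient I_P is fixed from the
#' mean zero-ligand baseline by default (`i_protein = NULL` with a zero
#' point present), supplied explicitly, or co-fitted
#' (`co_fit_protein = TRUE`).
#'
#' In the tight-binding regime (protein concentration much above Kd) the
#' titration approaches a piecewise-linear saturation curve and Kd is only
#' weakly identified; a warning is emitted when `p_init / kd_hat > 10`.
#'
#' @param series A `titration_series` with observable kind `"I354"`.
#' @param i_protein Free-protein emission coefficient; `NULL` to fix it
#'   from the zero-ligand baseline.
#' @param co_fit_protein Co-fit I_P together with Kd and I_complex.
#' @return A `binding_fit`; `protein_coefficient` holds I_P.
#' @export
fit_kd_fluorescence <- function(series, i_protein = NULL,
                                co_fit_protein = FALSE) {
  d <- check_series_for_fit(series)
  if (!identical(series$observable_kind, "I354"))
    warning("fitting the fluorescence model to observable kind '",
            series$observable_kind, "'", call. = FALSE)
  l <- d$ligand_conc; obs <- d$observable; p <- series$protein_init
  if (p <= 0) stop("protein concentration must be > 0", call. = FALSE)
  if (is.null(i_protein) && !co_fit_protein) {
    zero <- obs[l == 0]
    if (length(zero) == 0L)
      stop("no zero-ligand point: supply 'i_protein' or set co_fit_protein",
           call. = FALSE)
    i_protein <- mean(zero) / p
  }
  starts <- kd_starts(l, p)
  if (co_fit_protein) {
    ip0 <- if (is.null(i_protein)) max(obs) / p else i_protein
    residual_fn <- function(par)
      predict_fluorescence(exp(par[1]), pmax(par[2], 0), pmax(par[3], 0),
                           l, p) - obs
    start_grid <- t(vapply(starts, function(lk)
      c(lk, ip0 * 0.2, ip0), numeric(3)))
  } else {
    residual_fn <- function(par)
      predict_fluorescence(exp(par[1]), pmax(par[2], 0), i_protein, l, p) - obs
    start_grid <- t(vapply(starts, function(lk) {
      pl <- complex_concentration(l, p, exp(lk))$pl_eq
      base <- (p - pl) * i_protein
      ic0 <- sum(pl * (obs - base)) / max(sum(pl^2), .Machine$double.eps)
      c(lk, max(ic0, 0))
    }, numeric(2)))
  }
  fit <- lm_multistart(residual_fn, start_grid)
  kd_hat <- exp(fit$par[1])
  warn <- character()
  if (p / kd_hat > 10) {
    warn <- "tight-binding regime (p_init/Kd > 10): Kd is weakly identified"
    warning(warn, call. = FALSE)
  }
  refit <- function(o) {
    f <- function(par)
      predict_fluorescence(exp(par[1]), pmax(par[2], 0),
                           if (co_fit_protein) pmax(par[3], 0) else i_protein,
                           l, p) - o
    exp(lm_multistart(f, rbind(fit$par))$par[1])
  }
  new_binding_fit(
    kd_hat = kd_hat, complex_coefficient = fit$par[2],
    protein_coefficient = if (co_fit_protein) fit$par[3] else i_protein,
    residuals = -fit$fvec, fitted = obs + fit$fvec,
    rss = sum(fit$fvec^2),
    converged = fit$info %in% 1:4, n_points = length(obs),
    unit = series$conc_unit, observable_kind = series$observable_kind,
    method = list(model = "fluorescence",
                  i_protein_source = if (co_fit_protein) "co-fitted"
                                     else "fixed",
                  optimizer = "nls.lm multi-start on log(Kd)"),
    warnings = warn, refit = refit)
}

#' Uncertainty of the fitted dissociation constant
#'
#' Two estimators are provided because titration papers rarely state which
#' one their plus/minus values are: `replicate_sd` refits each replicate
#' trace separately and reports the standard deviation of the per-replicate
#' Kd estimates; `residual_bootstrap` resamples the fit residuals with
#' replacement, refits `B` perturbed datasets, and reports the bootstrap
#' standard deviation and a percentile confidence interval.
#'
#' @param fit A `binding_fit` from [fit_kd_absorbance()] or
#'   [fit_kd_fluorescence()].
#' @param series The series that was fitted.
#' @param method `"replicate_sd"` or `"residual_bootstrap"`.
#' @param B Bootstrap replicates (default 200).
#' @param level Confidence level for the bootstrap percentile interval.
#' @param seed RNG seed (bootstrap only); fixed seed gives identical output.
#' @return A list with `kd_sd`, `method`, and either `replicate_kds` or
#'   `ci` (percentile interval) plus `boot_kds`.
#' @export
estimate_uncertainty <- function(fit, series,
                                 method = c("replicate_sd",
                                            "residual_bootstrap"),
                                 B = 200L, level = 0.95, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "binding_fit"))
  d <- series$data
  if (method == "replicate_sd") {
    reps <- unique(d$replicate)
    if (length(reps) < 2L)
      stop("replicate_sd needs >= 2 replicates; use residual_bootstrap",
           call. = FALSE)
    # refit expects observations on the full point grid, replicate-major;
    # refit each replicate by tiling its trace across the grid
    kds <- vapply(reps, function(r) {
      sub <- d[d$replicate == r, ]
      obs <- rep(sub$observable, length.out = nrow(d))
      fit$refit(obs)
    }, numeric(1))
    list(kd_sd = stats::sd(kds), method = method, replicate_kds = kds)
  } else {
    fitted <- fit$fitted
    res <- fit$residuals
    boot_kds <- with_seed(seed, vapply(seq_len(B), function(b) {
      obs <- fitted + sample(res, length(res), replace = TRUE)
      fit$refit(obs)
    }, numeric(1)))
    alpha <- (1 - level) / 2
    list(kd_sd = stats::sd(boot_kds), method = method,
         ci = unname(stats::quantile(boot_kds, c(alpha, 1 - alpha))),
         boot_kds = boot_kds)
  }
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit (%s model): Kd = %.4g %s", x$method$model,
              x$kd_hat, x$unit))
  if (!is.na(x$kd_sd)) cat(sprintf(" +/- %.2g", x$kd_sd))
  cat(sprintf("\n  complex coefficient %.4g; RSS %.4g over %d points; %s\n",
              x$complex_coefficient, x$rss, x$n_points,
              if (x$converged) "converged" else "NOT converged"))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
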