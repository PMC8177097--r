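#' Fit the free-ligand extinction law
#'
#' Calibrates the absorbance-versus-concentration relationship of the free
#' ligand at the readout wavelength. Free heme self-associates in aqueous
#' buffer, so its apparent extinction is concentration dependent and the
#' calibration is polynomial; hematoporphyrin obeys Beer-Lambert and is
#' fitted linearly. The intercept is fixed at zero (buffer blank subtracted
#' upstream; zero absorbance at zero concentration).
#'
#' @param conc Ligand concentrations (>= 0), at least `degree` distinct
#'   non-zero values.
#' @param absorbance Measured absorbances (AU), same length as `conc`.
#' @param family `"polynomial"` or `"linear"`. If missing and `ligand` is
#'   given, chosen by [extinction_family()].
#' @param degree Polynomial degree (default 2). `family = "linear"` forces
#'   degree 1.
#' @param ligand Optional ligand tag (`"heme"`, `"hemin"`, `"HP"`, ...)
#'   used to pick the family when `family` is missing.
#' @param wavelength_nm Readout wavelength, stored as metadata (default 411).
#' @return An `extinction_model`: coefficients (power 1..degree; zero
#'   intercept), family, degree, `valid_range`, wavelength, and fit
#'   diagnostics (`rss`, `n_points`).
#' @examples
#' m <- fit_extinction(c(1, 2, 4), c(0.049, 0.096, 0.184), family = "polynomial")
#' evaluate_free_contribution(m, 2)
#' @seealso [evaluate_free_contribution()]
#' @export
fit_extinction <- function(conc, absorbance, family = NULL, degree = 2,
                           ligand = NULL, wavelength_nm = 411) {
  check_conc(conc, "conc")
  if (!is.numeric(absorbance) || any(!is.finite(absorbance)))
    stop("'absorbance' must be finite numeric", call. = FALSE)
  if (length(conc) != length(absorbance))
    stop("'conc' and 'absorbance' lengths differ", call. = FALSE)
  if (is.null(family)) {
    family <- if (is.null(ligand)) "polynomial" else extinction_family(ligand)
  }
  family <- match.arg(family, c("polynomial", "linear"))
  if (family == "linear") degree <- 1L
  degree <- as.integer(degree)
  if (degree < 1L) stop("'degree' must be >= 1", call. = FALSE)
  n_distinct <- length(unique(conc[conc > 0]))
  if (n_distinct < degree)
    stop(sprintf(
      "rank-deficient design: %d distinct non-zero concentrations for degree %d",
      n_distinct, degree), call. = FALSE)
  X <- outer(conc, seq_len(degree), `^`)
  fit <- stats::lm.fit(X, absorbance)
  if (fit$rank < degree)
    stop("rank-deficient design: calibration points do not determine the fit",
         call. = FALSE)
  beta <- unname(fit$coefficients)
  rss <- sum(fit$residuals^2)
  structure(
    list(family = family, degree = degree, coefficients = beta,
         # the enforced zero intercept anchors the law at c = 0, so the
         # calibrated domain always starts there
         valid_range = c(0, max(conc)), wavelength_nm = wavelength_nm,
         rss = rss, n_points = length(conc)),
    class = "extinction_model")
}

#' Default extinction family for a ligand
#'
#' Free heme aggregates (monomer-dimer equilibrium), giving a curved
#' absorbance-concentration relation calibrated with a polynomial;
#' hematoporphyrin stays monomeric at assay concentrations and is linear.
#'
#' @param ligand Character tag: `"heme"`/`"hemin"` map to `"polynomial"`,
#'   `"HP"`/`"hematoporphyrin"` to `"linear"`.
#' @return `"polynomial"` or `"linear"`.
#' @export
extinction_family <- function(ligand) {
  switch(tolower(ligand),
         "heme" = , "hemin" = , "heme b" = "polynomial",
         "hp" = , "hematoporphyrin" = "linear",
         stop(sprintf("unknown ligand tag '%s'", ligand), call. = FALSE))
}

#' Free-ligand absorbance contribution
#'
#' Evaluates the calibrated extinction law at a free-ligand concentration:
#' the `A_free` term of the total-absorbance model. By construction
#' `A_free(0) = 0`. Evaluation outside the calibrated concentration range is
#' allowed (polynomial extrapolation) but raises a warning unless
#' `quiet = TRUE`.
#'
#' @param model An [fit_extinction()] result.
#' @param free_conc Free ligand concentration(s), >= 0.
#' @param quiet Suppress the out-of-range warning (used inside optimizers).
#' @return Absorbance (AU), same length as `free_conc`.
#' @export
evaluate_free_contribution <- function(model, free_conc, quiet = FALSE) {
  stopifnot(inherits(model, "extinction_model"))
  check_conc(free_conc, "free_conc")
  out_of_range <- free_conc > model$valid_range[2] * (1 + 1e-9)
  if (!quiet && any(out_of_range))
    warning(sprintf(
      "%d concentration(s) outside the calibrated range [%g, %g]; extrapolating",
      sum(out_of_range), model$valid_range[1], model$valid_range[2]),
      call. = FALSE)
  polyval0(model$coefficients, free_conc)
}

#' @export
print.extinction_model <- function(x, ...) {
  cat(sprintf("Extinction model (%s, degree %d) at %g nm\n",
              x$family, x$degree, x$wavelength_nm))
  cat("  coefficients (powers 1..degree):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  cat(sprintf("  calibrated range [%g, %g], n = %d, RSS = %.3g\n",
              x$valid_range[1], x$valid_range[2], x$n_points, x$rss))
  invisible(x)
}
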