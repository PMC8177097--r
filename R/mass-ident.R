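# Exact-mass and isotopologue machinery for ligand identification by
# high-resolution MS. Isotope masses and abundances are embedded (IUPAC 2021
# values) so nothing is fetched at run time.

# One row per isotope: element, exact mass (Da), isotopic abundance.
ISOTOPES <- local({
  tab <- rbind(
    c("H",  1.0078250319,  0.999885), c("H",  2.0141017779, 0.000115),
    c("C", 12.0000000000,  0.9893),   c("C", 13.0033548350, 0.0107),
    c("N", 14.0030740040,  0.99636),  c("N", 15.0001088990, 0.00364),
    c("O", 15.9949146196,  0.99757),  c("O", 16.9991317570, 0.00038),
    c("O", 17.9991596130,  0.00205),
    c("P", 30.9737619980,  1.0),
    c("S", 31.9720711740,  0.9499),   c("S", 32.9714589100, 0.0075),
    c("S", 33.9678670040,  0.0425),   c("S", 35.9670807100, 0.0001),
    c("Cl", 34.9688526820, 0.7576),   c("Cl", 36.9659026020, 0.2424),
    c("Na", 22.9897692820, 1.0),
    c("K", 38.9637064860,  0.932581), c("K", 39.9639981660, 0.000117),
    c("K", 40.9618252580,  0.067302),
    c("Mg", 23.9850416970, 0.7899),   c("Mg", 24.9858369760, 0.1000),
    c("Mg", 25.9825929680, 0.1101),
    c("Fe", 53.9396083060, 0.05845),  c("Fe", 55.9349363260, 0.91754),
    c("Fe", 56.9353928410, 0.02119),  c("Fe", 57.9332744310, 0.00282),
    c("Zn", 63.9291420130, 0.4917),   c("Zn", 65.9260336390, 0.2773),
    c("Zn", 66.9271277460, 0.0404),   c("Zn", 67.9248442320, 0.1845),
    c("Zn", 69.9253192100, 0.0061),
    c("Cu", 62.9295977230, 0.6915),   c("Cu", 64.9277894870, 0.3085))
  data.frame(element = tab[, 1], mass = as.numeric(tab[, 2]),
             abundance = as.numeric(tab[, 3]), stringsAsFactors = FALSE)
})

ELECTRON_MASS <- 0.00054857990888  # Da
PROTON_MASS   <- 1.00727646688     # Da (H atom minus one electron)
H_ATOM_MASS   <- 1.0078250319      # Da

#' Parse a molecular formula in Hill notation
#'
#' @param formula A string such as `"C34H32FeN4O4"`, or an already-parsed
#'   named integer vector (returned unchanged after validation).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C34H32FeN4O4")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    tokens <- regmatches(formula, list(m))[[1]]
    if (sum(nchar(tokens)) != nchar(formula))
      stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
    el <- sub("[0-9]*$", "", tokens)
    n <- sub("^[A-Za-z]+", "", tokens)
    counts <- ifelse(n == "", 1L, suppressWarnings(as.integer(n)))
    names(counts) <- el
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  if (length(counts) == 0L || sum(counts) < 1L)
    stop("formula must contain at least one atom", call. = FALSE)
  unknown <- setdiff(names(counts), unique(ISOTOPES$element))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(counts < 0)) stop("negative element count", call. = FALSE)
  counts[counts > 0]
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the exact mass of that element's most
#' abundant isotope (e.g. 12C, 1H, 56Fe).
#'
#' @param formula Formula string or named count vector
#'   (see [parse_formula()]).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")            # 18.010565
#' monoisotopic_mass("C34H32FeN4O4")   # heme B, 616.17729
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(vapply(names(counts), function(el) {
    iso <- ISOTOPES[ISOTOPES$element == el, ]
    counts[[el]] * iso$mass[which.max(iso$abundance)]
  }, numeric(1)))
}

#' Ion specification
#'
#' Describes an ion hypothesis: a neutral-atom formula, the charge, and how
#' many protons were added (0 for even-electron or metal-centred cations
#' such as the intact ferric heme cation, 1 for `[M+H]+`, -1 for `[M-H]-`).
#' Electron bookkeeping is explicit: the ion mass is
#' `M + added_protons * m(H atom) - charge * m(electron)`.
#'
#' @param formula Formula string or named counts (atoms of the species as
#'   written, before proton addition).
#' @param charge Signed integer, non-zero.
#' @param added_protons Integer number of protons added (may be negative).
#' @param label Optional label carried into reports.
#' @return An `ion_spec` object.
#' @examples
#' ion_spec("C34H32FeN4O4", charge = 1, added_protons = 0)  # ferric heme [M]+
#' ion_spec("H2O", charge = 1, added_protons = 1)           # [M+H]+
#' @export
ion_spec <- function(formula, charge = 1L, added_protons = 0L, label = NULL) {
  counts <- parse_formula(formula)
  charge <- as.integer(charge)
  if (charge == 0L) stop("charge must be non-zero", call. = FALSE)
  structure(list(formula = counts, charge = charge,
                 added_protons = as.integer(added_protons),
                 label = label %||%
                   paste0(paste0(names(counts), counts, collapse = ""),
                          " z=", charge, " +", added_protons, "H")),
            class = "ion_spec")
}

#' Theoretical m/z of an ion
#'
#' Each added proton contributes the proton mass (1.00727647 Da); any
#' remaining charge is accounted for by electron removal or addition, so
#' `m/z = (M + added_protons x m(H+) - (charge - added_protons) x m(e)) /
#' |charge|`. For `[M+H]+` this is the conventional `M + 1.007276`; for an
#' intact even-electron cation such as ferric heme it is `M - m(e)` — the
#' 0.00055 Da electron matters at 4-decimal Orbitrap precision.
#'
#' @param ion An [ion_spec()].
#' @return m/z.
#' @examples
#' ion_mz(ion_spec("C34H32FeN4O4", 1, 0))  # 616.1767, ferric heme cation
#' @export
ion_mz <- function(ion) {
  stopifnot(inherits(ion, "ion_spec"))
  m <- monoisotopic_mass(ion$formula) + ion$added_protons * PROTON_MASS -
    (ion$charge - ion$added_protons) * ELECTRON_MASS
  m / abs(ion$charge)
}

#' Mass error in parts per million
#'
#' @param observed_mz,theoretical_mz m/z values; `theoretical_mz > 0`.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0))
    stop("theoretical_mz must be > 0", call. = FALSE)
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}

# Single-element isotope distribution aggregated at nominal-mass resolution:
# data.frame(nominal, prob, mz) with mz the abundance-weighted exact mass.
element_dist <- function(el) {
  iso <- ISOTOPES[ISOTOPES$element == el, ]
  data.frame(nominal = round(iso$mass), prob = iso$abundance,
             mz = iso$mass)
}

# Convolve two nominal-mass distributions. No pruning: aggregation at
# nominal resolution keeps the support small, and keeping every term makes
# the result independent of element order.
convolve_dist <- function(a, b, prune = 0) {
  nominal <- outer(a$nominal, b$nominal, `+`)
  prob <- outer(a$prob, b$prob)
  mz <- outer(a$mz, b$mz, `+`)
  key <- as.vector(nominal)
  p <- as.vector(prob)
  wm <- as.vector(mz) * p
  agg_p <- tapply(p, key, sum)
  agg_m <- tapply(wm, key, sum) / agg_p
  out <- data.frame(nominal = as.numeric(names(agg_p)),
                    prob = as.numeric(agg_p), mz = as.numeric(agg_m))
  out <- out[out$prob > prune, ]
  out[order(out$nominal), ]
}

#' Theoretical isotopologue envelope
#'
#' Predicts the isotope pattern of a formula by iterated convolution of the
#' embedded per-element isotope distributions, aggregated at nominal-mass
#' (1 Da) resolution — the resolution at which Orbitrap precursor envelopes
#' are compared visually. Iron-containing species show the diagnostic A-2
#' peak from 54Fe below the monoisotopic peak.
#'
#' @param formula Formula string or named counts.
#' @param max_peaks Keep at most this many of the most intense peaks.
#' @param normalize `"sum"` (intensities sum to 1) or `"base"` (base peak
#'   = 1).
#' @param charge,added_protons Optional ionization: peak positions are
#'   converted to m/z with the same bookkeeping as [ion_mz()].
#' @return An `isotope_pattern`: data.frame `(mz, intensity)` sorted by
#'   increasing m/z, with the normalization mode as attribute.
#' @examples
#' isotopologue_pattern("C34H32FeN4O4", max_peaks = 6)
#' @export
isotopologue_pattern <- function(formula, max_peaks = 8L,
                                 normalize = c("sum", "base"),
                                 charge = 0L, added_protons = 0L) {
  normalize <- match.arg(normalize)
  counts <- parse_formula(formula)
  if (max_peaks < 1L) stop("'max_peaks' must be >= 1", call. = FALSE)
  dist <- NULL
  for (el in names(counts)) {
    d <- element_dist(el)
    for (i in seq_len(counts[[el]]))
      dist <- if (is.null(dist)) d else convolve_dist(dist, d)
  }
  if (charge != 0L) {
    dist$mz <- (dist$mz + added_protons * H_ATOM_MASS -
                  charge * ELECTRON_MASS) / abs(charge)
  }
  dist <- dist[order(dist$prob, decreasing = TRUE), ][
    seq_len(min(max_peaks, nrow(dist))), ]
  dist <- dist[order(dist$mz), ]
  intensity <- if (normalize == "sum") dist$prob / sum(dist$prob)
               else dist$prob / max(dist$prob)
  structure(data.frame(mz = dist$mz, intensity = intensity),
            normalize = normalize, class = c("isotope_pattern", "data.frame"))
}

#' Match an observed precursor m/z against ion hypotheses
#'
#' Returns the candidate with the smallest absolute ppm error among those
#' within tolerance; exact ties go to the lower theoretical m/z. All
#' candidates are reported with their ppm errors so competing ion
#' hypotheses (e.g. `[M+H]+` versus an intact cation `[M]+`) can be
#' compared rather than silently decided.
#'
#' @param observed_mz Observed precursor m/z.
#' @param candidates List of [ion_spec()] objects.
#' @param tol_ppm Match tolerance in ppm (default 5).
#' @return A list with `matched` (index into `candidates`, or `NA` if none
#'   within tolerance), `best` (the matched `ion_spec` or `NULL`), and a
#'   `report` data.frame (label, theoretical_mz, ppm, within_tol).
#' @export
match_precursor <- function(observed_mz, candidates, tol_ppm = 5) {
  if (tol_ppm <= 0) stop("'tol_ppm' must be > 0", call. = FALSE)
  if (length(candidates) == 0L)
    return(list(matched = NA_integer_, best = NULL,
                report = data.frame(label = character(),
                                    theoretical_mz = numeric(),
                                    ppm = numeric(),
                                    within_tol = logical())))
  theo <- vapply(candidates, ion_mz, numeric(1))
  ppm <- ppm_error(observed_mz, theo)
  within <- abs(ppm) <= tol_ppm
  report <- data.frame(
    label = vapply(candidates, function(x) x$label, character(1)),
    theoretical_mz = theo, ppm = ppm, within_tol = within,
    stringsAsFactors = FALSE)
  if (!any(within))
    return(list(matched = NA_integer_, best = NULL, report = report))
  idx <- which(within)
  ord <- idx[order(abs(ppm[idx]), theo[idx])]
  list(matched = ord[1], best = candidates[[ord[1]]], report = report)
}
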