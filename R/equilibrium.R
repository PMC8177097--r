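#' Equilibrium complex concentration under ligand depletion
#'
#' Solves the 1:1 binding equilibrium P + L <-> PL for the complex
#' concentration when neither reactant is in large excess, using the
#' Morrison (tight-binding) quadratic. The complex concentration is the
#' smaller root of
#' \deqn{[PL]^2 - ([L]_0 + [P]_0 + K_d)[PL] + [L]_0 [P]_0 = 0,}
#' i.e. \eqn{([L]_0+[P]_0+K_d - \sqrt{([L]_0+[P]_0+K_d)^2 - 4 [L]_0 [P]_0})/2}.
#' The root is evaluated in the algebraically equivalent form
#' \eqn{2 [L]_0 [P]_0 / (s + \sqrt{s^2 - 4 [L]_0 [P]_0})} with
#' \eqn{s = [L]_0+[P]_0+K_d}, which avoids catastrophic cancellation when
#' \eqn{K_d \gg [L]_0, [P]_0}. The discriminant satisfies
#' \eqn{s^2 - 4LP \ge (L-P)^2 \ge 0}, so the root is always real.
#'
#' All three arguments must share one concentration unit; the result is in
#' that unit. `l_init` may be a vector (a titration schedule).
#'
#' @param l_init Initial (total) ligand concentration(s), >= 0.
#' @param p_init Initial (total) protein concentration, scalar >= 0.
#' @param kd Dissociation constant, scalar >= 0. `kd = 0` gives the
#'   stoichiometric limit `min(l_init, p_init)`.
#' @return An object of class `equilibrium_state`: a list with vectors
#'   `pl_eq`, `free_ligand`, `free_protein` and the inputs `l_init`,
#'   `p_init`, `kd`.
#' @examples
#' eq <- complex_concentration(l_init = 5, p_init = 5, kd = 1.4)
#' eq$pl_eq  # 2.963 uM if inputs are uM
#' @export
complex_concentration <- function(l_init, p_init, kd) {
  check_conc(l_init, "l_init")
  check_conc(p_init, "p_init")
  check_conc(kd, "kd")
  if (length(p_init) != 1L || length(kd) != 1L)
    stop("'p_init' and 'kd' must be scalars", call. = FALSE)
  s <- l_init + p_init + kd
  disc <- s^2 - 4 * l_init * p_init
  disc[disc < 0] <- 0  # guards rounding at the stoichiometric point
  denom <- s + sqrt(disc)
  pl <- ifelse(denom > 0, 2 * l_init * p_init / denom, 0)
  pl <- pmin(pl, pmin(l_init, p_init))  # clamp rounding excursions
  structure(
    list(pl_eq = pl,
         free_ligand = l_init - pl,
         free_protein = p_init - pl,
         l_init = l_init, p_init = p_init, kd = kd),
    class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("1:1 binding equilibrium (Kd =", format(x$kd), ")\n")
  print(data.frame(l_init = x$l_init, pl_eq = x$pl_eq,
                   free_ligand = x$free_ligand,
                   free_protein = x$free_protein))
  invisible(x)
}
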