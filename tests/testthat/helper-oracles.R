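# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Mass-action bisection: solve (p - x)(l - x) = kd * x for x in
# [0, min(l, p)] without the closed-form quadratic.
bisect_pl <- function(l, p, kd, iter = 200) {
  if (l == 0 || p == 0) return(0)
  f <- function(x) (p - x) * (l - x) - kd * x
  lo <- 0; hi <- min(l, p)
  if (f(hi) >= 0) return(hi)  # kd == 0 stoichiometric limit
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force isotopologue envelope by multinomial enumeration, aggregated
# at nominal-mass resolution. Supports the elements of heme B.
ISO_ORACLE <- list(
  C = data.frame(mass = c(12, 13.003354835), p = c(0.9893, 0.0107)),
  H = data.frame(mass = c(1.0078250319, 2.0141017779),
                 p = c(0.999885, 0.000115)),
  N = data.frame(mass = c(14.003074004, 15.000108899),
                 p = c(0.99636, 0.00364)),
  O = data.frame(mass = c(15.9949146196, 16.999131757, 17.999159613),
                 p = c(0.99757, 0.00038, 0.00205)),
  Fe = data.frame(mass = c(53.939608306, 55.934936326, 56.935392841,
                           57.933274431),
                  p = c(0.05845, 0.91754, 0.02119, 0.00282)))

# Enumerate isotope count vectors for n atoms of one element, keeping at
# most max_extra atoms off the principal isotope (prob beyond is negligible).
element_enum <- function(el, n, max_extra = 4) {
  iso <- ISO_ORACLE[[el]]
  main <- which.max(iso$p)
  others <- setdiff(seq_len(nrow(iso)), main)
  if (!length(others))
    return(data.frame(mass = n * iso$mass[main], p = iso$p[main]^n))
  # counts over the minor isotopes with total <= max_extra
  grid <- expand.grid(rep(list(0:max_extra), length(others)))
  grid <- grid[rowSums(grid) <= min(max_extra, n), , drop = FALSE]
  mass <- numeric(nrow(grid)); p <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    k <- as.numeric(grid[r, ]); k_main <- n - sum(k)
    p[r] <- exp(lfactorial(n) - sum(lfactorial(c(k_main, k)))) *
      iso$p[main]^k_main * prod(iso$p[others]^k)
    mass[r] <- k_main * iso$mass[main] + sum(k * iso$mass[others])
  }
  data.frame(mass = mass, p = p)
}

oracle_pattern <- function(counts, max_extra = 4) {
  dist <- data.frame(mass = 0, p = 1)
  for (el in names(counts)) {
    e <- element_enum(el, counts[[el]], max_extra)
    mass <- outer(dist$mass, e$mass, `+`)
    p <- outer(dist$p, e$p)
    dist <- data.frame(mass = as.vector(mass), p = as.vector(p))
    dist <- dist[dist$p > 1e-14, ]
  }
  key <- round(dist$mass)
  agg_p <- tapply(dist$p, key, sum)
  agg_m <- tapply(dist$p * dist$mass, key, sum) / agg_p
  out <- data.frame(nominal = as.numeric(names(agg_p)),
                    mz = as.numeric(agg_m), p = as.numeric(agg_p))
  out[order(out$nominal), ]
}

# Random rigid transform (rotation + translation), seeded by the caller.
random_rigid <- function() {
  A <- matrix(stats::rnorm(9), 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 5))
}
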