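make_ext_model <- function(law = c(0.05, -0.001), cmax = 12) {
  c_ <- seq(0.25, cmax, length.out = 20)
  a <- law[1] * c_ + if (length(law) > 1) law[2] * c_^2 else 0
  fit_extinction(c_, a, family = if (length(law) > 1) "polynomial"
                                 else "linear",
                 degree = length(law))
}

lin_ext <- function(slope = 0.05, cmax = 12)
  fit_extinction(seq(0.5, cmax, length.out = 10),
                 slope * seq(0.5, cmax, length.out = 10), family = "linear")

test_that("predicted absorbance matches oracle-assembled values", {
  m <- lin_ext(0.05)
  expect_equal(predict_absorbance(1.4, 0.08, m, 0, 5, quiet = TRUE), 0)
  expect_equal(predict_absorbance(0, 0.08, m, 3, 5, quiet = TRUE), 3 * 0.08)
  pl <- bisect_pl(5, 5, 1.4)
  expect_equal(predict_absorbance(1.4, 0.08, m, 5, 5, quiet = TRUE),
               pl * 0.08 + (5 - pl) * 0.05, tolerance = 1e-8)  # ~0.339
})

test_that("predicted fluorescence matches oracle-assembled values", {
  expect_equal(predict_fluorescence(1.4, 20, 100, 0, 10), 1000)
  expect_equal(predict_fluorescence(0, 20, 100, 50, 10), 200)  # saturated
  pl <- bisect_pl(10, 10, 0.14)
  expect_equal(predict_fluorescence(0.14, 20, 100, 10, 10),
               pl * 20 + (10 - pl) * 100, tolerance = 1e-6)
  expect_error(predict_fluorescence(1, -1, 100, 5, 10), ">= 0")
})

test_that("the two free-ligand evaluation conventions differ for curved laws", {
  m <- make_ext_model()
  a_free <- predict_absorbance(1.4, 0.08, m, 8, 5, "free", quiet = TRUE)
  a_init <- predict_absorbance(1.4, 0.08, m, 8, 5, "init", quiet = TRUE)
  expect_false(isTRUE(all.equal(a_free, a_init)))
  lin <- lin_ext()
  expect_equal(predict_absorbance(1.4, 0.08, lin, 8, 5, "free", quiet = TRUE),
               predict_absorbance(1.4, 0.08, lin, 8, 5, "init", quiet = TRUE),
               tolerance = 1e-12)  # conventions coincide for a linear law
})

test_that("noiseless absorbance fits recover the truth to 1e-6 relative", {
  m <- make_ext_model()
  for (kd in c(0.1, 0.7, 1.4, 3, 10)) {
    cfg <- synthetic_config(kd, 5, c(0.5, 1:11), noise_sd = 0,
                            n_replicates = 1)
    sim <- simulate_absorbance_titration(cfg)
    fit <- fit_kd_absorbance(sim$series, m)
    expect_true(fit$converged)
    expect_equal(fit$kd_hat, kd, tolerance = 1e-6)
    expect_equal(fit$complex_coefficient, 0.1, tolerance = 1e-5)
  }
})

test_that("noiseless fluorescence fits recover the truth to 1e-6 relative", {
  sched <- c(0, 1, 2, 4, 6, 8, 10, 15, 20, 30, 50)
  cfg <- synthetic_config(2, 10, sched, conc_unit = "nM", noise_sd = 0,
                          n_replicates = 1)
  sim <- simulate_fluorescence_titration(cfg)
  fit <- fit_kd_fluorescence(sim$series)
  expect_equal(fit$kd_hat, 2, tolerance = 1e-6)
  expect_equal(fit$complex_coefficient, 20, tolerance = 1e-5)
  expect_equal(fit$protein_coefficient, 100, tolerance = 1e-9)
})

test_that("fitting is invariant to the concentration unit", {
  m_um <- lin_ext(0.05, cmax = 12)
  cfg <- synthetic_config(1.4, 5, c(0.5, 1:11),
                          free_ligand_law = c(0.05), noise_sd = 0,
                          n_replicates = 1)
  sim <- simulate_absorbance_titration(cfg)
  fit_um <- fit_kd_absorbance(sim$series, m_um)
  # same data expressed in nM: concentrations x1000, coefficients /1000
  series_nm <- sim$series
  series_nm$protein_init <- 5000
  series_nm$data$ligand_conc <- series_nm$data$ligand_conc * 1000
  series_nm$conc_unit <- "nM"
  m_nm <- fit_extinction(seq(500, 12000, length.out = 10),
                         0.00005 * seq(500, 12000, length.out = 10),
                         family = "linear")
  fit_nm <- fit_kd_absorbance(series_nm, m_nm)
  expect_equal(fit_nm$kd_hat / 1000, fit_um$kd_hat, tolerance = 1e-5)
})

test_that("tight-binding identifiability warning fires when p/kd is large", {
  sched <- c(0, 1, 2, 4, 6, 8, 10, 15, 20, 30, 50)
  cfg <- synthetic_config(10 / 70, 10, sched, conc_unit = "nM",
                          noise_sd = 0, n_replicates = 1)
  sim <- simulate_fluorescence_titration(cfg)
  expect_warning(fit <- fit_kd_fluorescence(sim$series), "tight-binding")
  expect_true(length(fit$warnings) > 0)
  # comfortable regime: no warning
  cfg2 <- synthetic_config(5, 10, sched, conc_unit = "nM", noise_sd = 0,
                           n_replicates = 1)
  expect_silent(fit_kd_fluorescence(simulate_fluorescence_titration(cfg2)$series))
})

test_that("degenerate inputs are rejected with explicit errors", {
  m <- lin_ext()
  cfg <- synthetic_config(1.4, 5, c(1, 5), noise_sd = 0, n_replicates = 1)
  sim <- simulate_absorbance_titration(cfg)
  expect_error(fit_kd_absorbance(sim$series, m), "3 distinct")
  zero <- sim$series
  zero$data <- data.frame(replicate = 1, ligand_conc = c(1, 2, 3),
                          conc_unit = "uM", observable = c(0, 0, 0),
                          observable_kind = "A411")
  expect_error(fit_kd_absorbance(zero, m), "all-zero")
  # fluorescence without a zero-ligand point and without i_protein
  cfgf <- synthetic_config(1, 10, c(1, 2, 5, 10), conc_unit = "nM",
                           noise_sd = 0, n_replicates = 1)
  simf <- simulate_fluorescence_titration(cfgf)
  expect_error(fit_kd_fluorescence(simf$series), "zero-ligand")
  expect_silent(fit_kd_fluorescence(simf$series, i_protein = 100))
})

test_that("replicate SD is zero on zero-noise triplicates and bootstrap is seeded", {
  m <- make_ext_model()
  cfg <- synthetic_config(1.4, 5, c(0.5, 1:11), noise_sd = 0,
                          n_replicates = 3)
  sim <- simulate_absorbance_titration(cfg)
  fit <- fit_kd_absorbance(sim$series, m)
  u <- estimate_uncertainty(fit, sim$series, method = "replicate_sd")
  expect_equal(u$kd_sd, 0, tolerance = 1e-8)
  # single replicate: replicate_sd must direct the user to the bootstrap
  cfg1 <- synthetic_config(1.4, 5, c(0.5, 1:11), noise_sd = 0.003,
                           n_replicates = 1)
  sim1 <- simulate_absorbance_titration(cfg1)
  fit1 <- fit_kd_absorbance(sim1$series, m)
  expect_error(estimate_uncertainty(fit1, sim1$series, "replicate_sd"),
               "bootstrap")
  b1 <- estimate_uncertainty(fit1, sim1$series, "residual_bootstrap",
                             B = 25, seed = 11)
  b2 <- estimate_uncertainty(fit1, sim1$series, "residual_bootstrap",
                             B = 25, seed = 11)
  expect_identical(b1$kd_sd, b2$kd_sd)
  expect_gt(b1$kd_sd, 0)
})

test_that("bootstrap SD agrees with the asymptotic least-squares SE", {
  # independent oracle: numeric Jacobian of the model at the solution,
  # SE(kd) = sqrt(sigma^2 [(J'J)^-1]_kd)
  m <- make_ext_model()
  cfg <- synthetic_config(1.4, 5, c(0.5, 1:11), noise_sd = 0.003,
                          n_replicates = 3, seed = 5)
  sim <- simulate_absorbance_titration(cfg)
  fit <- fit_kd_absorbance(sim$series, m)
  l <- sim$series$data$ligand_conc
  pred <- function(th) predict_absorbance(th[1], th[2], m, l, 5,
                                          quiet = TRUE)
  th <- c(fit$kd_hat, fit$complex_coefficient)
  J <- sapply(1:2, function(j) {
    h <- 1e-6 * max(abs(th[j]), 1e-8)
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (pred(tp) - pred(tm)) / (2 * h)
  })
  sigma2 <- fit$rss / (fit$n_points - 2)
  se_kd <- sqrt(sigma2 * solve(t(J) %*% J)[1, 1])
  u <- estimate_uncertainty(fit, sim$series, "residual_bootstrap",
                            B = 400, seed = 3)
  expect_equal(u$kd_sd, se_kd, tolerance = 0.25)
})

test_that("differential spectra subtract pointwise and refuse grid mismatch", {
  w <- seq(300, 500, by = 2)
  a <- spectrum(w, exp(-(w - 412)^2 / 200))
  b <- spectrum(w, exp(-(w - 385)^2 / 300))
  expect_equal(differential_spectrum(a, a)$values, rep(0, length(w)))
  ab <- spectrum(w, a$values + b$values)
  expect_equal(differential_spectrum(ab, b)$values, a$values)  # (a+b)-b = a
  d <- differential_spectrum(a, b)
  expect_gt(d$values[which(w == 412)], 0)
  expect_lt(d$values[which(w == 384)], 0)
  expect_error(differential_spectrum(a, spectrum(w + 1, b$values)),
               "grids differ")
})

test_that("Soret peak location is interpolated and monotone windows refused", {
  w <- seq(350, 450, by = 1)
  s <- spectrum(w, 0.8 * exp(-(w - 412)^2 / 60))
  pk <- find_soret_peak(s, c(400, 430))
  expect_true(pk$found)
  expect_equal(pk$wavelength, 412, tolerance = 0.5)
  two <- spectrum(w, 1.0 * exp(-(w - 385)^2 / 80) +
                       0.4 * exp(-(w - 412)^2 / 60))
  pk2 <- find_soret_peak(two, c(400, 430))
  expect_equal(pk2$wavelength, 412, tolerance = 1)
  ramp <- find_soret_peak(spectrum(w, w / 100), c(400, 430))
  expect_false(ramp$found)
  expect_error(find_soret_peak(s, c(300, 430)), "window")
})
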