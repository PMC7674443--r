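test_that("missing hetNOE values are interpolated from nearest measured flanks", {
  full <- data.frame(residue = 1:3, noe = c(0.8, 0.7, 0.6))
  expect_equal(interpolate_missing_noe(full)$noe, full$noe)
  expect_equal(interpolate_missing_noe(full)$provenance, rep("measured", 3))

  one <- data.frame(residue = 1:3, noe = c(0.8, NA, 0.6))
  out <- interpolate_missing_noe(one)
  expect_equal(out$noe[2], 0.7)
  expect_equal(out$provenance[2], "interpolated")

  two <- data.frame(residue = 1:4, noe = c(0.8, NA, NA, 0.6))
  out2 <- interpolate_missing_noe(two)
  expect_equal(out2$noe[2:3], c(0.7, 0.7))   # both take the flank mean

  # leading/trailing gaps stay missing
  edge <- data.frame(residue = 1:4, noe = c(NA, 0.8, 0.6, NA))
  out3 <- interpolate_missing_noe(edge)
  expect_true(is.na(out3$noe[1]) && is.na(out3$noe[4]))
  expect_error(interpolate_missing_noe(data.frame(residue = c(1, 3), noe = c(1, 1))),
               "consecutive")
})

test_that("flexibility threshold is strict and unlabeled residues stay unlabeled", {
  prof <- classify_flexible(data.frame(residue = 1:4,
                                       noe = c(0.8, -0.2, 0.5, NA)))
  expect_equal(prof$label, c("rigid", "flexible", "rigid", NA))
})

test_that("H/D protection classes enforce exchange monotonicity", {
  rec <- data.frame(residue = 1:3,
                    retained_20min = c(FALSE, TRUE, TRUE),
                    retained_18h = c(FALSE, FALSE, TRUE))
  out <- classify_hdx(rec)
  expect_equal(out$class, c("fast", "protected_20min", "protected_18h"))
  bad <- data.frame(residue = 7, retained_20min = FALSE, retained_18h = TRUE)
  expect_error(classify_hdx(bad), "residue 7")
})

test_that("R2eff inverts constant-time intensity ratios", {
  s <- data.frame(residue = 1, nu_cpmg_hz = c(50, 100, 200),
                  intensity = c(1000, exp(-1) * 1000, 500),
                  intensity_ref = 1000)
  r2 <- r2eff_from_intensities(s, t_relax = 0.040)
  expect_equal(r2$r2eff[1], 0)
  expect_equal(r2$r2eff[2], 25.0)
  expect_equal(r2$r2eff[3], log(2) / 0.040, tolerance = 1e-9)

  s$intensity[2] <- -1
  expect_error(r2eff_from_intensities(s), "nu_cpmg = 100")
})

test_that("delta-R2 screening uses a strict 2 1/s cutoff", {
  flat <- data.frame(residue = 1, nu_cpmg_hz = c(50, 100, 1000),
                     r2eff = c(15, 15, 15))
  out <- delta_r2(flat)
  expect_equal(out$delta_r2, 0)
  expect_false(out$flagged)

  # forward model with strong exchange is flagged
  nu <- c(50, 100, 150, 200, 250, 300, 400, 500, 600, 800, 1000)
  curve <- data.frame(residue = 2, nu_cpmg_hz = nu,
                      r2eff = luz_meiboom(nu, 15, 1e4, 2500))
  out2 <- delta_r2(curve)
  expect_gt(out2$delta_r2, 2)
  expect_true(out2$flagged)

  # boundary: exactly 2.0 is not flagged
  edge <- data.frame(residue = 3, nu_cpmg_hz = c(50, 1000), r2eff = c(12, 10))
  expect_false(delta_r2(edge)$flagged)
  expect_true(delta_r2(data.frame(residue = 3, nu_cpmg_hz = c(50, 1000),
                                  r2eff = c(12.0001, 10)))$flagged)

  # residues missing an endpoint are skipped with a warning
  expect_warning(out3 <- delta_r2(rbind(flat, data.frame(
    residue = 9, nu_cpmg_hz = c(100, 200, 400), r2eff = c(1, 1, 1)))),
    "residue 9")
  expect_equal(out3$residue, 1)
})

test_that("the fast-exchange curve has the correct analytic limits and shape", {
  r2_0 <- 14; phi <- 2e4; kex <- 2500
  expect_equal(luz_meiboom(1e5, r2_0, phi, kex), r2_0, tolerance = 1e-3)
  expect_equal(luz_meiboom(1e-3, r2_0, phi, kex), r2_0 + phi / kex,
               tolerance = 1e-3)
  nu <- 10^seq(0, 4, length.out = 200)
  expect_true(all(diff(luz_meiboom(nu, r2_0, phi, kex)) <= 1e-12))
  # zero amplitude -> exactly flat
  expect_equal(luz_meiboom(c(50, 1000), r2_0, 0, kex), c(r2_0, r2_0))
})

test_that("the general two-state curve reduces to fast exchange when kex >> dw", {
  nu <- c(50, 100, 200, 400, 800, 1600)
  kex <- 5e4; pa <- 0.95; dw <- 300; r2_0 <- 12
  phi <- pa * (1 - pa) * dw^2
  cr <- carver_richards(nu, r2_0, kex, pa, dw)
  lm <- luz_meiboom(nu, r2_0, phi, kex)
  expect_lt(max(abs(cr - lm)), 0.02 * max(lm - r2_0))
})

test_that("a shared exchange rate is recovered from noiseless dispersion data", {
  res <- data.frame(residue = 1:5, r2_0 = c(12, 14, 16, 18, 20),
                    phi_ex = c(5e3, 1e4, 2e4, 3.5e4, 5e4))
  d <- make_dispersion_dataset(dispersion_spec(residues = res, kex = 2500))
  r2 <- r2eff_from_intensities(d, attr(d, "t_relax"))
  fit <- fit_two_state(r2, n_boot = 0)
  expect_true(fit$identifiable)
  expect_lt(abs(fit$kex - 2500) / 2500, 0.01)
  expect_equal(fit$per_residue$r2_0, res$r2_0, tolerance = 1e-3)
  expect_equal(fit$per_residue$phi_ex, res$phi_ex, tolerance = 1e-2)
})

test_that("the exchange rate is recovered within 20 percent under 2 percent noise", {
  errs <- vapply(1:10, function(s) {
    d <- make_dispersion_dataset(dispersion_spec(noise = 0.02, seed = 400 + s))
    r2 <- r2eff_from_intensities(d, attr(d, "t_relax"))
    abs(fit_two_state(r2, n_boot = 0)$kex - 2500) / 2500
  }, 0)
  expect_lt(median(errs), 0.20)
})

test_that("zero-amplitude data leave the exchange rate unidentifiable, not wrong", {
  res <- data.frame(residue = 1:3, r2_0 = c(12, 15, 18), phi_ex = c(0, 0, 0))
  d <- make_dispersion_dataset(dispersion_spec(residues = res))
  r2 <- r2eff_from_intensities(d, attr(d, "t_relax"))
  fit <- fit_two_state(r2, n_boot = 0)
  expect_false(fit$identifiable)
  expect_true(is.na(fit$kex))
  expect_equal(fit$per_residue$r2_0, res$r2_0, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  few <- data.frame(residue = 1, nu_cpmg_hz = c(50, 100, 200), r2eff = 1:3)
  expect_error(fit_two_state(few), "fewer than 4")
})

test_that("bootstrap uncertainty covers the true rate at the nominal 1.4-sigma width", {
  cover <- vapply(1:25, function(s) {
    d <- make_dispersion_dataset(dispersion_spec(noise = 0.02, seed = 100 + s))
    r2 <- r2eff_from_intensities(d, attr(d, "t_relax"))
    f <- fit_two_state(r2, n_boot = 200, seed = s)
    abs(f$kex - 2500) <= 1.4 * f$kex_sd
  }, TRUE)
  expect_gte(mean(cover), 0.8)
})

test_that("the general model fits per-residue parameters from its own forward curve", {
  nu <- c(50, 100, 150, 200, 250, 300, 400, 500, 600, 800, 1000)
  truth <- carver_richards(nu, 12, 2500, 0.97, 400)
  d <- data.frame(residue = 1, nu_cpmg_hz = nu, r2eff = truth)
  fit <- fit_two_state(d, model = "general")
  expect_true(all(fit$per_residue$converged))
  pred <- carver_richards(nu, fit$per_residue$r2_0, fit$per_residue$kex,
                          fit$per_residue$pa, fit$per_residue$dw)
  expect_lt(max(abs(pred - truth)), 0.05)
})
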