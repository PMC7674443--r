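# Backbone-flexibility classification (hetNOE, H/D exchange) and CPMG
# relaxation-dispersion analysis with a two-state exchange model.
#
# The default dispersion model is the fast-exchange (Luz-Meiboom) closed
# form; the general equal-R2 two-state (Carver-Richards) expression is
# available behind `model = "general"`.

#' Interpolate missing hetNOE values from flanking residues
#'
#' Each missing interior value is replaced by the mean of the nearest
#' measured values on either side (so a run of consecutive gaps all receive
#' the same mean). Leading and trailing gaps are left missing. Provenance is
#' recorded per residue as `"measured"` or `"interpolated"`.
#'
#' @param profile data.frame with columns `residue` (consecutive integers)
#'   and `noe` (`NA` where unmeasured).
#' @return the profile with gaps filled and a `provenance` column.
#' @export
interpolate_missing_noe <- function(profile) {
  stopifnot(all(c("residue", "noe") %in% names(profile)))
  profile <- profile[order(profile$residue), ]
  if (any(diff(profile$residue) != 1L)) {
    stop("profile must be indexed by consecutive residues")
  }
  noe <- profile$noe
  prov <- ifelse(is.na(noe), NA_character_, "measured")
  meas <- which(!is.na(noe))
  if (length(meas) >= 2L) {
    for (i in which(is.na(noe))) {
      lo <- meas[meas < i]; hi <- meas[meas > i]
      if (length(lo) && length(hi)) {
        noe[i] <- (noe[max(lo)] + noe[min(hi)]) / 2
        prov[i] <- "interpolated"
      }
    }
  }
  profile$noe <- noe
  profile$provenance <- prov
  profile
}

#' Classify residues as rigid or flexible from hetNOE
#'
#' Flexible iff `noe < threshold` (strict); residues still missing after
#' interpolation are unlabeled (`NA`).
#'
#' @param profile data.frame with `residue` and `noe`.
#' @param threshold hetNOE cutoff (default 0.5).
#' @return the profile with a `label` column (`"rigid"` / `"flexible"`).
#' @export
classify_flexible <- function(profile, threshold = 0.5) {
  profile$label <- ifelse(is.na(profile$noe), NA_character_,
                          ifelse(profile$noe < threshold, "flexible", "rigid"))
  profile
}

#' Three-way H/D-exchange protection classes
#'
#' `fast` (signal lost within 20 min), `protected_20min` (retained at 20 min
#' but not 18 h), `protected_18h` (retained at both times). Retention at 18 h
#' without retention at 20 min violates the monotonicity of exchange and is
#' an error.
#'
#' @param records data.frame with `residue`, `retained_20min`,
#'   `retained_18h` (logicals).
#' @return the records with a `class` column.
#' @export
classify_hdx <- function(records) {
  stopifnot(all(c("residue", "retained_20min", "retained_18h") %in% names(records)))
  bad <- records$retained_18h & !records$retained_20min
  if (any(bad)) {
    stop("residue ", records$residue[which(bad)[1]],
         ": retained at 18 h but not at 20 min")
  }
  records$class <- ifelse(!records$retained_20min, "fast",
                          ifelse(!records$retained_18h, "protected_20min",
                                 "protected_18h"))
  records
}

#' Effective transverse relaxation rates from CPMG peak intensities
#'
#' Constant-time relation `R2eff(nu) = -(1/T_relax) * log(I(nu) / I0)`.
#' The default relaxation delay is 0.040 s (two 20 ms CPMG blocks).
#'
#' @param series data.frame with `residue`, `nu_cpmg_hz`, `intensity`,
#'   `intensity_ref`.
#' @param t_relax total constant-time relaxation delay in seconds.
#' @return data.frame `residue`, `nu_cpmg_hz`, `r2eff` (1/s).
#' @export
r2eff_from_intensities <- function(series, t_relax = 0.040) {
  stopifnot(t_relax > 0,
            all(c("residue", "nu_cpmg_hz", "intensity", "intensity_ref") %in% names(series)))
  bad <- series$intensity <= 0 | series$intensity_ref <= 0
  if (any(bad)) {
    b <- which(bad)[1]
    stop("non-positive intensity at nu_cpmg = ", series$nu_cpmg_hz[b],
         " Hz (residue ", series$residue[b], ")")
  }
  data.frame(residue = series$residue,
             nu_cpmg_hz = series$nu_cpmg_hz,
             r2eff = -log(series$intensity / series$intensity_ref) / t_relax)
}

#' Exchange screening statistic: R2eff(low) - R2eff(high)
#'
#' The per-residue difference of effective relaxation rates at the slowest
#' and fastest pulsing rates; residues with a difference strictly greater
#' than `threshold` are flagged as exchange-broadened. Residues missing
#' either rate are skipped with a warning.
#'
#' @param r2eff data.frame from [r2eff_from_intensities()].
#' @param low,high pulsing rates in Hz (defaults 50 and 1000).
#' @param threshold flagging cutoff in 1/s (default 2, strict `>`).
#' @return data.frame `residue`, `delta_r2`, `flagged`.
#' @export
delta_r2 <- function(r2eff, low = 50, high = 1000, threshold = 2) {
  res <- sort(unique(r2eff$residue))
  rows <- lapply(res, function(r) {
    d <- r2eff[r2eff$residue == r, ]
    i_lo <- which(abs(d$nu_cpmg_hz - low) < 1e-6)
    i_hi <- which(abs(d$nu_cpmg_hz - high) < 1e-6)
    if (!length(i_lo) || !length(i_hi)) {
      warning("residue ", r, ": missing ", low, " Hz or ", high,
              " Hz point; skipped")
      return(NULL)
    }
    data.frame(residue = r, delta_r2 = d$r2eff[i_lo[1]] - d$r2eff[i_hi[1]])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(residue = integer(0), delta_r2 = numeric(0),
                                      flagged = logical(0)))
  out$flagged <- out$delta_r2 > threshold
  out
}

#' Fast-exchange (Luz-Meiboom) dispersion curve
#'
#' `R2eff(nu) = R2_0 + (phi_ex / kex) * (1 - (4 nu / kex) * tanh(kex / (4 nu)))`,
#' valid when the exchange rate far exceeds the chemical-shift difference.
#' Limits: `R2_0 + phi_ex/kex` as `nu -> 0`, `R2_0` as `nu -> Inf`.
#'
#' @param nu CPMG pulsing rate(s), Hz.
#' @param r2_0 exchange-free rate, 1/s.
#' @param phi_ex amplitude factor `pA*pB*dw^2`, 1/s^2.
#' @param kex exchange rate, 1/s.
#' @return R2eff in 1/s.
#' @export
luz_meiboom <- function(nu, r2_0, phi_ex, kex) {
  x <- kex / (4 * nu)
  r2_0 + (phi_ex / kex) * (1 - tanh(x) / x)
}

#' General equal-R2 two-state (Carver-Richards) dispersion curve
#'
#' Full closed form for two-site exchange with equal intrinsic rates,
#' parameterized by the major-state population `pa`, shift difference `dw`
#' (rad/s) and exchange rate `kex` (1/s). Reduces to [luz_meiboom()] with
#' `phi_ex = pa*(1-pa)*dw^2` when `kex >> dw`.
#'
#' @param nu CPMG pulsing rate(s), Hz.
#' @param r2_0 exchange-free rate, 1/s.
#' @param kex exchange rate, 1/s.
#' @param pa major-state population (0.5 < pa < 1).
#' @param dw chemical-shift difference, rad/s.
#' @return R2eff in 1/s.
#' @export
carver_richards <- function(nu, r2_0, kex, pa, dw) {
  pb <- 1 - pa
  tau_cp <- 1 / (2 * nu)                 # delay between successive pi pulses
  psi <- kex^2 - dw^2
  zeta <- -2 * dw * kex * (pa - pb)
  root <- sqrt(psi^2 + zeta^2)
  d_plus  <- 0.5 * ( 1 + (psi + 2 * dw^2) / root)
  d_minus <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  eta_plus  <- tau_cp / sqrt(2) * sqrt( psi + root)
  eta_minus <- tau_cp / sqrt(2) * sqrt(-psi + root)
  arg <- d_plus * cosh(eta_plus) - d_minus * cos(eta_minus)
  r2_0 + 0.5 * (kex - acosh(pmax(arg, 1)) / tau_cp)
}

# Luz-Meiboom dispersion shape g(nu; kex) such that
# R2eff = r2_0 + phi_ex * g; linear in (r2_0, phi_ex) at fixed kex.
lm_shape <- function(nu, kex) {
  x <- kex / (4 * nu)
  (1 - tanh(x) / x) / kex
}

# Profile out (r2_0, phi_ex >= 0) per residue at fixed kex; returns SSR and
# coefficients.
lm_profile_fit <- function(split_data, kex) {
  fits <- lapply(split_data, function(d) {
    g <- lm_shape(d$nu_cpmg_hz, kex)
    X <- cbind(1, g)
    co <- stats::lm.fit(X, d$r2eff)$coefficients
    if (is.na(co[2]) || co[2] < 0) {       # enforce phi_ex >= 0
      co <- c(mean(d$r2eff), 0)
    }
    resid <- d$r2eff - (co[1] + co[2] * g)
    list(r2_0 = unname(co[1]), phi_ex = unname(co[2]), ssr = sum(resid^2))
  })
  list(ssr = sum(vapply(fits, `[[`, 0, "ssr")), fits = fits)
}

fit_global_kex <- function(split_data, kex_range) {
  obj <- function(log_kex) lm_profile_fit(split_data, exp(log_kex))$ssr
  # coarse grid to detect flat (unidentifiable) objectives and bracket the optimum
  grid <- seq(log(kex_range[1]), log(kex_range[2]), length.out = 41L)
  vals <- vapply(grid, obj, 0)
  flat <- (max(vals) - min(vals)) <= 1e-10 * max(max(vals), 1e-12)
  if (flat) return(list(kex = NA_real_, identifiable = FALSE, ssr = min(vals)))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  op <- stats::optimize(obj, interval = c(lo, hi), tol = 1e-8)
  list(kex = exp(op$minimum), identifiable = TRUE, ssr = op$objective)
}

#' Fit a two-state exchange model to CPMG dispersion series
#'
#' Default: fast-exchange (Luz-Meiboom) model with a single exchange rate
#' `kex` shared by all residues and per-residue `R2_0` and `phi_ex`
#' (`phi_ex >= 0`). At fixed `kex` the model is linear in the per-residue
#' parameters, which are profiled out exactly; `kex` is then found by 1-D
#' minimization on a log scale. The `kex` uncertainty is estimated by
#' bootstrap over residues. With `global_kex = FALSE` each residue is fitted
#' with its own rate. `model = "general"` fits the Carver-Richards form
#' per residue via Levenberg-Marquardt.
#'
#' A dataset with no dispersion (`phi_ex ~ 0` everywhere) leaves `kex`
#' undetermined; the fit is then returned with `identifiable = FALSE` rather
#' than failing.
#'
#' @param r2eff data.frame `residue`, `nu_cpmg_hz`, `r2eff` (see
#'   [r2eff_from_intensities()]); at least 4 distinct rates per residue.
#' @param model `"fast"` (Luz-Meiboom, default) or `"general"`
#'   (Carver-Richards, per residue).
#' @param global_kex share one `kex` across residues (default `TRUE`).
#' @param kex_range search interval for `kex`, 1/s.
#' @param n_boot bootstrap resamples over residues for the `kex` uncertainty
#'   (global fit only; default 200, minimum recommended).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `dispersion_fit`: `kex`, `kex_sd`, `per_residue`
#'   data.frame, `model`, `identifiable`, `ssr`.
#' @export
fit_two_state <- function(r2eff, model = c("fast", "general"),
                          global_kex = TRUE, kex_range = c(10, 1e6),
                          n_boot = 200L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(all(c("residue", "nu_cpmg_hz", "r2eff") %in% names(r2eff)))
  split_data <- split(r2eff, r2eff$residue)
  if (!length(split_data)) stop("no residues to fit")
  npts <- vapply(split_data, function(d) length(unique(d$nu_cpmg_hz)), 1L)
  if (any(npts < 4L)) {
    stop("residue ", names(split_data)[which(npts < 4L)[1]],
         " has fewer than 4 distinct pulsing rates")
  }
  residues <- as.integer(names(split_data))

  if (model == "general") {
    per <- do.call(rbind, lapply(seq_along(split_data), function(i) {
      d <- split_data[[i]]
      if (length(unique(d$nu_cpmg_hz)) < 5L) {
        stop("residue ", residues[i], ": Carver-Richards needs >= 5 rates (4 parameters)")
      }
      start <- c(r2_0 = min(d$r2eff), log_kex = log(2000),
                 logit_pa = 2, log_dw = log(200))
      fn <- function(p) {
        pa <- 1 / (1 + exp(-p[3])) * 0.5 + 0.5   # constrain pa to (0.5, 1)
        d$r2eff - carver_richards(d$nu_cpmg_hz, p[1], exp(p[2]), pa, exp(p[4]))
      }
      fit <- minpack.lm::nls.lm(par = start, fn = fn,
                                control = minpack.lm::nls.lm.control(maxiter = 200))
      p <- fit$par
      data.frame(residue = residues[i], r2_0 = p[1], kex = exp(p[2]),
                 pa = 1 / (1 + exp(-p[3])) * 0.5 + 0.5, dw = exp(p[4]),
                 converged = fit$info %in% 1:4, ssr = fit$deviance)
    }))
    rownames(per) <- NULL
    return(structure(list(kex = NA_real_, kex_sd = NA_real_, per_residue = per,
                          model = "general", identifiable = TRUE,
                          ssr = sum(per$ssr)),
                     class = "dispersion_fit"))
  }

  if (!global_kex) {
    per <- do.call(rbind, lapply(seq_along(split_data), function(i) {
      f <- fit_global_kex(split_data[i], kex_range)
      co <- lm_profile_fit(split_data[i], if (is.na(f$kex)) 2500 else f$kex)$fits[[1]]
      data.frame(residue = residues[i], r2_0 = co$r2_0, phi_ex = co$phi_ex,
                 kex = f$kex, identifiable = f$identifiable)
    }))
    return(structure(list(kex = NA_real_, kex_sd = NA_real_, per_residue = per,
                          model = "fast", identifiable = all(per$identifiable),
                          ssr = NA_real_),
                     class = "dispersion_fit"))
  }

  main <- fit_global_kex(split_data, kex_range)
  co <- lm_profile_fit(split_data, if (is.na(main$kex)) mean(kex_range) else main$kex)
  per <- data.frame(residue = residues,
                    r2_0 = vapply(co$fits, `[[`, 0, "r2_0"),
                    phi_ex = vapply(co$fits, `[[`, 0, "phi_ex"))
  kex_sd <- NA_real_
  if (main$identifiable && length(split_data) >= 2L && n_boot > 0L) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample(length(split_data), replace = TRUE)
        fit_global_kex(split_data[idx], kex_range)$kex
      }, 0)
    })
    kex_sd <- stats::sd(boots, na.rm = TRUE)
  }
  structure(list(kex = main$kex, kex_sd = kex_sd, per_residue = per,
                 model = "fast", identifiable = main$identifiable,
                 ssr = main$ssr),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat("<dispersion_fit> model ", x$model, "\n", sep = "")
  if (x$model == "fast") {
    if (isTRUE(x$identifiable)) {
      cat("  global kex = ", format(x$kex, digits = 5), " 1/s",
          if (!is.na(x$kex_sd)) paste0(" (sd ", format(x$kex_sd, digits = 3), ")"),
          "\n", sep = "")
    } else cat("  kex unidentifiable (no measurable dispersion)\n")
  }
  print(utils::head(x$per_residue, 10))
  invisible(x)
}
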