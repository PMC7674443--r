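# Synthetic-data generators with planted ground truth for every pipeline
# stage. Realism is deliberately minimal: only the statistics the analyses
# consume (inter-atom distances, per-region scatter, SG geometry, dispersion
# curves, mass sums, radial exponentials) are controlled. Every generator is
# a pure function of its spec and seed.

#' Specification for a synthetic structure ensemble
#'
#' Defaults emulate the study conditions of a 19-model ensemble of a
#' 168-residue, five-disulfide luciferase: rigid core 10-18 / 36-81 / 96-145
#' (everything else disordered), bonds 52-127, 56-123, 59-120, 65-77,
#' 136-148 planted at satisfaction fractions 0.924, 0.561, 1, 1, 1 matching
#' the ensemble statistics reported for that system. `sigma_core` is the
#' per-axis Gaussian coordinate scatter of core atoms (0.57 Angstrom makes
#' the model-to-representative C-alpha RMSD come out near 1.4 Angstrom,
#' since two isotropically perturbed copies differ by ~ sigma * sqrt(6)).
#'
#' @param n_models number of models (default 19).
#' @param n_residues chain length (default 168).
#' @param rigid_ranges residue ranges perturbed with `sigma_core`.
#' @param sigma_core per-axis coordinate noise of rigid residues, Angstrom.
#' @param flexible_ranges ranges perturbed with `sigma_flex`; residues in
#'   neither list are treated as flexible (disordered termini behavior).
#' @param sigma_flex per-axis coordinate noise of flexible residues, Angstrom.
#' @param planted_bonds data.frame `res_i`, `res_j`, `fraction`: cysteine
#'   pairs whose SG atoms sit at bonding distance (1.9-2.3 Angstrom) in the
#'   stated fraction of models and >= 5 Angstrom apart otherwise.
#' @param satisfied_models optional list (one integer vector per bond) fixing
#'   exactly which models satisfy each bond; overrides `fraction`.
#' @param extra_cysteines residue numbers given a free (never planted) SG.
#' @param seed RNG seed.
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_models = 19L, n_residues = 168L,
                          rigid_ranges = list(c(10, 18), c(36, 81), c(96, 145)),
                          sigma_core = 0.57,
                          flexible_ranges = NULL, sigma_flex = 5,
                          planted_bonds = data.frame(
                            res_i = c(52L, 56L, 59L, 65L, 136L),
                            res_j = c(127L, 123L, 120L, 77L, 148L),
                            fraction = c(0.924, 0.561, 1, 1, 1)),
                          satisfied_models = NULL,
                          extra_cysteines = integer(0), seed = 1L) {
  spec <- list(n_models = as.integer(n_models), n_residues = as.integer(n_residues),
               rigid_ranges = rigid_ranges, sigma_core = sigma_core,
               flexible_ranges = flexible_ranges, sigma_flex = sigma_flex,
               planted_bonds = planted_bonds, satisfied_models = satisfied_models,
               extra_cysteines = as.integer(extra_cysteines), seed = as.integer(seed))
  stopifnot(spec$n_models >= 1L, spec$n_residues >= 2L,
            sigma_core >= 0, sigma_flex >= 0)
  all_res <- c(expand_ranges(rigid_ranges), expand_ranges(flexible_ranges))
  if (length(all_res) && (min(all_res) < 1L || max(all_res) > n_residues)) {
    stop("ranges outside 1..n_residues")
  }
  if (nrow(planted_bonds)) {
    stopifnot(all(planted_bonds$fraction >= 0), all(planted_bonds$fraction <= 1),
              all(c(planted_bonds$res_i, planted_bonds$res_j) >= 1),
              all(c(planted_bonds$res_i, planted_bonds$res_j) <= n_residues))
    if (anyDuplicated(c(planted_bonds$res_i, planted_bonds$res_j))) {
      stop("a cysteine appears in more than one planted bond")
    }
  }
  structure(spec, class = "ensemble_spec")
}

# Position-based relaxation of a C-alpha trace: consecutive residues at
# 3.8 A, planted-bond pairs at 5.5 A, bond midpoints kept >= 8 A apart,
# weak spherical confinement. Robust without step-size tuning.
relax_trace <- function(pos, bonds, n_iter = 400L, confine = NULL) {
  n <- nrow(pos)
  confine <- confine %||% (3.2 * n^(1/3))
  pr <- if (nrow(bonds) > 1L) utils::combn(nrow(bonds), 2L) else NULL
  for (it in seq_len(n_iter)) {
    # chain spacing (Jacobi-style half-corrections)
    v <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
    len <- sqrt(rowSums(v^2))
    corr <- v * ((len - 3.8) / pmax(len, 1e-9) * 0.25)
    pos[-n, ] <- pos[-n, ] + corr
    pos[-1, ] <- pos[-1, ] - corr
    if (nrow(bonds)) {
      i <- bonds[, 1]; j <- bonds[, 2]
      v <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
      len <- sqrt(rowSums(v^2))
      corr <- v * ((len - 5.5) / pmax(len, 1e-9) * 0.25)
      pos[i, ] <- pos[i, ] + corr
      pos[j, ] <- pos[j, ] - corr
      if (!is.null(pr)) {
        mid <- (pos[i, , drop = FALSE] + pos[j, , drop = FALSE]) / 2
        for (p in seq_len(ncol(pr))) {
          a <- pr[1, p]; b <- pr[2, p]
          d <- mid[b, ] - mid[a, ]
          dl <- vnorm(d)
          if (dl < 8) {
            push <- unitize(d) * (8 - dl) * 0.1
            pos[c(i[a], j[a]), ] <- sweep(pos[c(i[a], j[a]), , drop = FALSE], 2, push, `-`)
            pos[c(i[b], j[b]), ] <- sweep(pos[c(i[b], j[b]), , drop = FALSE], 2, push, `+`)
          }
        }
      }
    }
    r <- sqrt(rowSums(pos^2))
    out <- r > confine
    if (any(out)) pos[out, ] <- pos[out, ] * ((confine + 0.8 * (r[out] - confine)) / r[out])
  }
  pos
}

#' Generate a synthetic multi-model ensemble with planted ground truth
#'
#' Builds a smooth compact C-alpha trace (correlated random walk relaxed to
#' 3.8-Angstrom spacing, with planted-bond residues pulled to contact range
#' and confined to a globule), adds N and C backbone atoms and SG atoms on
#' the designated cysteines, then perturbs each model: rigid-range atoms with
#' per-axis Gaussian `sigma_core`, flexible residues with `sigma_flex`. For
#' each planted bond, the SG pair is placed at a distance drawn from
#' [1.9, 2.3] Angstrom in exactly `round(fraction * n_models)` models
#' (a seeded random subset unless `satisfied_models` fixes it) and at
#' >= 5 Angstrom otherwise. Deterministic given the spec's seed.
#'
#' @param spec an [ensemble_spec()].
#' @return an `ensemble` (see [new_ensemble()]).
#' @export
make_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$n_residues
  bonds <- as.matrix(spec$planted_bonds[, c("res_i", "res_j"), drop = FALSE])
  storage.mode(bonds) <- "integer"
  with_seed(spec$seed, {
    # correlated random-walk start, then constraint relaxation
    dirs <- matrix(0, n - 1L, 3L)
    d <- random_unit()
    for (k in seq_len(n - 1L)) {
      d <- unitize(0.8 * d + 0.6 * random_unit())
      dirs[k, ] <- d
    }
    base <- rbind(0, apply(dirs * 3.8, 2, cumsum))
    base <- relax_trace(base, bonds)
    if (nrow(bonds)) {
      dca <- sqrt(rowSums((base[bonds[, 1], , drop = FALSE] -
                             base[bonds[, 2], , drop = FALSE])^2))
      if (any(dca < 3) || any(dca > 9)) {
        stop("infeasible geometry: planted bond C-alpha distance ",
             format(max(dca), digits = 3), " A after relaxation")
      }
    }
    cys <- sort(unique(c(as.vector(bonds), spec$extra_cysteines)))
    aa <- rep("A", n)
    aa[cys] <- "C"
    # per-residue noise level: rigid ranges get sigma_core, everything else
    # (listed flexible ranges and unlisted residues alike) sigma_flex
    sigma <- rep(spec$sigma_flex, n)
    sigma[expand_ranges(spec$rigid_ranges)] <- spec$sigma_core
    sg_dir <- random_unit(length(cys))
    sat <- vector("list", nrow(bonds))
    if (nrow(bonds)) {
      for (b in seq_len(nrow(bonds))) {
        sat[[b]] <- if (!is.null(spec$satisfied_models)) {
          as.integer(spec$satisfied_models[[b]])
        } else {
          k <- round(spec$planted_bonds$fraction[b] * spec$n_models)
          if (k > 0L) sample(spec$n_models, k) else integer(0)
        }
      }
    }
    # backbone N toward the previous residue, C toward the next
    step <- base[-1, , drop = FALSE] - base[-n, , drop = FALSE]
    step <- step / sqrt(rowSums(step^2))
    prev_dir <- rbind(c(1, 0, 0), -step)
    next_dir <- rbind(step, c(1, 0, 0))
    models <- vector("list", spec$n_models)
    for (m in seq_len(spec$n_models)) {
      ca <- base + matrix(stats::rnorm(3L * n, 0, rep(sigma, 3L)), n, 3L)
      npos <- ca + 1.46 * prev_dir
      cpos <- ca + 1.52 * next_dir
      sg <- ca[cys, , drop = FALSE] + 2.4 * sg_dir
      rownames(sg) <- as.character(cys)
      if (nrow(bonds)) {
        for (b in seq_len(nrow(bonds))) {
          ri <- as.character(bonds[b, 1]); rj <- as.character(bonds[b, 2])
          if (m %in% sat[[b]]) {
            mid <- (ca[bonds[b, 1], ] + ca[bonds[b, 2], ]) / 2
            dd <- stats::runif(1, 1.9, 2.3)
            u <- as.numeric(random_unit())
            sg[ri, ] <- mid - u * dd / 2
            sg[rj, ] <- mid + u * dd / 2
          } else {
            u <- unitize(ca[bonds[b, 2], ] - ca[bonds[b, 1], ])
            sg[ri, ] <- ca[bonds[b, 1], ] - 2.4 * u
            sg[rj, ] <- ca[bonds[b, 2], ] + 2.4 * u
          }
        }
      }
      resno_bb <- rep(seq_len(n), each = 3L)
      df <- data.frame(
        resno = c(resno_bb, cys),
        atom = c(rep(c("N", "CA", "C"), n), rep("SG", length(cys))),
        element = c(rep(c("N", "C", "C"), n), rep("S", length(cys))),
        x = c(rbind(npos[, 1], ca[, 1], cpos[, 1]), sg[, 1]),
        y = c(rbind(npos[, 2], ca[, 2], cpos[, 2]), sg[, 2]),
        z = c(rbind(npos[, 3], ca[, 3], cpos[, 3]), sg[, 3]),
        stringsAsFactors = FALSE)
      df$aa <- aa[df$resno]
      df$resid <- unname(AA_1TO3[df$aa])
      ord <- order(df$resno, match(df$atom, c("N", "CA", "C", "SG")))
      df <- df[ord, c("resno", "resid", "aa", "atom", "element", "x", "y", "z")]
      rownames(df) <- NULL
      models[[m]] <- df
    }
    new_ensemble(models)
  })
}

#' Specification for a synthetic CPMG dispersion dataset
#'
#' Defaults emulate the study's relaxation-dispersion design: the 11 pulsing
#' rates 50-1000 Hz, a 40 ms constant-time block, a shared exchange rate of
#' 2500 1/s, and per-residue amplitudes `phi_ex` log-uniform in
#' 5e3-5e4 1/s^2.
#'
#' @param residues data.frame `residue`, `r2_0`, `phi_ex`; `NULL` draws
#'   `n_residues` of them from the default bands.
#' @param n_residues number of residues when `residues` is `NULL`.
#' @param kex shared exchange rate, 1/s.
#' @param rates CPMG pulsing rates, Hz.
#' @param noise multiplicative Gaussian intensity noise fraction.
#' @param t_relax constant-time relaxation delay, s.
#' @param seed RNG seed.
#' @return list of class `dispersion_spec`.
#' @export
dispersion_spec <- function(residues = NULL, n_residues = 5L, kex = 2500,
                            rates = c(50, 100, 150, 200, 250, 300, 400, 500,
                                      600, 800, 1000),
                            noise = 0, t_relax = 0.040, seed = 1L) {
  stopifnot(kex > 0, all(rates > 0), !anyDuplicated(rates), noise >= 0,
            t_relax > 0)
  structure(list(residues = residues, n_residues = as.integer(n_residues),
                 kex = kex, rates = rates, noise = noise, t_relax = t_relax,
                 seed = as.integer(seed)),
            class = "dispersion_spec")
}

#' Generate a synthetic CPMG intensity dataset
#'
#' Forward Luz-Meiboom model: `I(nu) = I0 * exp(-R2eff(nu) * t_relax)` with
#' multiplicative Gaussian noise. [r2eff_from_intensities()] inverts it
#' exactly at zero noise.
#'
#' @param spec a [dispersion_spec()].
#' @return data.frame `residue`, `nu_cpmg_hz`, `intensity`, `intensity_ref`
#'   with attributes `t_relax` and `truth` (the generating parameters).
#' @export
make_dispersion_dataset <- function(spec) {
  stopifnot(inherits(spec, "dispersion_spec"))
  with_seed(spec$seed, {
    res <- spec$residues
    if (is.null(res)) {
      res <- data.frame(residue = seq_len(spec$n_residues),
                        r2_0 = stats::runif(spec$n_residues, 12, 20),
                        phi_ex = 10^stats::runif(spec$n_residues,
                                                 log10(5e3), log10(5e4)))
    }
    i0 <- 1e5
    rows <- do.call(rbind, lapply(seq_len(nrow(res)), function(k) {
      r2 <- luz_meiboom(spec$rates, res$r2_0[k], res$phi_ex[k], spec$kex)
      data.frame(residue = res$residue[k], nu_cpmg_hz = spec$rates,
                 intensity = i0 * exp(-r2 * spec$t_relax),
                 intensity_ref = i0)
    }))
    if (spec$noise > 0) {
      rows$intensity <- rows$intensity *
        (1 + stats::rnorm(nrow(rows), 0, spec$noise))
      rows$intensity <- pmax(rows$intensity, 1e-6 * i0)
    }
    attr(rows, "t_relax") <- spec$t_relax
    attr(rows, "truth") <- list(kex = spec$kex, residues = res)
    rows
  })
}

#' Generate synthetic hetNOE and H/D-exchange tables
#'
#' Rigid residues draw hetNOE from 0.7-0.9, flexible residues (listed ranges
#' and any residue in neither list) from -0.3-0.4, mirroring the bands seen
#' in well-folded helical cores versus disordered termini. Amide protection
#' is assigned only within rigid ranges: each rigid residue is retained at
#' 20 min with probability `p_protected`, and of those a fraction go on to
#' survive 18 h (probability `p_18h`).
#'
#' @param rigid_ranges,flexible_ranges residue ranges (disjoint).
#' @param n_residues chain length (default: max residue in the ranges).
#' @param missing residues whose NOE is blanked (`NA`), to be interpolated.
#' @param p_protected,p_18h protection probabilities within rigid ranges.
#' @param seed RNG seed.
#' @return list with `noe` (data.frame `residue`, `noe`) and `hdx`
#'   (data.frame `residue`, `retained_20min`, `retained_18h`).
#' @export
make_hetnoe_and_hdx <- function(rigid_ranges, flexible_ranges = NULL,
                                n_residues = NULL, missing = integer(0),
                                p_protected = 0.6, p_18h = 0.4, seed = 1L) {
  rigid <- expand_ranges(rigid_ranges)
  flex <- expand_ranges(flexible_ranges)
  if (length(intersect(rigid, flex))) stop("rigid and flexible ranges overlap")
  n_residues <- n_residues %||% max(c(rigid, flex, 1L))
  with_seed(seed, {
    residue <- seq_len(n_residues)
    is_rigid <- residue %in% rigid
    noe <- ifelse(is_rigid, stats::runif(n_residues, 0.7, 0.9),
                  stats::runif(n_residues, -0.3, 0.4))
    noe[residue %in% missing] <- NA_real_
    ret20 <- is_rigid & stats::runif(n_residues) < p_protected
    ret18 <- ret20 & stats::runif(n_residues) < p_18h
    list(noe = data.frame(residue = residue, noe = noe),
         hdx = data.frame(residue = residue, retained_20min = ret20,
                          retained_18h = ret18))
  })
}

#' Generate synthetic sedimentation-equilibrium scans
#'
#' Wraps [simulate_scan()] over the full speed-by-concentration design
#' (defaults: 12,000 / 22,000 / 37,000 rpm at 1.2 / 0.6 / 0.3 mg/mL, nine
#' scans) with additive absorbance noise. The reference concentration of
#' each scan scales with its loading concentration.
#'
#' @param M molar mass, g/mol (default 22,000).
#' @param speeds rotor speeds, rpm.
#' @param conc loading concentrations, mg/mL.
#' @param radii radial grid, cm.
#' @param noise_sd additive absorbance noise SD, AU (default 0.005).
#' @param vbar,rho,temperature physical parameters (see [simulate_scan()]).
#' @param baseline per-scan additive offset, AU.
#' @param seed RNG seed.
#' @return list of `auc_scan` data.frames (length `length(speeds) * length(conc)`).
#' @export
make_auc_scans <- function(M = 22000, speeds = c(12000, 22000, 37000),
                           conc = c(1.2, 0.6, 0.3),
                           radii = seq(6.9, 7.2, length.out = 60),
                           noise_sd = 0.005, vbar = 0.73, rho = 1.006983,
                           temperature = 293.15, baseline = 0.02, seed = 1L) {
  with_seed(seed, {
    scans <- list()
    for (cc in conc) {
      for (sp in speeds) {
        s <- simulate_scan(M = M, vbar = vbar, rho = rho, rpm = sp,
                           radii = radii, c_ref = 0.35 * cc, baseline = baseline,
                           noise_sd = 0, temperature = temperature,
                           conc_label = cc)
        if (noise_sd > 0) {
          s$absorbance <- s$absorbance + stats::rnorm(nrow(s), 0, noise_sd)
        }
        scans[[length(scans) + 1L]] <- s
      }
    }
    scans
  })
}

#' Generate an observed-mass table for disulfide-linked fragment groups
#'
#' Computes the mass of each linked group (sum of member peptide masses
#' minus two hydrogens per disulfide, all cysteines paired) with optional
#' Gaussian mass error, as an LC-MS observation table.
#'
#' @param sequence protein one-letter string.
#' @param linked_groups list of groups; each group is a list of `c(start, end)`
#'   spans.
#' @param mass_error_sd Gaussian mass error SD, Da (default 0).
#' @param mass_type,label passed to [peptide_mass()].
#' @param seed RNG seed.
#' @param path optional TSV output path.
#' @return data.frame `observed_mass`, `spans` (and writes `path` if given).
#' @export
make_digest_sample <- function(sequence, linked_groups, mass_error_sd = 0,
                               mass_type = "average", label = "none",
                               seed = 1L, path = NULL) {
  rows <- lapply(linked_groups, function(group) {
    peps <- vapply(group, function(sp) substr(sequence, sp[1], sp[2]), "")
    n_cys <- sum(vapply(strsplit(peps, ""), function(a) sum(a == "C"), 1L))
    h2 <- 2 * (if (mass_type == "average") MASS_H_AVG else MASS_H_MONO)
    mass <- sum(vapply(peps, peptide_mass, 0, mass_type = mass_type,
                       label = label)) - (n_cys %/% 2L) * h2
    data.frame(observed_mass = mass,
               spans = paste(vapply(group, function(sp)
                 sprintf("%d-%d", sp[1], sp[2]), ""), collapse = "+"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(observed_mass = numeric(0), spans = character(0))
  }
  if (mass_error_sd > 0 && nrow(out)) {
    out$observed_mass <- out$observed_mass +
      with_seed(seed, stats::rnorm(nrow(out), 0, mass_error_sd))
  }
  if (!is.null(path)) write_tsv(out, path)
  out
}
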