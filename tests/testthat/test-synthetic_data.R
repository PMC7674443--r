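test_that("generators are pure functions of spec and seed", {
  a <- make_ensemble(ensemble_spec(seed = 33))
  b <- make_ensemble(ensemble_spec(seed = 33))
  expect_identical(a, b)
  c <- make_ensemble(ensemble_spec(seed = 34))
  expect_false(identical(a, c))

  d1 <- make_dispersion_dataset(dispersion_spec(noise = 0.02, seed = 5))
  d2 <- make_dispersion_dataset(dispersion_spec(noise = 0.02, seed = 5))
  expect_identical(d1, d2)

  s1 <- make_auc_scans(seed = 5)
  s2 <- make_auc_scans(seed = 5)
  expect_identical(s1, s2)

  # global RNG state is untouched
  set.seed(77); before <- .Random.seed
  invisible(make_ensemble(ensemble_spec(seed = 1)))
  expect_identical(before, .Random.seed)
})

test_that("zero noise and no flexible ranges give identical models", {
  spec <- ensemble_spec(n_models = 4L, n_residues = 25L,
                        rigid_ranges = list(c(1, 25)), sigma_core = 0,
                        planted_bonds = data.frame(res_i = integer(0),
                                                   res_j = integer(0),
                                                   fraction = numeric(0)),
                        extra_cysteines = c(5L, 20L), seed = 2)
  ens <- make_ensemble(spec)
  expect_identical(ens$models[[1]], ens$models[[4]])
  M <- pairwise_rmsd_matrix(ens, "CA", list(c(1, 25)))
  expect_equal(max(abs(M)), 0, tolerance = 1e-9)
})

test_that("bond satisfaction fractions are honored exactly by counting", {
  ens <- make_ensemble(ensemble_spec(
    n_models = 10L, n_residues = 50L, rigid_ranges = list(c(1, 50)),
    planted_bonds = data.frame(res_i = 12L, res_j = 38L, fraction = 0.7),
    seed = 12))
  st <- pair_frequency(sg_distance_table(ens))
  expect_equal(st$pairs$frequency, 0.7)
})

test_that("the paper-condition spec supports end-to-end pairing recovery", {
  ens <- make_ensemble(ensemble_spec(seed = 55))
  got <- assign_pairing(pair_frequency(sg_distance_table(ens)))$pairs
  expect_equal(got$res_i, c(52, 56, 59, 65, 136))
  expect_equal(got$res_j, c(127, 123, 120, 77, 148))
  expect_equal(length(ens$resno), 168L)
  expect_equal(nchar(ens$sequence), 168L)
})

test_that("ensemble specifications are validated up front", {
  expect_error(ensemble_spec(planted_bonds = data.frame(
    res_i = c(5L, 5L), res_j = c(20L, 30L), fraction = c(1, 1))),
    "more than one planted bond")
  expect_error(ensemble_spec(planted_bonds = data.frame(
    res_i = 5L, res_j = 20L, fraction = 1.2)))
  expect_error(ensemble_spec(n_residues = 50L,
                             rigid_ranges = list(c(10, 80))),
               "outside")
})

test_that("noise-free dispersion data invert exactly through R2eff", {
  res <- data.frame(residue = 1:2, r2_0 = c(12, 18), phi_ex = c(1e4, 3e4))
  d <- make_dispersion_dataset(dispersion_spec(residues = res, kex = 2500))
  r2 <- r2eff_from_intensities(d, attr(d, "t_relax"))
  nu <- unique(d$nu_cpmg_hz)
  expect_equal(r2$r2eff[r2$residue == 1], luz_meiboom(nu, 12, 1e4, 2500),
               tolerance = 1e-10)
  # strong exchange produces a flaggable dispersion
  dr <- delta_r2(r2eff_from_intensities(
    make_dispersion_dataset(dispersion_spec(
      residues = data.frame(residue = 1, r2_0 = 15, phi_ex = 2e4),
      kex = 2500)), 0.040))
  expect_true(dr$flagged)
  # zero amplitude -> flat intensities
  flat <- make_dispersion_dataset(dispersion_spec(
    residues = data.frame(residue = 1, r2_0 = 15, phi_ex = 0)))
  expect_equal(length(unique(round(flat$intensity, 9))), 1L)
})

test_that("hetNOE and protection tables follow the planted rigid/flexible layout", {
  rigid <- list(c(10, 18), c(36, 81), c(96, 145))
  out <- make_hetnoe_and_hdx(rigid, n_residues = 168, seed = 3)
  prof <- classify_flexible(interpolate_missing_noe(out$noe))
  rigid_set <- expand_ranges(rigid)
  expect_true(all(prof$label[prof$residue %in% rigid_set] == "rigid"))
  expect_true(all(prof$label[!prof$residue %in% rigid_set] == "flexible"))

  # a blanked residue inside a rigid run interpolates to >= 0.5
  out2 <- make_hetnoe_and_hdx(rigid, n_residues = 168, missing = 50L, seed = 4)
  prof2 <- interpolate_missing_noe(out2$noe)
  expect_gte(prof2$noe[prof2$residue == 50], 0.5)
  expect_equal(prof2$provenance[prof2$residue == 50], "interpolated")

  # protection only within rigid ranges, and 18 h implies 20 min
  hdx <- classify_hdx(out$hdx)
  expect_true(all(hdx$residue[hdx$class != "fast"] %in% rigid_set))
  expect_true(all(hdx$retained_20min[hdx$retained_18h]))
})

test_that("the AUC design produces nine scans with speed-ordered gradients", {
  scans <- make_auc_scans(M = 22000, noise_sd = 0)
  expect_length(scans, 9L)
  rise <- vapply(scans, function(s) max(s$absorbance) - min(s$absorbance), 0)
  rpm <- vapply(scans, function(s) s$rpm[1], 0)
  for (cc in unique(vapply(scans, function(s) attr(s, "params")$conc_label, 0))) {
    sel <- vapply(scans, function(s) attr(s, "params")$conc_label == cc, TRUE)
    expect_true(all(diff(rise[sel][order(rpm[sel])]) > 0))
  }
  fit <- global_fit(scans)
  expect_lt(abs(fit$M - 22000) / 22000, 1e-3)
})

test_that("digest samples reproduce the linked-fragment mass and survive mass error", {
  tab <- make_digest_sample(gluc_sequence(),
                            list(list(c(50, 54), c(55, 64), c(106, 129))))
  expect_equal(nrow(tab), 1L)
  expect_lt(abs(tab$observed_mass - 4259.01), 0.1)

  empty <- make_digest_sample(gluc_sequence(), list())
  expect_equal(nrow(empty), 0L)

  noisy <- make_digest_sample(gluc_sequence(),
                              list(list(c(50, 54), c(55, 64), c(106, 129))),
                              mass_error_sd = 0.05, seed = 9)
  sp <- enumerate_linked_species(digest(gluc_sequence()))
  hit <- match_mass(noisy$observed_mass, sp, tolerance = 0.5)
  expect_equal(hit$spans[1], "50-54+55-64+106-129")
})
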