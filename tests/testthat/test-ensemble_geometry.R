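test_that("superposition recovers identity and exact rigid motions", {
  set.seed(1)
  X <- matrix(rnorm(15), ncol = 3)
  sp <- kabsch_superpose(X, X)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)  # 90 deg about z
  Y <- sweep(X %*% t(Rz), 2, c(5, 0, 0), `+`)
  sp <- kabsch_superpose(X, Y)
  expect_lt(sp$rmsd, 1e-6)
  expect_equal(apply_superposition(X, sp), Y, tolerance = 1e-9)
})

test_that("superposition rejects degenerate input", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("rotations are proper, RMSD is symmetric and rigid-motion invariant", {
  set.seed(7)
  for (rep in 1:10) {
    A <- matrix(rnorm(30), ncol = 3)
    B <- matrix(rnorm(30), ncol = 3)
    sp <- kabsch_superpose(A, B)
    expect_lt(max(abs(crossprod(sp$rotation) - diag(3))), 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    expect_equal(sp$rmsd, kabsch_superpose(B, A)$rmsd, tolerance = 1e-9)
    Q <- random_rotation(); t <- rnorm(3)
    A_moved <- sweep(A %*% t(Q), 2, t, `+`)
    expect_equal(kabsch_superpose(A_moved, B)$rmsd, sp$rmsd, tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD agrees with a rotation-grid search on a 4-atom toy", {
  set.seed(11)
  A <- matrix(rnorm(12), ncol = 3)
  B <- A %*% t(random_rotation()) + matrix(rnorm(12, sd = 0.3), ncol = 3)
  exact <- kabsch_superpose(A, B)$rmsd
  gridded <- grid_min_rmsd(A, B, n_alpha = 60, n_beta = 60, n_gamma = 60)
  expect_gte(gridded, exact - 1e-9)   # grid cannot beat the analytic optimum
  expect_lt(gridded - exact, 0.02)
})

test_that("pairwise RMSD matrix is symmetric, zero-diagonal, rigid-motion aware", {
  base <- matrix(rnorm(30), ncol = 3)
  m1 <- toy_model(base)
  ens <- new_ensemble(list(m1, m1))
  M <- pairwise_rmsd_matrix(ens)
  expect_equal(unclass(M), matrix(0, 2, 2), ignore_attr = TRUE)

  Q <- random_rotation()
  m3 <- toy_model(sweep(base %*% t(Q), 2, c(3, -2, 1), `+`))
  m2 <- toy_model(base + rnorm(30, sd = 0.5))
  ens3 <- new_ensemble(list(m1, m2, m3))
  M3 <- pairwise_rmsd_matrix(ens3)
  expect_equal(unclass(M3), t(unclass(M3)), tolerance = 1e-9)
  expect_lt(M3[1, 3], 1e-9)          # model 3 is a rigid copy of model 1
  expect_gt(M3[1, 2], 0.1)
})

test_that("mean pairwise RMSD of an isotropically noisy core matches direct simulation", {
  n_res <- 40
  sigma <- 1.0
  ens <- make_ensemble(ensemble_spec(
    n_models = 19L, n_residues = n_res, rigid_ranges = list(c(1, n_res)),
    sigma_core = sigma, planted_bonds = data.frame(res_i = integer(0),
                                                   res_j = integer(0),
                                                   fraction = numeric(0)),
    seed = 3))
  M <- pairwise_rmsd_matrix(ens, "CA", list(c(1, n_res)))
  observed <- mean(M[upper.tri(M)])
  # independent oracle: direct simulation of the same noise model
  set.seed(99)
  sim <- replicate(200, {
    base <- matrix(rnorm(3 * n_res, sd = 5), ncol = 3)
    a <- base + rnorm(3 * n_res, sd = sigma)
    b <- base + rnorm(3 * n_res, sd = sigma)
    kabsch_superpose(a, b)$rmsd
  })
  expect_lt(abs(observed - mean(sim)) / mean(sim), 0.15)
})

test_that("representative selection equals exhaustive row-mean argmin", {
  expect_equal(select_representative(matrix(1, 4, 4) - diag(4)), 1L)  # tie -> lowest
  M <- rbind(c(0, 2, 2), c(2, 0, 0), c(2, 0, 0))
  M <- (M + t(M)) / 2
  M3 <- rbind(c(0, 2, 2), c(2, 0, 0), c(2, 0, 0))
  expect_equal(select_representative(M3), 2L)

  set.seed(13)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    A <- matrix(runif(n * n), n)
    A <- (A + t(A)) / 2; diag(A) <- 0
    exhaustive <- which.min(vapply(seq_len(n), function(i) mean(A[i, -i]), 0))
    expect_equal(select_representative(A), exhaustive)
  }
})

test_that("RMSD-to-representative statistics match a direct per-model recomputation", {
  ens <- make_ensemble(ensemble_spec(seed = 21))
  sel <- "10-18,36-81,96-145"
  M <- pairwise_rmsd_matrix(ens, "CA", sel)
  rep_i <- select_representative(M)
  stats <- rmsd_to_reference_stats(ens, rep_i, "CA", sel)
  # direct oracle: recompute each model's RMSD from coordinates
  co <- select_coords(ens, "CA", sel)
  direct <- vapply(setdiff(1:19, rep_i),
                   function(i) kabsch_superpose(co[[i]], co[[rep_i]])$rmsd, 0)
  expect_equal(stats$mean, mean(direct), tolerance = 1e-12)
  expect_equal(stats$sd, sd(direct), tolerance = 1e-12)
  expect_lt(abs(stats$mean - mean(direct)) / mean(direct), 0.15)
  # identical models give exactly 0 +/- 0
  m <- toy_model(matrix(rnorm(30), ncol = 3))
  ens0 <- new_ensemble(list(m, m, m))
  s0 <- rmsd_to_reference_stats(ens0, 1)
  expect_equal(s0$mean, 0, tolerance = 1e-10)
  expect_equal(s0$sd, 0, tolerance = 1e-10)
})

test_that("displacement profiles expose flexible termini and planted hotspots", {
  spec <- ensemble_spec(n_models = 10L, n_residues = 60L,
                        rigid_ranges = list(c(11, 50)), sigma_core = 0.5,
                        sigma_flex = 5,
                        planted_bonds = data.frame(res_i = integer(0),
                                                   res_j = integer(0),
                                                   fraction = numeric(0)),
                        seed = 8)
  ens <- make_ensemble(spec)
  M <- pairwise_rmsd_matrix(ens, "CA", list(c(11, 50)))
  prof <- per_residue_displacement(ens, select_representative(M), "CA",
                                   superpose_ranges = list(c(11, 50)))
  term <- prof$mean[prof$resno %in% c(1:10, 51:60)]
  core <- prof$mean[prof$resno %in% 11:50]
  expect_gt(mean(term), mean(core))
  expect_true(all(prof$mean >= 0) && all(prof$sd >= 0))

  # single flexible residue at 10x core noise is a local maximum
  spec2 <- ensemble_spec(n_models = 10L, n_residues = 60L,
                         rigid_ranges = list(c(1, 29), c(31, 60)),
                         sigma_core = 0.5, sigma_flex = 5,
                         flexible_ranges = list(c(30, 30)),
                         planted_bonds = data.frame(res_i = integer(0),
                                                    res_j = integer(0),
                                                    fraction = numeric(0)),
                         seed = 9)
  ens2 <- make_ensemble(spec2)
  prof2 <- per_residue_displacement(ens2, 1, "CA",
                                    superpose_ranges = list(c(1, 29), c(31, 60)))
  expect_equal(prof2$resno[which.max(prof2$mean)], 30L)
  # identical models: all-zero profile
  m <- toy_model(matrix(rnorm(45), ncol = 3))
  prof0 <- per_residue_displacement(new_ensemble(list(m, m)), 1, "CA",
                                    superpose_ranges = list(c(1, 15)))
  expect_equal(max(prof0$mean), 0, tolerance = 1e-10)
})

test_that("superposition RMSD agrees with an independent implementation", {
  set.seed(31)
  A <- matrix(rnorm(60), ncol = 3)
  B <- A + matrix(rnorm(60, sd = 0.8), ncol = 3)
  ours <- kabsch_superpose(A, B)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})
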