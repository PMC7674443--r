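# Optimal superposition, pairwise RMSD, representative selection, and
# per-residue displacement profiles for structure ensembles.

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `mobile` onto `reference` (reflections excluded). The transform maps a
#' coordinate row `x` to `x %*% t(R) + t`.
#'
#' @param mobile,reference n x 3 coordinate matrices, `n >= 3`, not collinear.
#' @return list of class `superposition` with elements `rotation` (3 x 3,
#'   determinant +1), `translation` (length-3) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stop("mobile and reference must be equal-size n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 atoms are required for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  sv_x <- svd(X)$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1)) {
    stop("degenerate (collinear) coordinates: rotation is not determined")
  }
  C <- crossprod(X, Y)                      # 3 x 3 covariance
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # y ~ R x (column convention)
  fitted <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd), class = "superposition")
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 matrix.
#' @param sp a `superposition` from [kabsch_superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' Pairwise superposition-RMSD matrix over an ensemble
#'
#' Entry `(i, j)` is the minimized RMSD between models `i` and `j` on the
#' chosen atom set and residue ranges.
#'
#' @inheritParams select_coords
#' @return symmetric matrix of class `rmsd_matrix` with a `selection`
#'   attribute recording the atom set and ranges used.
#' @export
pairwise_rmsd_matrix <- function(ensemble, atom_name = "CA", residue_ranges = NULL) {
  coords <- select_coords(ensemble, atom_name, residue_ranges)
  n <- length(coords)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      M[i, j] <- M[j, i] <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
    }
  }
  structure(M, class = c("rmsd_matrix", "matrix"),
            selection = list(atom_name = atom_name, residue_ranges = residue_ranges))
}

#' Representative model: lowest mean RMSD to all others
#'
#' @param matrix a symmetric RMSD matrix (e.g. from [pairwise_rmsd_matrix()]).
#' @return 1-based model index minimizing the off-diagonal row mean; ties are
#'   broken by the lowest index.
#' @export
select_representative <- function(matrix) {
  M <- unclass(matrix)
  n <- nrow(M)
  if (is.null(n) || n < 2L) stop("need at least 2 models")
  means <- (rowSums(M) - diag(M)) / (n - 1L)
  which.min(means)  # which.min returns the first (lowest) index on ties
}

#' RMSD of each model to the representative: mean and SD
#'
#' Averaged over the non-representative models, on the stated selection
#' (e.g. backbone C-alpha of the well-defined ranges).
#'
#' @inheritParams select_coords
#' @param representative 1-based index of the representative model.
#' @return list with `mean`, `sd` (Angstrom) and the per-model `rmsd` vector.
#' @export
rmsd_to_reference_stats <- function(ensemble, representative,
                                    atom_name = "CA", residue_ranges = NULL) {
  coords <- select_coords(ensemble, atom_name, residue_ranges)
  n <- length(coords)
  if (n < 2L) stop("need at least 2 models")
  ref <- coords[[representative]]
  others <- setdiff(seq_len(n), representative)
  r <- vapply(others, function(i) kabsch_superpose(coords[[i]], ref)$rmsd, 0)
  list(mean = mean(r), sd = stats::sd(r),
       rmsd = stats::setNames(r, others), representative = representative)
}

#' Per-residue displacement profile relative to the representative
#'
#' Each model is superposed onto the representative on the caller-supplied
#' rigid-core ranges (no hidden default), then the displacement of the chosen
#' atom is measured for every residue carrying it. Mean and SD are taken over
#' the non-representative models.
#'
#' @inheritParams select_coords
#' @param representative 1-based representative model index.
#' @param superpose_ranges residue ranges used for the superposition fit
#'   (required; typically the well-defined core).
#' @return data.frame with columns `resno`, `mean` and `sd` (Angstrom).
#' @export
per_residue_displacement <- function(ensemble, representative,
                                     atom_name = "CA", superpose_ranges) {
  if (missing(superpose_ranges) || is.null(superpose_ranges)) {
    stop("superpose_ranges must be given explicitly")
  }
  fit_coords <- select_coords(ensemble, atom_name, superpose_ranges)
  all_coords <- select_coords(ensemble, atom_name, NULL)
  n <- length(fit_coords)
  if (n < 2L) stop("need at least 2 models")
  ref_fit <- fit_coords[[representative]]
  ref_all <- all_coords[[representative]]
  others <- setdiff(seq_len(n), representative)
  disp <- vapply(others, function(i) {
    sp <- kabsch_superpose(fit_coords[[i]], ref_fit)
    moved <- apply_superposition(all_coords[[i]], sp)
    sqrt(rowSums((moved - ref_all)^2))
  }, numeric(nrow(ref_all)))
  resno <- as.integer(sub(":.*$", "", rownames(ref_all)))
  data.frame(resno = resno,
             mean = rowMeans(disp),
             sd = apply(disp, 1, stats::sd))
}
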