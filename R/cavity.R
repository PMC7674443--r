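# Interior-cavity and open-pocket detection on a single structure model by
# grid flood-fill, with lining-residue reporting and composition classes.

# Bondi van der Waals radii (Angstrom); unlisted elements fall back to carbon.
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                 SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- BONDI_RADII[toupper(element)]
  r[is.na(r)] <- BONDI_RADII[["C"]]
  unname(r)
}

# Occupancy grid: TRUE where a grid center lies within (vdW + probe) of any
# heavy atom. Returns logical 3-D array plus axis origins.
occupancy_grid <- function(xyz, radii, probe, spacing, origin, dims) {
  occ <- array(FALSE, dims)
  for (a in seq_len(nrow(xyz))) {
    r <- radii[a] + probe
    lo <- pmax(1L, floor((xyz[a, ] - r - origin) / spacing) + 1L)
    hi <- pmin(dims, ceiling((xyz[a, ] + r - origin) / spacing) + 1L)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- (origin[1] + (ix - 1) * spacing - xyz[a, 1])^2
    dy2 <- (origin[2] + (iy - 1) * spacing - xyz[a, 2])^2
    dz2 <- (origin[3] + (iz - 1) * spacing - xyz[a, 3])^2
    local <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
    occ[ix, iy, iz] <- occ[ix, iy, iz] | local
  }
  occ
}

# 6-connected flood fill over `open` cells from seed linear indices.
flood_fill <- function(open, seeds) {
  dims <- dim(open)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  visited <- array(FALSE, dims)
  frontier <- seeds[open[seeds] & !visited[seeds]]
  visited[frontier] <- TRUE
  sx <- 1L; sy <- nx; sz <- nx * ny
  while (length(frontier)) {
    i0 <- frontier - 1L
    ix <- i0 %% nx; iy <- (i0 %/% nx) %% ny; iz <- i0 %/% sz
    nb <- c(frontier[ix > 0L] - sx, frontier[ix < nx - 1L] + sx,
            frontier[iy > 0L] - sy, frontier[iy < ny - 1L] + sy,
            frontier[iz > 0L] - sz, frontier[iz < nz - 1L] + sz)
    nb <- unique(nb[open[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

boundary_indices <- function(dims) {
  idx <- array(seq_len(prod(dims)), dims)
  unique(c(idx[1, , ], idx[dims[1], , ], idx[, 1, ], idx[, dims[2], ],
           idx[, , 1], idx[, , dims[3]]))
}

connected_components <- function(open) {
  comps <- list()
  remaining <- open
  repeat {
    seed <- which(remaining)[1]
    if (is.na(seed)) break
    comp <- flood_fill(remaining, seed)
    comps[[length(comps) + 1L]] <- which(comp)
    remaining[comp] <- FALSE
  }
  comps
}

grid_centers <- function(linear, dims, origin, spacing) {
  i0 <- linear - 1L
  cbind(origin[1] + (i0 %% dims[1]) * spacing,
        origin[2] + ((i0 %/% dims[1]) %% dims[2]) * spacing,
        origin[3] + (i0 %/% (dims[1] * dims[2])) * spacing)
}

#' Detect interior cavities or open pockets by grid flood-fill
#'
#' A regular grid covers the model's bounding box plus a margin. Cells within
#' `vdW + probe` of any heavy atom are occupied; flood-fill (6-connectivity)
#' from the box boundary marks the exterior; remaining empty connected
#' components of volume at least `min_volume` are interior cavities, sorted
#' by volume.
#'
#' Open-mouthed pockets are invisible to this closed-cavity definition, so
#' `mode = "pocket"` first repeats the exterior flood-fill with an enlarged
#' probe (`envelope_probe`, default 3.0 Angstrom, sized to seal a
#' substrate-scale mouth); cells empty at the normal probe but inside that
#' envelope are pocket space, and its connected components are reported the
#' same way.
#'
#' @param model a per-model atom data.frame (element of `ensemble$models`).
#' @param spacing grid spacing, Angstrom (default 0.6).
#' @param probe probe radius, Angstrom (default 1.4, water-sized).
#' @param min_volume minimum reported volume, Angstrom^3 (default 30).
#' @param mode `"cavity"` (closed interior voids, default) or `"pocket"`.
#' @param envelope_probe enlarged probe for pocket mode, Angstrom.
#' @return list of `cavity_result` objects, each with `voxels` (n x 3 center
#'   coordinates), `volume` (Angstrom^3) and `spacing`; empty list if none.
#' @export
detect_cavities <- function(model, spacing = 0.6, probe = 1.4, min_volume = 30,
                            mode = c("cavity", "pocket"), envelope_probe = 3.0) {
  mode <- match.arg(mode)
  stopifnot(spacing > 0, probe >= 0, min_volume >= 0)
  heavy <- model[model$element != "H", , drop = FALSE]
  if (!nrow(heavy)) stop("model has no heavy atoms")
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  radii <- vdw_radius(heavy$element)
  max_probe <- if (mode == "pocket") max(probe, envelope_probe) else probe
  margin <- max(radii) + max_probe + 2 * spacing
  origin <- apply(xyz, 2, min) - margin
  upper <- apply(xyz, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((upper - origin) / spacing)) + 1L)
  occ <- occupancy_grid(xyz, radii, probe, spacing, origin, dims)
  exterior <- flood_fill(!occ, boundary_indices(dims))
  space <- !occ & !exterior          # closed interior voids
  if (mode == "pocket") {
    occ_env <- occupancy_grid(xyz, radii, envelope_probe, spacing, origin, dims)
    exterior_env <- flood_fill(!occ_env, boundary_indices(dims))
    space <- !occ & !exterior_env    # empty cells inside the sealed envelope
  }
  comps <- connected_components(space)
  vols <- vapply(comps, length, 1L) * spacing^3
  keep <- order(vols, decreasing = TRUE)
  keep <- keep[vols[keep] >= min_volume]
  lapply(keep, function(k) {
    structure(list(voxels = grid_centers(comps[[k]], dims, origin, spacing),
                   volume = vols[k], spacing = spacing, mode = mode),
              class = "cavity_result")
  })
}

#' @export
print.cavity_result <- function(x, ...) {
  cat("<cavity_result> ", x$mode, ", volume ", round(x$volume, 1),
      " A^3 (", nrow(x$voxels), " voxels at ", x$spacing, " A)\n", sep = "")
  invisible(x)
}

#' Residues lining a cavity
#'
#' Residues with at least one heavy atom within `cutoff` of at least one
#' cavity voxel center, sorted by residue number.
#'
#' @param cavity a `cavity_result`.
#' @param model the model the cavity was detected on.
#' @param cutoff Angstrom (default 4.5).
#' @return integer vector of residue numbers.
#' @export
lining_residues <- function(cavity, model, cutoff = 4.5) {
  heavy <- model[model$element != "H", , drop = FALSE]
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  vox <- cavity$voxels
  near <- vapply(seq_len(nrow(xyz)), function(a) {
    d2 <- (vox[, 1] - xyz[a, 1])^2 + (vox[, 2] - xyz[a, 2])^2 +
      (vox[, 3] - xyz[a, 3])^2
    any(d2 <= cutoff^2)
  }, TRUE)
  sort(unique(heavy$resno[near]))
}

#' Composition classes of a residue set
#'
#' Classes follow the conventional surface coloring: positive `{R, K, H}`,
#' negative `{E, D}`, hydrophobic `{A, V, L, I, M, F, W, Y, P}`, polar the
#' remainder (`G, S, T, C, N, Q`).
#'
#' @param residues residue numbers.
#' @param sequence full-protein one-letter string indexed by residue number
#'   (residue `i` is `substr(sequence, i, i)`).
#' @return named integer vector: `positive`, `negative`, `hydrophobic`,
#'   `polar`, `total`.
#' @export
annotate_composition <- function(residues, sequence) {
  if (length(residues) && max(residues) > nchar(sequence)) {
    stop("residue number beyond sequence length")
  }
  aa <- vapply(residues, function(i) substr(sequence, i, i), "")
  c(positive = sum(aa %in% c("R", "K", "H")),
    negative = sum(aa %in% c("E", "D")),
    hydrophobic = sum(aa %in% c("A", "V", "L", "I", "M", "F", "W", "Y", "P")),
    polar = sum(aa %in% c("G", "S", "T", "C", "N", "Q")),
    total = length(aa))
}
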