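# Shared fixtures and independent oracles, all built in code.

AA3 <- c(A = "ALA", C = "CYS", G = "GLY", R = "ARG", K = "LYS", H = "HIS",
         E = "GLU", D = "ASP", S = "SER", V = "VAL", L = "LEU", I = "ILE",
         M = "MET", F = "PHE", W = "TRP", Y = "TYR", P = "PRO", T = "THR",
         N = "ASN", Q = "GLN")

# One-atom-per-residue toy model (CA unless stated); coords is n x 3.
toy_model <- function(coords, aa = NULL, atom = "CA", element = "C",
                      resno = seq_len(nrow(coords))) {
  aa <- aa %||% rep("A", nrow(coords))
  data.frame(resno = resno, resid = unname(AA3[aa]), aa = aa,
             atom = atom, element = element,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Independent oracle: minimum RMSD over a dense Euler-angle (z-y-z) rotation
# grid, vectorized over (alpha, gamma) per beta slice. Translation is
# optimal automatically by centering both point sets.
grid_min_rmsd <- function(mobile, reference, n_alpha = 100, n_beta = 100,
                          n_gamma = 100) {
  X <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Y <- sweep(as.matrix(reference), 2, colMeans(reference))
  n <- nrow(X)
  alpha <- seq(0, 2 * pi, length.out = n_alpha + 1)[-(n_alpha + 1)]
  beta <- seq(0, pi, length.out = n_beta)
  gamma <- seq(0, 2 * pi, length.out = n_gamma + 1)[-(n_gamma + 1)]
  ag <- expand.grid(alpha = alpha, gamma = gamma)
  ca <- cos(ag$alpha); sa <- sin(ag$alpha)
  cg <- cos(ag$gamma); sg <- sin(ag$gamma)
  best <- Inf
  for (b in beta) {
    cb <- cos(b); sb <- sin(b)
    # R = Rz(alpha) Ry(beta) Rz(gamma), one row per (alpha, gamma)
    r11 <- ca * cb * cg - sa * sg; r12 <- -ca * cb * sg - sa * cg; r13 <- ca * sb
    r21 <- sa * cb * cg + ca * sg; r22 <- -sa * cb * sg + ca * cg; r23 <- sa * sb
    r31 <- -sb * cg;               r32 <- sb * sg;                 r33 <- cb
    ss <- 0
    for (i in seq_len(n)) {
      dx <- r11 * X[i, 1] + r12 * X[i, 2] + r13 * X[i, 3] - Y[i, 1]
      dy <- r21 * X[i, 1] + r22 * X[i, 2] + r23 * X[i, 3] - Y[i, 2]
      dz <- r31 * X[i, 1] + r32 * X[i, 2] + r33 * X[i, 3] - Y[i, 3]
      ss <- ss + dx^2 + dy^2 + dz^2
    }
    best <- min(best, min(ss))
  }
  sqrt(best / n)
}

# Independent oracle: all perfect matchings of `members`, built by always
# pairing the HIGHEST remaining element (different recursion than the
# package's lowest-first search); returns list of 2-column matrices.
oracle_all_matchings <- function(members) {
  if (!length(members)) return(list(NULL))
  members <- sort(members)
  a <- members[length(members)]
  rest <- members[-length(members)]
  out <- list()
  for (b in rest) {
    for (sub in oracle_all_matchings(setdiff(rest, b))) {
      out[[length(out) + 1L]] <- rbind(sub, c(b, a))
    }
  }
  out
}

oracle_best_matching_score <- function(members, weights) {
  # weights: named vector "i-j" (i < j)
  scores <- vapply(oracle_all_matchings(members), function(m) {
    sum(weights[paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]), sep = "-")])
  }, 0)
  max(scores)
}

# Build a cys_pair_stats object directly from a named frequency table
# ("i-j" = frequency), with synthetic distances consistent with the
# frequencies over `n_models` models and a 3 Angstrom threshold.
stats_from_freq <- function(freq, n_models = 100) {
  ab <- do.call(rbind, strsplit(names(freq), "-", fixed = TRUE))
  pairs <- data.frame(res_i = as.integer(ab[, 1]), res_j = as.integer(ab[, 2]))
  D <- t(vapply(freq, function(f) {
    k <- round(f * n_models)
    c(rep(2.0, k), rep(6.0, n_models - k))
  }, numeric(n_models)))
  structure(list(pairs = pairs, distances = D, n_models = n_models),
            class = "cys_pair_stats")
}

# Hollow shell of pseudo-atoms whose interior empty sphere (inside
# vdW 1.7 + probe 1.4) has radius `cavity_radius`; optionally with a bore
# hole of angular half-width `hole_deg` around +z.
hollow_shell_model <- function(cavity_radius = 6, probe = 1.4, hole_deg = 0) {
  R <- cavity_radius + 1.7 + probe
  th <- seq(0, pi, length.out = 26)
  ph <- seq(0, 2 * pi, length.out = 2 * 26 + 1)[-(2 * 26 + 1)]
  g <- expand.grid(th = th, ph = ph)
  if (hole_deg > 0) g <- g[g$th > hole_deg * pi / 180, ]
  coords <- cbind(R * sin(g$th) * cos(g$ph),
                  R * sin(g$th) * sin(g$ph),
                  R * cos(g$th))
  coords <- coords[!duplicated(round(coords, 3)), , drop = FALSE]
  toy_model(coords)
}

# Paper-condition synthetic ensemble spec shared by several tests.
default_bonds <- function() {
  data.frame(res_i = c(52L, 56L, 59L, 65L, 136L),
             res_j = c(127L, 123L, 120L, 77L, 148L),
             fraction = c(0.924, 0.561, 1, 1, 1))
}
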