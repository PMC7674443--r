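# Disulfide-connectivity inference from gamma-sulfur (SG) distance
# statistics across a structure ensemble. Pair occurrences are counted
# independently per pair (one SG may be under threshold to two partners in
# the same model); disjointness is imposed only at the matching step.

#' Per-pair SG-SG distances across an ensemble
#'
#' Computes the Euclidean SG-SG distance for every unordered cysteine pair in
#' every model. Frequencies are left unset; see [pair_frequency()].
#'
#' @param ensemble an `ensemble`.
#' @param cysteines residue numbers of the cysteines to consider; default all
#'   CYS residues in the sequence. Each must carry an SG atom in every model.
#' @return object of class `cys_pair_stats`: list with `pairs` (data.frame
#'   `res_i`, `res_j`), `distances` (n_pairs x n_models matrix, Angstrom) and
#'   `n_models`.
#' @export
sg_distance_table <- function(ensemble, cysteines = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (is.null(cysteines)) {
    aa <- strsplit(ensemble$sequence, "")[[1]]
    cysteines <- ensemble$resno[aa == "C"]
  }
  cysteines <- sort(unique(as.integer(cysteines)))
  if (length(cysteines) < 2L) stop("need at least two cysteines")
  # SG coordinates per model, validated residue-by-residue
  sg <- lapply(seq_along(ensemble$models), function(k) {
    m <- ensemble$models[[k]]
    out <- matrix(NA_real_, length(cysteines), 3L)
    for (ci in seq_along(cysteines)) {
      row <- which(m$resno == cysteines[ci] & m$atom == "SG")
      if (!length(row)) {
        stop("no SG atom for residue ", cysteines[ci],
             " in model ", ensemble$model_ids[k])
      }
      out[ci, ] <- as.numeric(m[row[1], c("x", "y", "z")])
    }
    out
  })
  pairs <- t(utils::combn(seq_along(cysteines), 2L))
  D <- vapply(sg, function(co) {
    sqrt(rowSums((co[pairs[, 1], , drop = FALSE] - co[pairs[, 2], , drop = FALSE])^2))
  }, numeric(nrow(pairs)))
  D <- matrix(D, nrow = nrow(pairs))
  structure(
    list(pairs = data.frame(res_i = cysteines[pairs[, 1]],
                            res_j = cysteines[pairs[, 2]]),
         distances = D, n_models = length(sg)),
    class = "cys_pair_stats"
  )
}

#' @export
print.cys_pair_stats <- function(x, ...) {
  cat("<cys_pair_stats> ", nrow(x$pairs), " pairs x ", x$n_models, " models\n", sep = "")
  df <- x$pairs
  df$min_d <- apply(x$distances, 1, min)
  df$median_d <- apply(x$distances, 1, stats::median)
  print(utils::head(df[order(df$min_d), ], 10))
  invisible(x)
}

#' Fraction of models with SG-SG distance under threshold
#'
#' Strict inequality: a pair at exactly the threshold does not count.
#'
#' @param stats a `cys_pair_stats` from [sg_distance_table()].
#' @param threshold distance threshold in Angstrom (default 3.0).
#' @return the same object with `pairs$frequency` filled in.
#' @export
pair_frequency <- function(stats, threshold = 3.0) {
  stopifnot(inherits(stats, "cys_pair_stats"), threshold > 0)
  stats$pairs$frequency <- rowMeans(stats$distances < threshold)
  stats$threshold <- threshold
  stats
}

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")

# Exact maximum-weight perfect matching by recursion over the free cysteines.
# Intended for the <= 12 cysteines of disulfide-rich small proteins
# (10,395 matchings at n = 12).
max_weight_matching <- function(members, weight_of) {
  if (!length(members)) return(list(score = 0, pairs = NULL))
  a <- members[1]
  best <- NULL
  for (b in members[-1]) {
    sub <- max_weight_matching(setdiff(members, c(a, b)), weight_of)
    sc <- weight_of(a, b) + sub$score
    if (is.null(best) || sc > best$score + 1e-12) {
      best <- list(score = sc, pairs = rbind(c(a, b), sub$pairs))
    }
  }
  best
}

#' Assign disulfide connectivity by maximum-weight perfect matching
#'
#' Finds the disjoint set of cysteine pairs maximizing the summed
#' sub-threshold frequency, honoring any pairs fixed a priori (for example
#' bonds that are unambiguous in every model). An odd number of free
#' cysteines is an error: in a fully oxidized protein every cysteine is
#' bonded.
#'
#' @param stats a `cys_pair_stats` with frequencies (see [pair_frequency()]).
#' @param fixed_pairs optional two-column matrix / data.frame of residue
#'   pairs honored verbatim.
#' @return list of class `pairing` with `pairs` (data.frame `res_i`, `res_j`,
#'   `frequency`, `fixed`), `score` (sum of member frequencies) and
#'   `unpaired` (always empty on success).
#' @export
assign_pairing <- function(stats, fixed_pairs = NULL) {
  stopifnot(inherits(stats, "cys_pair_stats"))
  if (is.null(stats$pairs$frequency)) stop("call pair_frequency() first")
  freq <- stats$pairs$frequency
  names(freq) <- pair_key(stats$pairs$res_i, stats$pairs$res_j)
  weight_of <- function(a, b) {
    w <- freq[pair_key(a, b)]
    if (is.na(w)) 0 else unname(w)
  }
  cys <- sort(unique(c(stats$pairs$res_i, stats$pairs$res_j)))
  fixed <- NULL
  if (!is.null(fixed_pairs)) {
    fixed <- as.matrix(fixed_pairs)[, 1:2, drop = FALSE]
    storage.mode(fixed) <- "integer"
    if (anyDuplicated(as.vector(fixed))) stop("a cysteine appears twice in fixed_pairs")
  }
  free <- setdiff(cys, as.vector(fixed))
  if (length(free) %% 2L != 0L) {
    stop("odd number of free cysteines (", length(free),
         "): a perfect pairing requires an even count")
  }
  best <- max_weight_matching(free, weight_of)
  pairs <- rbind(fixed, best$pairs)
  df <- data.frame(res_i = pmin(pairs[, 1], pairs[, 2]),
                   res_j = pmax(pairs[, 1], pairs[, 2]),
                   frequency = vapply(seq_len(nrow(pairs)),
                                      function(r) weight_of(pairs[r, 1], pairs[r, 2]), 0),
                   fixed = seq_len(nrow(pairs)) <= NROW(fixed))
  df <- df[order(df$res_i), ]
  rownames(df) <- NULL
  structure(list(pairs = df, score = sum(df$frequency), unpaired = integer(0)),
            class = "pairing")
}

#' @export
print.pairing <- function(x, ...) {
  cat("<pairing> score ", format(x$score, digits = 4), "\n", sep = "")
  print(x$pairs)
  invisible(x)
}

#' Models consistent with a disulfide pairing
#'
#' A model is consistent when every pair of the pairing has SG-SG distance
#' strictly under the threshold in that model.
#'
#' @param ensemble an `ensemble`.
#' @param pairing a `pairing` (from [assign_pairing()]) or a two-column
#'   matrix of residue pairs.
#' @param threshold Angstrom (default 3.0, strict `<`).
#' @return list with `count` and 1-based `model_indices`.
#' @export
models_consistent_with_pairing <- function(ensemble, pairing, threshold = 3.0) {
  pairs <- if (inherits(pairing, "pairing")) {
    as.matrix(pairing$pairs[, c("res_i", "res_j")])
  } else as.matrix(pairing)[, 1:2, drop = FALSE]
  stats <- sg_distance_table(ensemble, cysteines = unique(as.vector(pairs)))
  key <- pair_key(stats$pairs$res_i, stats$pairs$res_j)
  rows <- match(pair_key(pairs[, 1], pairs[, 2]), key)
  if (anyNA(rows)) stop("pairing refers to cysteines absent from the ensemble")
  ok <- colSums(stats$distances[rows, , drop = FALSE] < threshold) == nrow(pairs)
  list(count = sum(ok), model_indices = which(ok))
}
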