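# Disulfide mapping by limited proteolysis + LC-MS: in-silico digestion,
# enumeration of disulfide-linked multi-peptide species, average/monoisotopic
# mass computation, observed-mass matching, and connectivity implications.

# Residue masses (Da): average and monoisotopic; nitrogen counts per residue
# (backbone amide + side chain) for uniform 15N labeling shifts.
AA_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
AA_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
AA_NITROGENS <- c(
  G = 1, A = 1, S = 1, P = 1, V = 1, T = 1, C = 1, L = 1, I = 1, N = 2,
  D = 1, Q = 2, K = 2, E = 1, M = 1, H = 3, F = 1, R = 4, Y = 1, W = 2)
MASS_WATER_AVG <- 18.01528
MASS_WATER_MONO <- 18.010565
MASS_H_AVG <- 1.00794
MASS_H_MONO <- 1.007825
MASS_15N_SHIFT <- 0.99703

#' Mature GLuc sequence (secretion tag removed, E100A/G103R)
#'
#' The 168-residue mature *Gaussia princeps* luciferase used throughout the
#' worked examples: UniProtKB Q9BLZ2 minus its 17-residue secretion tag,
#' numbered from the first post-tag residue (K1), carrying the
#' expression-enhancing substitutions E100A and G103R. Also shipped as
#' `inst/extdata/gluc_mature.fasta`.
#'
#' @return one-letter amino-acid string of length 168.
#' @export
gluc_sequence <- function() {
  paste0(
    "KPTENNEDFNIVAVASNFATTDLDADRGKLPGKKLPLEVLKEMEANARKA",
    "GCTRGCLICLSHIKCTPKMKKFIPGRCHTYEGDKESAQGGIGEAIVDIPA",
    "IPRFKDLEPMEQFIAQVDLCVDCTTGCLKGLANVQCSDLLKKWLPQRCAT",
    "FASKIQGQVDKIKGAGGD")
}

#' Read a protein sequence from FASTA
#'
#' Thin wrapper returning named one-letter strings.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  stats::setNames(toupper(unlist(seqs)), names(seqs))
}

#' In-silico proteolytic digest
#'
#' Trypsin rule: cleave C-terminal to K or R except when the next residue is
#' P. Peptides are generated for 0 to `max_missed_cleavages` missed sites;
#' spans are in the numbering of the input sequence.
#'
#' @param sequence one-letter protein sequence.
#' @param protease currently `"trypsin"`.
#' @param max_missed_cleavages non-negative integer (default 0).
#' @return data.frame with `start`, `end`, `sequence`, `n_missed`, `n_cys`
#'   and a list-column `cys_positions`.
#' @export
digest <- function(sequence, protease = "trypsin", max_missed_cleavages = 0L) {
  protease <- match.arg(protease)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!length(aa)) stop("empty sequence")
  unknown <- setdiff(unique(aa), names(AA_MASS_AVG))
  if (length(unknown)) stop("unknown residue letter(s): ", paste(unknown, collapse = ", "))
  L <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < L & aa[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, L)              # fragment k spans bounds[k]+1 .. bounds[k+1]
  n_frag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(n_frag)) {
    for (m in 0:max_missed_cleavages) {
      j <- i + m
      if (j > n_frag) break
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      pep <- substr(sequence, s, e)
      cys <- s - 1L + which(strsplit(pep, "")[[1]] == "C")
      rows[[length(rows) + 1L]] <-
        data.frame(start = s, end = e, sequence = pep, n_missed = m,
                   n_cys = length(cys), stringsAsFactors = FALSE)
      rows[[length(rows)]]$cys_positions <- I(list(cys))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Peptide mass (average or monoisotopic, optional uniform 15N labeling)
#'
#' Sum of residue masses plus water; uniform 15N labeling adds 0.99703 Da
#' per nitrogen atom (backbone and side chain).
#'
#' @param sequence peptide one-letter string.
#' @param mass_type `"average"` (default) or `"monoisotopic"`.
#' @param label `"none"` (default) or `"15N"`.
#' @return mass in Da.
#' @export
peptide_mass <- function(sequence, mass_type = c("average", "monoisotopic"),
                         label = c("none", "15N")) {
  mass_type <- match.arg(mass_type)
  label <- match.arg(label)
  aa <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(unique(aa), names(AA_MASS_AVG))
  if (length(unknown)) stop("unknown residue letter(s): ", paste(unknown, collapse = ", "))
  tbl <- if (mass_type == "average") AA_MASS_AVG else AA_MASS_MONO
  water <- if (mass_type == "average") MASS_WATER_AVG else MASS_WATER_MONO
  m <- sum(tbl[aa]) + water
  if (label == "15N") m <- m + MASS_15N_SHIFT * sum(AA_NITROGENS[aa])
  unname(m)
}

#' Enumerate disulfide-linked peptide species
#'
#' All subsets of at most `max_peptides` digest fragments in which every
#' member contains at least one cysteine (required only for multi-peptide
#' species). Under the default all-cysteines-paired oxidation model,
#' `n_disulfides = floor(total cysteines / 2)` and each bond removes two
#' hydrogens; `oxidation = "free"` additionally enumerates every feasible
#' lower bond count.
#'
#' @param peptides digest data.frame from [digest()].
#' @param max_peptides maximum fragments per species (default 3).
#' @param mass_type,label passed to [peptide_mass()].
#' @param oxidation `"all_paired"` (default) or `"free"`.
#' @param max_species guard against combinatorial explosion (default 2e5).
#' @return data.frame with `spans`, `n_peptides`, `n_cys`, `n_disulfides`,
#'   `mass` and a list-column `peptide_rows` (row indices into `peptides`).
#' @export
enumerate_linked_species <- function(peptides, max_peptides = 3L,
                                     mass_type = c("average", "monoisotopic"),
                                     label = c("none", "15N"),
                                     oxidation = c("all_paired", "free"),
                                     max_species = 2e5) {
  mass_type <- match.arg(mass_type)
  label <- match.arg(label)
  oxidation <- match.arg(oxidation)
  stopifnot(max_peptides >= 1L)
  n <- nrow(peptides)
  pep_mass <- vapply(peptides$sequence, peptide_mass, 0,
                     mass_type = mass_type, label = label, USE.NAMES = FALSE)
  h2 <- 2 * (if (mass_type == "average") MASS_H_AVG else MASS_H_MONO)
  with_cys <- which(peptides$n_cys > 0L)
  sizes <- if (max_peptides >= 2L) 2:max_peptides else integer(0)
  n_cand <- n + sum(choose(length(with_cys), sizes))
  if (n_cand > max_species) {
    stop("candidate species count ", n_cand, " exceeds max_species = ", max_species)
  }
  multi <- unlist(lapply(sizes, function(k) {
    if (length(with_cys) < k) return(NULL)
    cols <- utils::combn(with_cys, k)
    lapply(seq_len(ncol(cols)), function(j) cols[, j])
  }), recursive = FALSE)
  # members of a multi-peptide species must not overlap in sequence
  multi <- Filter(function(idx) {
    spans <- unlist(lapply(idx, function(i) peptides$start[i]:peptides$end[i]))
    !anyDuplicated(spans)
  }, multi %||% list())
  subsets <- c(lapply(seq_len(n), function(i) i), multi)
  rows <- lapply(subsets, function(idx) {
    total_cys <- sum(peptides$n_cys[idx])
    n_ss_max <- total_cys %/% 2L
    n_ss <- if (oxidation == "all_paired") n_ss_max else 0:n_ss_max
    data.frame(
      spans = paste(sprintf("%d-%d", peptides$start[idx], peptides$end[idx]),
                    collapse = "+"),
      n_peptides = length(idx), n_cys = total_cys, n_disulfides = n_ss,
      mass = sum(pep_mass[idx]) - n_ss * h2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$peptide_rows <- I(rep(subsets,
                            vapply(rows, nrow, 1L)))
  rownames(out) <- NULL
  out
}

#' Match an observed mass against candidate linked species
#'
#' @param observed observed mass, Da.
#' @param species data.frame from [enumerate_linked_species()].
#' @param tolerance Da (default 0.5).
#' @return the species rows within tolerance, with a `delta` column
#'   (observed - computed), sorted by `abs(delta)`. Empty data.frame when
#'   nothing matches.
#' @export
match_mass <- function(observed, species, tolerance = 0.5) {
  stopifnot(tolerance > 0)
  species$delta <- observed - species$mass
  hit <- species[abs(species$delta) <= tolerance, , drop = FALSE]
  hit[order(abs(hit$delta)), , drop = FALSE]
}

# All perfect matchings of a cysteine set (list of two-column matrices).
all_perfect_matchings <- function(members) {
  if (!length(members)) return(list(NULL))
  a <- members[1]
  out <- list()
  for (b in members[-1]) {
    for (sub in all_perfect_matchings(setdiff(members, c(a, b)))) {
      out[[length(out) + 1L]] <- rbind(c(a, b), sub)
    }
  }
  out
}

graph_connected <- function(n_nodes, edges) {
  if (n_nodes <= 1L) return(TRUE)
  seen <- c(1L)
  repeat {
    nxt <- unique(c(edges[edges[, 1] %in% seen, 2], edges[edges[, 2] %in% seen, 1]))
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
  }
  length(seen) == n_nodes
}

#' Cysteine-connectivity implications of a matched linked species
#'
#' Enumerates every pairing of the species' cysteines in which (a) all
#' cysteines are bonded, (b) the peptides are held together (the
#' inter-peptide bond graph is connected), and (c) only `candidate_pairs`
#' are used when supplied. Reports, per cysteine pair, whether it occurs in
#' some valid pairing (`compatible`) or in every valid pairing (`implied`).
#'
#' @param match one row of a [match_mass()] result (or an
#'   `enumerate_linked_species()` row) with at least 2 peptides.
#' @param peptides the digest data.frame the species was built from.
#' @param candidate_pairs optional two-column matrix restricting the allowed
#'   cysteine pairs.
#' @return data.frame `cys_a`, `cys_b`, `inter_peptide`, `compatible`,
#'   `implied`; zero rows for a single-peptide species.
#' @export
connectivity_implications <- function(match, peptides, candidate_pairs = NULL) {
  idx <- match$peptide_rows[[1]]
  if (length(idx) < 2L) {
    return(data.frame(cys_a = integer(0), cys_b = integer(0),
                      inter_peptide = logical(0), compatible = logical(0),
                      implied = logical(0)))
  }
  cys <- unlist(peptides$cys_positions[idx])
  owner <- rep(seq_along(idx), lengths(peptides$cys_positions[idx]))
  names(owner) <- cys
  allowed <- function(a, b) {
    if (is.null(candidate_pairs)) return(TRUE)
    any((candidate_pairs[, 1] == a & candidate_pairs[, 2] == b) |
        (candidate_pairs[, 1] == b & candidate_pairs[, 2] == a))
  }
  valid <- Filter(function(m) {
    ok <- all(vapply(seq_len(nrow(m)), function(r) allowed(m[r, 1], m[r, 2]), TRUE))
    if (!ok) return(FALSE)
    inter <- m[owner[as.character(m[, 1])] != owner[as.character(m[, 2])], , drop = FALSE]
    edges <- cbind(owner[as.character(inter[, 1])], owner[as.character(inter[, 2])])
    graph_connected(length(idx), edges)
  }, all_perfect_matchings(sort(cys)))
  if (!length(valid)) {
    return(data.frame(cys_a = integer(0), cys_b = integer(0),
                      inter_peptide = logical(0), compatible = logical(0),
                      implied = logical(0)))
  }
  keys <- lapply(valid, function(m) pair_key(m[, 1], m[, 2]))
  all_keys <- sort(unique(unlist(keys)))
  in_all <- vapply(all_keys, function(k) all(vapply(keys, function(ks) k %in% ks, TRUE)), TRUE)
  ab <- do.call(rbind, strsplit(all_keys, "-", fixed = TRUE))
  a <- as.integer(ab[, 1]); b <- as.integer(ab[, 2])
  data.frame(cys_a = a, cys_b = b,
             inter_peptide = owner[as.character(a)] != owner[as.character(b)],
             compatible = TRUE, implied = unname(in_all), row.names = NULL)
}
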