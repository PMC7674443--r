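# Multi-model PDB input/output and typed access to models, residues and atoms.
#
# The container is deliberately simple: an `ensemble` is a list of per-model
# atom tables (one data.frame per MODEL block) that all share one residue
# sequence, which is validated on construction rather than assumed.

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

AA_1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK"
)

#' Build an ensemble from per-model atom tables
#'
#' Each model is a data.frame with columns `resno`, `resid` (three-letter),
#' `aa` (one-letter), `atom`, `element`, `x`, `y`, `z`. All models must share
#' the same `(resno, aa)` residue list; this is enforced here, never assumed.
#'
#' @param models list of per-model atom data.frames.
#' @param model_ids integer model identifiers (defaults to `1:n`).
#' @return an object of class `ensemble` with elements `models`, `model_ids`,
#'   `resno` (residue numbers) and `sequence` (one-letter string).
#' @export
new_ensemble <- function(models, model_ids = seq_along(models)) {
  stopifnot(length(models) >= 1L, length(model_ids) == length(models))
  ref <- residue_table(models[[1]])
  if (any(diff(ref$resno) <= 0L)) stop("residue numbers must be strictly increasing")
  for (k in seq_along(models)[-1]) {
    cur <- residue_table(models[[k]])
    if (nrow(cur) != nrow(ref)) {
      stop("model ", model_ids[k], " has ", nrow(cur),
           " residues but model ", model_ids[1], " has ", nrow(ref))
    }
    bad <- which(cur$resno != ref$resno | cur$aa != ref$aa)
    if (length(bad)) {
      b <- bad[1]
      stop("sequence mismatch at residue ", ref$resno[b], ": ",
           ref$aa3[b], " (model ", model_ids[1], ") vs ",
           cur$aa3[b], " (model ", model_ids[k], ")")
    }
  }
  structure(
    list(models = models, model_ids = as.integer(model_ids),
         resno = ref$resno, sequence = paste(ref$aa, collapse = "")),
    class = "ensemble"
  )
}

residue_table <- function(model) {
  idx <- !duplicated(model$resno)
  data.frame(resno = model$resno[idx], aa = model$aa[idx],
             aa3 = model$resid[idx], stringsAsFactors = FALSE)
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", length(x$models), " model(s), ",
      length(x$resno), " residues\n", sep = "")
  cat("  residues ", x$resno[1], "-", x$resno[length(x$resno)],
      "; sequence ", substr(x$sequence, 1, 40),
      if (nchar(x$sequence) > 40) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of models in an ensemble
#' @param ensemble an `ensemble`.
#' @return integer count.
#' @export
n_models <- function(ensemble) length(ensemble$models)

parse_atom_lines <- function(lines, model_label) {
  nm  <- trimws(substr(lines, 13, 16))
  alt <- substr(lines, 17, 17)
  res3 <- trimws(substr(lines, 18, 20))
  resno <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  icode <- substr(lines, 27, 27)
  if (any(icode != " ")) {
    stop("insertion codes are not supported (model ", model_label,
         ", residue ", resno[which(icode != " ")[1]], ")")
  }
  keep <- alt %in% c(" ", "A", "")
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " alternate-location atoms (altLoc not 'A' or blank)")
    lines <- lines[keep]; nm <- nm[keep]; res3 <- res3[keep]; resno <- resno[keep]
  }
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  if (anyNA(x) || anyNA(y) || anyNA(z) || anyNA(resno)) {
    stop("malformed ATOM record in model ", model_label)
  }
  elem <- trimws(substr(lines, 77, 78))
  # derive element from the atom name where column 77-78 is blank
  fallback <- sub("^[0-9]*", "", nm)
  fallback <- toupper(substr(fallback, 1, 1))
  elem <- ifelse(nzchar(elem), toupper(elem), fallback)
  aa <- unname(AA_3TO1[res3])
  if (anyNA(aa)) {
    unk <- unique(res3[is.na(aa)])
    warning("unknown residue type(s) mapped to X: ", paste(unk, collapse = ", "))
    aa[is.na(aa)] <- "X"
  }
  if (any(res3 == "MSE")) warning("MSE (selenomethionine) mapped to M")
  data.frame(resno = resno, resid = res3, aa = aa, atom = nm, element = elem,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

#' Read a multi-model PDB file
#'
#' Parses fixed-column `ATOM` records, one model per `MODEL`/`ENDMDL` block;
#' a file without `MODEL` records yields a one-model ensemble. Residue
#' numbering is taken verbatim from the file (no renumbering). Alternate
#' locations other than `'A'`/blank are dropped with a warning; insertion
#' codes are rejected. Hydrogens are read and retained in the atom tables but
#' excluded from geometry selections by default (see [select_coords()]).
#'
#' @param path path to a PDB file.
#' @return an [new_ensemble()] object.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(startsWith(rec, "MODEL"))
  if (length(model_starts) == 0L) {
    atoms <- lines[rec == "ATOM  "]
    if (!length(atoms)) stop("no ATOM records in ", path)
    return(new_ensemble(list(parse_atom_lines(atoms, 1L)), 1L))
  }
  model_ends <- which(startsWith(rec, "ENDMDL"))
  if (length(model_ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records in ", path)
  }
  models <- vector("list", length(model_starts))
  ids <- integer(length(model_starts))
  for (k in seq_along(model_starts)) {
    block <- lines[(model_starts[k] + 1L):(model_ends[k] - 1L)]
    atoms <- block[substr(block, 1, 6) == "ATOM  "]
    if (!length(atoms)) stop("model block ", k, " contains no ATOM records")
    id <- suppressWarnings(as.integer(trimws(substr(lines[model_starts[k]], 7, 14))))
    ids[k] <- if (is.na(id)) k else id
    models[[k]] <- parse_atom_lines(atoms, ids[k])
  }
  new_ensemble(models, ids)
}

format_atom_name <- function(name, element) {
  # element symbol occupies columns 13-14 right-justified for 1-letter elements
  if (nchar(name) >= 4L) return(substr(name, 1, 4))
  if (nchar(element) == 1L) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

#' Write a multi-model PDB file
#'
#' Standard `MODEL`/`ATOM`/`ENDMDL` layout with fixed 8.3 coordinate fields;
#' round-trips through [read_multimodel_pdb()] to 0.001 Angstrom. Coordinates
#' outside the fixed-width field (beyond -999.999 / 9999.999) are an error.
#'
#' @param ensemble an `ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ensemble"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  for (k in seq_along(ensemble$models)) {
    m <- ensemble$models[[k]]
    xyz <- as.matrix(m[, c("x", "y", "z")])
    if (any(xyz > 9999.999 + 5e-4) || any(xyz < -999.999 - 5e-4)) {
      stop("coordinate out of PDB fixed-width range in model ",
           ensemble$model_ids[k])
    }
    writeLines(sprintf("MODEL     %4d", ensemble$model_ids[k]), con)
    nms <- vapply(seq_len(nrow(m)),
                  function(i) format_atom_name(m$atom[i], m$element[i]), "")
    writeLines(sprintf(
      "ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(m)), nms, m$resid, m$resno, m$x, m$y, m$z, 1, 0,
      m$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Extract aligned coordinates for one atom type over residue ranges
#'
#' Returns per-model coordinate matrices aligned across models (identical
#' residue/atom order). `atom_name = "heavy"` selects all non-hydrogen atoms
#' of the selected residues; atoms not present in every model are then
#' dropped pairwise with a warning. For a named atom, a residue missing that
#' atom in any model is an error naming the model and residue.
#'
#' @param ensemble an `ensemble`.
#' @param atom_name atom label (e.g. `"CA"`, `"SG"`) or `"heavy"`.
#' @param residue_ranges selection accepted by [expand_ranges()]; `NULL`
#'   selects all residues.
#' @return list of n_sel x 3 matrices, one per model, rownames `resno:atom`.
#' @export
select_coords <- function(ensemble, atom_name = "CA", residue_ranges = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  residues <- if (is.null(residue_ranges)) ensemble$resno else expand_ranges(residue_ranges)
  if (!length(residues)) stop("empty residue selection")
  missing <- setdiff(residues, ensemble$resno)
  if (length(missing)) {
    stop("residue(s) not in ensemble: ", paste(missing, collapse = ", "))
  }
  heavy <- identical(atom_name, "heavy")
  keys <- NULL
  per_model <- lapply(seq_along(ensemble$models), function(k) {
    m <- ensemble$models[[k]]
    sel <- m$resno %in% residues & m$element != "H" &
      (if (heavy) TRUE else m$atom == atom_name)
    mm <- m[sel, , drop = FALSE]
    mm <- mm[order(mm$resno), , drop = FALSE]
    mm
  })
  if (heavy) {
    key_list <- lapply(per_model, function(mm) paste(mm$resno, mm$atom, sep = ":"))
    keys <- Reduce(intersect, key_list)
    if (!length(keys)) stop("no common heavy atoms across models for the selection")
    n_drop <- max(vapply(key_list, length, 1L)) - length(keys)
    if (n_drop > 0) warning("dropped ", n_drop, " atom(s) not present in every model")
  } else {
    for (k in seq_along(per_model)) {
      have <- unique(per_model[[k]]$resno)
      lack <- setdiff(residues, have)
      if (length(lack)) {
        stop("atom ", atom_name, " missing for residue ", lack[1],
             " in model ", ensemble$model_ids[k])
      }
    }
    keys <- paste(residues, atom_name, sep = ":")
  }
  lapply(per_model, function(mm) {
    rn <- paste(mm$resno, mm$atom, sep = ":")
    mm <- mm[match(keys, rn), , drop = FALSE]
    out <- as.matrix(mm[, c("x", "y", "z")])
    rownames(out) <- keys
    out
  })
}

#' One-letter sequence of a model
#'
#' @param model a per-model atom data.frame (element of `ensemble$models`).
#' @return one-letter amino-acid string (unknown residues are `X`).
#' @export
extract_sequence <- function(model) {
  paste(residue_table(model)$aa, collapse = "")
}
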