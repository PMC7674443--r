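# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand residue-range specifications
#'
#' Accepts a list of `c(start, end)` pairs, a two-column matrix, a plain
#' integer vector of residue numbers, or a compact string such as
#' `"10-18,36-81,96-145"`, and returns the sorted unique residue numbers.
#'
#' @param ranges ranges in any of the accepted forms.
#' @return integer vector of residue numbers.
#' @examples
#' expand_ranges("10-12,20")
#' expand_ranges(list(c(1, 3), c(7, 8)))
#' @export
expand_ranges <- function(ranges) {
  if (is.null(ranges)) return(integer(0))
  if (is.character(ranges)) {
    stopifnot(length(ranges) == 1L)
    parts <- strsplit(ranges, ",", fixed = TRUE)[[1]]
    parts <- trimws(parts[nzchar(trimws(parts))])
    ranges <- lapply(parts, function(p) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      if (anyNA(ab) || length(ab) > 2L) stop("cannot parse range '", p, "'")
      ab
    })
  }
  if (is.matrix(ranges)) ranges <- split(ranges, seq_len(nrow(ranges)))
  if (is.numeric(ranges)) return(sort(unique(as.integer(ranges))))
  out <- unlist(lapply(ranges, function(r) {
    r <- as.integer(r)
    if (length(r) == 1L) r else {
      if (r[2] < r[1]) stop("range end before start: ", r[1], "-", r[2])
      seq.int(r[1], r[2])
    }
  }))
  sort(unique(out))
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Random unit 3-vector(s); n x 3 matrix.
random_unit <- function(n = 1L) {
  v <- matrix(stats::rnorm(3L * n), ncol = 3L)
  v / sqrt(rowSums(v^2))
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) c(1, 0, 0) else v / n
}

# Deterministic JSON report writer (no timestamps -> byte-identical reruns).
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
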