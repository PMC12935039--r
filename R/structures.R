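#' RNA secondary structure objects
#'
#' An `rna_structure` bundles a sequence over `A,C,G,U,N` with a set of base
#' pairs. Pairs are stored as a two-column integer matrix of 1-based residue
#' indices `(i, j)` with `i < j`; each residue may appear in at most one pair.
#' Pseudoknots (crossing pairs) are representable: `pairs` is a general set,
#' not restricted to nested configurations.
#'
#' @param name identifier for the molecule.
#' @param sequence character scalar over `A,C,G,U,N`; `T` is accepted on input
#'   and converted to `U`.
#' @param pairs two-column matrix (or empty) of 1-based paired indices.
#' @return an object of class `rna_structure`.
#' @export
rna_structure <- function(name, sequence, pairs = NULL) {
  sequence <- normalize_sequence(sequence)
  L <- nchar(sequence)
  pairs <- normalize_pairs(pairs)
  if (nrow(pairs)) {
    if (any(pairs < 1L) || any(pairs > L))
      stop("pair index out of range 1..", L)
    if (any(pairs[, 1L] >= pairs[, 2L]))
      stop("pairs must satisfy i < j")
    idx <- as.vector(pairs)
    if (anyDuplicated(idx))
      stop("a residue appears in more than one pair")
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  structure(
    list(name = as.character(name), sequence = sequence, pairs = pairs),
    class = "rna_structure"
  )
}

normalize_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("acgutn", "ACGUTN", sequence)
  s <- gsub("T", "U", s, fixed = TRUE)
  bad <- setdiff(unique(strsplit(s, "")[[1L]]), c("A", "C", "G", "U", "N"))
  if (length(bad))
    stop("illegal characters in sequence: ", paste(bad, collapse = ", "))
  s
}

normalize_pairs <- function(pairs) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0L) ||
      length(pairs) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  swap <- pairs[, 1L] > pairs[, 2L]
  pairs[swap, ] <- pairs[swap, 2:1]
  pairs
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> ", x$name, "\n", sep = "")
  cat("  length: ", nchar(x$sequence), " nt, ", nrow(x$pairs),
      " base pairs\n", sep = "")
  if (nchar(x$sequence) <= 80L) {
    cat("  ", x$sequence, "\n  ", dotbracket_string(x), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.rna_structure <- function(x) nchar(x$sequence)

#' Convert a structure to / from a binary pairing matrix
#'
#' `pairs_to_matrix()` builds the symmetric L-by-L 0/1 pairing matrix with 1 at
#' `(i, j)` and `(j, i)` for every base pair. `matrix_to_pairs()` is its exact
#' inverse, returning an `rna_structure` given the matrix and the sequence.
#'
#' @param s an `rna_structure`.
#' @return `pairs_to_matrix()`: an L-by-L integer matrix with zero diagonal and
#'   row sums in `{0, 1}`.
#' @export
pairs_to_matrix <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  L <- nchar(s$sequence)
  m <- matrix(0L, L, L)
  if (nrow(s$pairs)) {
    m[s$pairs] <- 1L
    m[s$pairs[, 2:1, drop = FALSE]] <- 1L
  }
  m
}

#' @rdname pairs_to_matrix
#' @param m symmetric binary pairing matrix.
#' @param sequence sequence of matching length.
#' @param name identifier for the resulting structure.
#' @export
matrix_to_pairs <- function(m, sequence, name = "structure") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nchar(sequence) == nrow(m))
  if (!isTRUE(all.equal(m, t(m)))) stop("pairing matrix must be symmetric")
  idx <- which(m != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  rna_structure(name, sequence, idx)
}

# partner vector: partner[i] = j if (i,j) paired, else NA
partner_vector <- function(s) {
  L <- nchar(s$sequence)
  p <- rep(NA_integer_, L)
  if (nrow(s$pairs)) {
    p[s$pairs[, 1L]] <- s$pairs[, 2L]
    p[s$pairs[, 2L]] <- s$pairs[, 1L]
  }
  p
}

# Greedy first-fit assignment of pairs to bracket layers so that no two pairs
# in one layer cross. Returns an integer layer index per pair.
assign_bracket_layers <- function(pairs) {
  n <- nrow(pairs)
  if (!n) return(integer(0))
  ord <- order(pairs[, 1L])
  layer <- integer(n)
  layers <- list()
  for (k in ord) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    placed <- FALSE
    for (l in seq_along(layers)) {
      members <- layers[[l]]
      crosses <- any((pairs[members, 1L] < i & i < pairs[members, 2L] &
                        pairs[members, 2L] < j) |
                       (i < pairs[members, 1L] & pairs[members, 1L] < j &
                          j < pairs[members, 2L]))
      if (!crosses) {
        layers[[l]] <- c(members, k)
        layer[k] <- l
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      layers[[length(layers) + 1L]] <- k
      layer[k] <- length(layers)
    }
  }
  layer
}

# bracket alphabets: four classic layers, then letter pairs (Aa, Bb, ...)
# for deeply crossing pair sets
bracket_open  <- c("(", "[", "{", "<", LETTERS)
bracket_close <- c(")", "]", "}", ">", letters)

dotbracket_string <- function(s) {
  L <- nchar(s$sequence)
  out <- rep(".", L)
  if (nrow(s$pairs)) {
    layer <- assign_bracket_layers(s$pairs)
    if (max(layer) > length(bracket_open))
      stop("structure needs more than ", length(bracket_open),
           " bracket layers")
    out[s$pairs[, 1L]] <- bracket_open[layer]
    out[s$pairs[, 2L]] <- bracket_close[layer]
  }
  paste(out, collapse = "")
}
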