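#' Structural constraints on a pairing-score grid
#'
#' Constraints a called structure must satisfy: no sharp loops (pairs with
#' `|i - j| < min_loop` are forbidden), one partner per nucleotide (always
#' enforced by [call_pairs()]), and optionally canonical pairs only
#' (AU/GC/GU).
#'
#' @param min_loop minimum sequence separation of a pair (default 4).
#' @param canonical_only zero non-canonical entries (default FALSE).
#' @param threshold probability above which a pair may be called
#'   (default 0.5).
#' @return object of class `constraint_spec`.
#' @export
constraint_spec <- function(min_loop = 4, canonical_only = FALSE,
                            threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1, min_loop >= 0)
  structure(list(min_loop = min_loop, canonical_only = canonical_only,
                 one_partner = TRUE, threshold = threshold),
            class = "constraint_spec")
}

is_canonical_matrix <- function(sequence) {
  ch <- strsplit(normalize_sequence(sequence), "")[[1L]]
  ok <- list(A = "U", U = c("A", "G"), G = c("C", "U"), C = "G", N = character(0))
  L <- length(ch)
  m <- matrix(FALSE, L, L)
  for (i in seq_len(L)) m[i, ] <- ch %in% ok[[ch[i]]]
  m
}

#' Constrain a score grid
#'
#' Symmetrizes the grid as `(S + t(S)) / 2`, zeroes entries with
#' `|i - j| < min_loop`, and (when `canonical_only`) zeroes entries whose
#' base combination is not AU/GC/GU. The result never exceeds the
#' symmetrized input element-wise.
#'
#' @param g numeric L-by-L score grid.
#' @param sequence sequence of matching length.
#' @param spec a [constraint_spec].
#' @return constrained grid of class `pair_score_grid`.
#' @export
apply_constraints <- function(g, sequence, spec = constraint_spec()) {
  g <- unclass(g)
  stopifnot(is.matrix(g), nrow(g) == ncol(g))
  if (nchar(sequence) != nrow(g))
    stop("grid/sequence shape mismatch")
  g <- (g + t(g)) / 2
  L <- nrow(g)
  sep <- abs(outer(seq_len(L), seq_len(L), `-`))
  g[sep < spec$min_loop] <- 0
  if (spec$canonical_only) g[!is_canonical_matrix(sequence)] <- 0
  structure(g, class = c("pair_score_grid", "matrix", "array"))
}

# descending-score greedy selection (ties lexicographic by (i, j));
# cand is already sorted; returns logical selection vector
greedy_select <- function(cand, L) {
  sel <- logical(nrow(cand))
  taken <- logical(L)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    if (!taken[i] && !taken[j]) {
      sel[r] <- TRUE
      taken[i] <- TRUE; taken[j] <- TRUE
    }
  }
  sel
}

# deterministic (1,2)-swap hill climbing on a matching: repeatedly replace one
# selected pair by up to two compatible unselected pairs when the total score
# strictly increases
local_improve <- function(cand, sc, sel, L) {
  repeat {
    taken <- logical(L)
    taken[as.vector(cand[sel, , drop = FALSE])] <- TRUE
    best_gain <- 1e-9; best <- NULL
    for (f in which(sel)) {
      uv <- cand[f, ]
      ok <- function(m) {
        all(!taken[cand[m, ]] | cand[m, ] %in% uv)
      }
      near <- which(!sel & (cand[, 1L] %in% uv | cand[, 2L] %in% uv))
      near <- near[vapply(near, ok, logical(1L))]
      for (a in near) {
        gain <- sc[a] - sc[f]
        if (gain > best_gain) { best_gain <- gain; best <- list(f = f, add = a) }
        for (b in near[near > a]) {
          if (length(intersect(cand[a, ], cand[b, ]))) next
          gain2 <- sc[a] + sc[b] - sc[f]
          if (gain2 > best_gain) {
            best_gain <- gain2; best <- list(f = f, add = c(a, b))
          }
        }
      }
    }
    if (is.null(best)) return(sel)
    sel[best$f] <- FALSE
    sel[best$add] <- TRUE
  }
}

# exact maximum-weight matching by depth-first branch and bound over the
# descending-sorted candidates; node_cap bounds the search deterministically
# (NULL return = cap exhausted)
bb_matching <- function(cand, sc, L, node_cap = 20000L) {
  n <- nrow(cand)
  suffix <- rev(cumsum(rev(sc)))
  best_total <- -1; best_sel <- NULL
  nodes <- 0L; capped <- FALSE
  taken <- logical(L)
  sel <- logical(n)
  recurse <- function(m, total) {
    nodes <<- nodes + 1L
    if (nodes > node_cap) { capped <<- TRUE; return() }
    if (total > best_total) { best_total <<- total; best_sel <<- sel }
    if (m > n || capped) return()
    if (total + suffix[m] <= best_total) return()  # bound
    for (k in m:n) {
      if (capped) return()
      if (total + suffix[k] <= best_total) return()
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (taken[i] || taken[j]) next
      taken[i] <<- TRUE; taken[j] <<- TRUE; sel[k] <<- TRUE
      recurse(k + 1L, total + sc[k])
      taken[i] <<- FALSE; taken[j] <<- FALSE; sel[k] <<- FALSE
    }
  }
  recurse(1L, 0)
  if (capped) NULL else best_sel
}

#' Call base pairs from a constrained grid
#'
#' Selects the set of base pairs with scores above the threshold that
#' maximizes the total called score subject to one partner per base:
#' candidates are visited in order of decreasing score (ties broken
#' lexicographically by `(i, j)`) and matched exactly by a deterministic
#' branch-and-bound; on grids with very many above-threshold entries the
#' matcher falls back to the same greedy-plus-local-improvement pass (with
#' near-binary network scores all three coincide). The result always
#' satisfies one-partner-per-base, and every called pair scores above the
#' threshold. No nesting constraint is imposed, so pseudoknots can be
#' called; `nested_only` additionally drops crossing pairs (keeping
#' higher-scoring ones) for consumers that require a nested structure.
#'
#' @param g constrained L-by-L score grid (see [apply_constraints()]).
#' @param spec a [constraint_spec].
#' @param sequence optional sequence for the returned structure (a run of
#'   `N`s is substituted when absent).
#' @param name identifier for the returned structure.
#' @param nested_only drop crossing pairs (default FALSE).
#' @return an [rna_structure].
#' @export
call_pairs <- function(g, spec = constraint_spec(), sequence = NULL,
                       name = "prediction", nested_only = FALSE) {
  g <- unclass(g)
  L <- nrow(g)
  if (is.null(sequence)) sequence <- paste(rep("N", L), collapse = "")
  cand <- which(upper.tri(g) & g > spec$threshold, arr.ind = TRUE)
  acc <- matrix(integer(0), ncol = 2L)
  if (nrow(cand)) {
    sc <- g[cand]
    ord <- order(-sc, cand[, 1L], cand[, 2L])
    cand <- cand[ord, , drop = FALSE]; sc <- sc[ord]
    sel <- greedy_select(cand, L)
    # exact matching only where the conflict graph is small enough for the
    # branch and bound to finish quickly; dense grids take the greedy path
    nvert <- length(unique(as.vector(cand)))
    exact <- if (nrow(cand) <= 48L && nvert <= 16L)
      bb_matching(cand, sc, L) else NULL
    sel <- if (!is.null(exact) && sum(sc[exact]) > sum(sc[sel])) exact
           else local_improve(cand, sc, sel, L)
    acc0 <- cand[sel, , drop = FALSE]
    # resort by score for the deterministic crossing filter
    acc0 <- acc0[order(-g[acc0], acc0[, 1L], acc0[, 2L]), , drop = FALSE]
    for (r in seq_len(nrow(acc0))) {
      i <- acc0[r, 1L]; j <- acc0[r, 2L]
      if (nested_only && nrow(acc)) {
        crosses <- any((acc[, 1L] < i & i < acc[, 2L] & acc[, 2L] < j) |
                         (i < acc[, 1L] & acc[, 1L] < j & j < acc[, 2L]))
        if (crosses) next
      }
      acc <- rbind(acc, c(i, j))
    }
  }
  rna_structure(name, sequence, acc)
}

#' @export
print.pair_score_grid <- function(x, ...) {
  cat("<pair_score_grid> ", nrow(x), "x", ncol(x),
      ", scores in [", sprintf("%.3f", min(x)), ", ",
      sprintf("%.3f", max(x)), "]\n", sep = "")
  invisible(x)
}
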