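# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own algorithms.

# AUROC by trapezoidal integration of the empirical ROC curve
roc_trapezoid <- function(score, positive) {
  ths <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0); fpr <- c(0)
  n1 <- sum(positive); n0 <- sum(!positive)
  for (th in ths) {
    called <- score >= th
    tpr <- c(tpr, sum(called & positive) / n1)
    fpr <- c(fpr, sum(called & !positive) / n0)
  }
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# exhaustive enumeration of all valid canonical structures of a short
# sequence; returns the maximum achievable score under the Nussinov weights
# minus the reactivity penalty, and one optimal pair set
bf_weights <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)
bf_enumerate <- function(seq, min_loop = 3, penalty = NULL) {
  ch <- strsplit(seq, "")[[1L]]
  L <- length(ch)
  if (is.null(penalty)) penalty <- rep(0, L)
  cand <- list()
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (j - i - 1 >= min_loop) {
      w <- bf_weights[paste0(ch[i], ch[j])]
      if (!is.na(w)) cand[[length(cand) + 1L]] <-
          c(i, j, unname(w) - penalty[i] - penalty[j])
    }
  }
  best <- list(score = 0, pairs = matrix(integer(0), ncol = 2L))
  crosses <- function(pairs, i, j) {
    if (!nrow(pairs)) return(FALSE)
    any((pairs[, 1L] < i & i < pairs[, 2L] & pairs[, 2L] < j) |
          (i < pairs[, 1L] & pairs[, 1L] < j & j < pairs[, 2L]))
  }
  recurse <- function(k, used, score, pairs) {
    if (score > best$score) best <<- list(score = score, pairs = pairs)
    if (k > length(cand)) return()
    for (m in k:length(cand)) {
      p <- cand[[m]]
      if (!used[p[1L]] && !used[p[2L]] &&
          !crosses(pairs, p[1L], p[2L])) {  # nested structures only
        u2 <- used; u2[p[1L]] <- TRUE; u2[p[2L]] <- TRUE
        recurse(m + 1L, u2, score + p[3L], rbind(pairs, p[1:2]))
      }
    }
  }
  recurse(1L, rep(FALSE, L), 0, matrix(integer(0), ncol = 2L))
  best
}

# exact maximum-weight matching over above-threshold grid entries by
# exhaustive recursion (small instances only)
bf_max_matching <- function(g, threshold, min_loop = 0) {
  L <- nrow(g)
  cand <- which(upper.tri(g) & g > threshold, arr.ind = TRUE)
  if (min_loop > 0)
    cand <- cand[abs(cand[, 1L] - cand[, 2L]) >= min_loop, , drop = FALSE]
  best <- 0
  recurse <- function(k, used, total) {
    if (total > best) best <<- total
    if (k > nrow(cand)) return()
    for (m in k:nrow(cand)) {
      i <- cand[m, 1L]; j <- cand[m, 2L]
      if (!used[i] && !used[j]) {
        u2 <- used; u2[i] <- TRUE; u2[j] <- TRUE
        recurse(m + 1L, u2, total + g[i, j])
      }
    }
  }
  if (nrow(cand)) recurse(1L, rep(FALSE, L), 0)
  best
}

# random nested (pseudoknot-free) structure over a random sequence
random_nested_structure <- function(L, name = "rand", p_pair = 0.6,
                                    min_loop = 3) {
  seq <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
  pairs <- matrix(integer(0), ncol = 2L)
  build <- function(a, b) {
    while (a < b) {
      if (b - a - 1 >= min_loop && stats::runif(1) < p_pair) {
        pairs <<- rbind(pairs, c(a, b))
        inner_a <- a + 1L; inner_b <- b - 1L
        build(inner_a, inner_b)
        return(invisible(NULL))
      }
      a <- a + 1L
    }
    invisible(NULL)
  }
  # several independent stems side by side
  cuts <- sort(sample(seq_len(L), size = min(3L, max(1L, L %/% 12L))))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, L)
  for (k in seq_along(starts))
    if (ends[k] - starts[k] > min_loop + 1L) build(starts[k], ends[k])
  rna_structure(name, seq, pairs)
}

# a probed record with explicit per-base values (A/C everywhere by default
# so nothing is masked by base identity)
make_profile <- function(coverage, mutations = NULL, reactivity = NULL) {
  if (is.null(mutations)) mutations <- round(coverage * 0.01)
  reactivity_profile(coverage, mutations, reactivity)
}

tiny_efold_config <- function(...) {
  base <- list(seq_dim = 16, n_blocks = 2, attn_heads = 4, relpos_max = 8,
               ff_dim = 24, conv_hidden = 24, conv_kernel = 3,
               seq_trans_dim = 12, outer_dim = 6, resnet_hidden = 8,
               pair_trans_dim = 10, head_dim = 10, head_hidden = 8)
  do.call(efold_config, utils::modifyList(base, list(...)))
}
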