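#' Closed boundaries of a structure
#'
#' A cut position `c` (number of residues in the left part, so
#' `c = 1 .. L-1`) is closed when no base pair `(i, j)` spans it, i.e. no
#' pair has `i <= c < j`. Fragments cut only at closed boundaries inherit a
#' self-contained piece of the parent structure. All pairs, including
#' pseudoknotted ones, block cuts.
#'
#' @param s an [rna_structure].
#' @return sorted integer vector of closed cut positions (possibly empty;
#'   the endpoints 0 and L are implicit and never returned).
#' @export
find_closed_boundaries <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  L <- nchar(s$sequence)
  if (L < 2L) return(integer(0))
  open <- integer(L)  # open[c] = number of pairs with i <= c < j
  if (nrow(s$pairs)) {
    d <- integer(L + 1L)
    d[s$pairs[, 1L]] <- d[s$pairs[, 1L]] + 1L
    d[s$pairs[, 2L]] <- d[s$pairs[, 2L]] - 1L
    open <- cumsum(d[seq_len(L)])
  }
  which(open[seq_len(L - 1L)] == 0L)
}

#' Fragment records from long-structure segmentation
#'
#' @param parent parent identifier.
#' @param span 2-vector `c(start, end)`: 1-based inclusive residue range.
#' @param sequence fragment sequence slice.
#' @param restricted_pairs parent pairs inside the span, reindexed to
#'   fragment coordinates.
#' @param profile optional sliced [reactivity_profile].
#' @return object of class `fragment_record`.
#' @export
fragment_record <- function(parent, span, sequence, restricted_pairs,
                            profile = NULL) {
  structure(
    list(parent = parent, span = span, sequence = sequence,
         restricted = rna_structure(sprintf("%s_%d_%d", parent, span[1L],
                                            span[2L]),
                                    sequence, restricted_pairs),
         profile = profile, refolded = NULL, auroc = NA_real_,
         f1_vs_parent = NA_real_, retained = NA),
    class = "fragment_record"
  )
}

#' @export
print.fragment_record <- function(x, ...) {
  cat("<fragment_record> ", x$parent, " [", x$span[1L], ", ", x$span[2L],
      "] (", nchar(x$sequence), " nt, ", nrow(x$restricted$pairs),
      " pairs)", sep = "")
  if (!is.na(x$retained))
    cat(sprintf("  auroc=%.3f f1=%.3f %s", x$auroc, x$f1_vs_parent,
                if (x$retained) "retained" else "dropped"))
  cat("\n")
  invisible(x)
}

slice_profile <- function(p, a, b) {
  if (is.null(p)) return(NULL)
  idx <- seq.int(a, b)
  reactivity_profile(coverage = p$coverage[idx], mutations = p$mutations[idx],
                     reactivity = p$reactivity[idx],
                     normalized = if (is.null(p$normalized)) NULL else p$normalized[idx],
                     mask_sentinel = p$mask_sentinel)
}

#' Segment a long probed record into modular fragments
#'
#' Greedy left-to-right placement of cuts at closed boundaries so that
#' fragment lengths fall within `[min_len, max_len]` where feasible, never
#' exceeding `hard_max`. Among admissible cuts the one closest to the
#' midpoint of the target window is chosen (ties to the smaller cut). When no
#' closed boundary lies in the window, the nearest closed boundary beyond it
#' (up to `hard_max`) is used; failing that, the nearest one before it; a
#' stretch with no usable boundary at all is emitted whole with a warning.
#' Records no longer than `max_len` are returned as a single fragment.
#'
#' @param rec a [probed_record] with a structure model (profile optional),
#'   or an [rna_structure].
#' @param min_len,max_len target fragment length window (defaults 150, 300).
#' @param hard_max absolute fragment length ceiling (default 2000).
#' @return list of [fragment_record]s covering the record.
#' @export
segment_long_record <- function(rec, min_len = 150, max_len = 300,
                                hard_max = 2000) {
  if (inherits(rec, "rna_structure"))
    rec <- list(name = rec$name, sequence = rec$sequence, structure = rec,
                merged = NULL)
  s <- rec$structure
  if (is.null(s)) stop("record has no structure to segment")
  profile <- rec$merged
  L <- nchar(s$sequence)
  bounds <- find_closed_boundaries(s)
  cuts <- integer(0)
  start <- 0L  # residues consumed
  while (L - start > max_len) {
    cand <- bounds[bounds > start]
    window <- cand[cand - start >= min_len & cand - start <= max_len]
    if (length(window)) {
      # one-step lookahead: prefer cuts whose remainder can still be
      # segmented (or needs no further cut), then the midpoint-closest
      feasible <- vapply(window, function(b) {
        L - b <= max_len ||
          any(bounds > b & bounds - b >= min_len & bounds - b <= max_len)
      }, logical(1L))
      if (any(feasible)) window <- window[feasible]
      mid <- start + (min_len + max_len) / 2
      cut <- window[which.min(abs(window - mid))]
    } else {
      beyond <- cand[cand - start > max_len & cand - start <= hard_max]
      before <- cand[cand - start < min_len]
      if (length(beyond)) {
        cut <- beyond[1L]
        warning("no closed boundary in [", min_len, ", ", max_len,
                "] after position ", start, "; cutting at ", cut)
      } else if (length(before)) {
        cut <- before[length(before)]
        warning("no closed boundary within hard_max after position ", start,
                "; falling back to last closed boundary at ", cut)
      } else {
        warning("record ", rec$name, " unsegmentable after position ", start)
        break
      }
    }
    cuts <- c(cuts, cut)
    start <- cut
  }
  spans <- cbind(c(1L, cuts + 1L), c(cuts, L))
  lapply(seq_len(nrow(spans)), function(k) {
    a <- spans[k, 1L]; b <- spans[k, 2L]
    inside <- s$pairs[, 1L] >= a & s$pairs[, 2L] <= b
    rp <- s$pairs[inside, , drop = FALSE]
    rp[] <- rp - a + 1L
    fragment_record(rec$name, c(a, b),
                    substr(s$sequence, a, b), rp,
                    slice_profile(profile, a, b))
  })
}

#' Validate a fragment by refolding
#'
#' Refolds the fragment's sequence with its sliced probing signal through the
#' supplied engine, then scores the refolded model against the signal (AUROC)
#' and against the parent's restricted pairs (F1). The fragment is retained
#' when both exceed `cfg$min_auroc` (0.8 by default).
#'
#' @param f a [fragment_record] with a profile.
#' @param engine folding engine `function(sequence, profile)`; default the
#'   bundled Nussinov engine.
#' @param cfg a [qc_config] supplying the AUROC/F1 threshold.
#' @return the fragment with `refolded`, `auroc`, `f1_vs_parent` and
#'   `retained` filled in.
#' @export
validate_fragment <- function(f, engine = nussinov_engine(),
                              cfg = qc_config()) {
  stopifnot(inherits(f, "fragment_record"))
  if (is.null(f$profile)) stop("fragment has no probing profile")
  refolded <- tryCatch(engine(f$sequence, f$profile),
                       error = function(e) stop("engine failed on fragment ",
                                                f$restricted$name, ": ",
                                                conditionMessage(e)))
  f$refolded <- refolded
  f$auroc <- auroc(refolded, f$profile)
  f$f1_vs_parent <- pair_prf(refolded, f$restricted)$f1
  f$retained <- f$auroc > cfg$min_auroc & f$f1_vs_parent > cfg$min_auroc
  f
}
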