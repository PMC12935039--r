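#' Base-pair precision, recall and F1
#'
#' Compares two structure models over the same sequence by exact `(i, j)`
#' base-pair matches (no slip tolerance; pseudoknotted pairs count as
#' ordinary pairs). F1 is the harmonic mean of precision and sensitivity.
#' Degenerate conventions: both pair sets empty gives F1 = 1; exactly one
#' empty gives F1 = 0; a precision or recall with zero denominator is treated
#' as 0 inside F1.
#'
#' @param predicted,reference [rna_structure] objects of equal length.
#' @return a list of class `prf_result` with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
pair_prf <- function(predicted, reference) {
  stopifnot(inherits(predicted, "rna_structure"),
            inherits(reference, "rna_structure"))
  if (nchar(predicted$sequence) != nchar(reference$sequence))
    stop("structures have different lengths")
  pk <- pair_keys(predicted$pairs)
  rk <- pair_keys(reference$pairs)
  tp <- length(intersect(pk, rk))
  fp <- length(setdiff(pk, rk))
  fn <- length(setdiff(rk, pk))
  if (tp + fp + fn == 0L) {
    prec <- 1; rec <- 1; f1 <- 1
  } else {
    prec <- if (tp + fp > 0L) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = prec, recall = rec, f1 = f1),
            class = "prf_result")
}

pair_keys <- function(pairs) {
  if (!nrow(pairs)) return(character(0))
  paste(pairs[, 1L], pairs[, 2L], sep = ":")
}

#' @export
print.prf_result <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d fn=%d  precision=%.3f recall=%.3f F1=%.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Structure-vs-probing AUROC
#'
#' Area under the ROC curve of reactivity as a classifier separating unpaired
#' (positive class) from paired (negative class) bases, computed as the
#' Mann-Whitney statistic `U / (n1 * n0)` with tied scores counted 0.5.
#' Masked bases are excluded; the statistic is rank-based and therefore
#' invariant to any strictly monotone transform of the reactivities, so raw
#' and normalized profiles give the same value.
#'
#' @param structure an [rna_structure].
#' @param profile a [reactivity_profile] of matching length.
#' @return AUROC in `[0, 1]`. Errors when either class is empty after
#'   masking.
#' @export
auroc <- function(structure, profile) {
  stopifnot(inherits(structure, "rna_structure"),
            inherits(profile, "reactivity_profile"))
  L <- nchar(structure$sequence)
  if (length(profile$coverage) != L)
    stop("profile length does not match structure")
  slot <- if (!is.null(profile$normalized)) "normalized" else "reactivity"
  vals <- if (slot == "normalized") profile$normalized else profile$reactivity
  masked <- is_masked(profile, slot)
  unpaired <- is.na(partner_vector(structure))
  use <- !masked
  score <- vals[use]
  pos <- unpaired[use]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: one class empty after masking")
  r <- rank(score)  # average ranks handle ties as 0.5
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Aggregate per-structure metrics
#'
#' Averages precision, recall and F1 across structures by first computing
#' each metric per structure and then taking the unweighted arithmetic mean
#' (not pooled counts, which weight large structures more).
#'
#' @param results nonempty list of `prf_result` objects.
#' @return list with mean `precision`, `recall`, `f1`, and `n`.
#' @export
aggregate_metrics <- function(results) {
  stopifnot(length(results) >= 1L)
  list(precision = mean(vapply(results, `[[`, numeric(1L), "precision")),
       recall = mean(vapply(results, `[[`, numeric(1L), "recall")),
       f1 = mean(vapply(results, `[[`, numeric(1L), "f1")),
       n = length(results))
}
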