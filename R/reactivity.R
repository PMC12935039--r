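#' Per-base chemical reactivity profiles
#'
#' A `reactivity_profile` carries, for every base of a reference, the read
#' coverage, the mutated-read count, the raw mutation fraction
#' (`mutations / coverage`) and, once computed, the normalized reactivity in
#' `[0, 1]`. Masked entries (low coverage, G/U bases, primer regions) carry the
#' sentinel value `-1000` in the `reactivity`/`normalized` slots and are
#' excluded from every downstream statistic.
#'
#' @param coverage integer vector of reads per base.
#' @param mutations integer vector of mutated-read counts per base.
#' @param reactivity optional raw reactivity; computed as
#'   `mutations / coverage` when missing.
#' @param normalized optional normalized reactivity.
#' @param mask_sentinel sentinel marking masked entries (default -1000).
#' @return an object of class `reactivity_profile`.
#' @export
reactivity_profile <- function(coverage, mutations, reactivity = NULL,
                               normalized = NULL, mask_sentinel = -1000) {
  coverage <- as.numeric(coverage)
  mutations <- as.numeric(mutations)
  stopifnot(length(coverage) == length(mutations))
  if (any(mutations > coverage, na.rm = TRUE))
    stop("mutations cannot exceed coverage")
  if (is.null(reactivity)) {
    reactivity <- ifelse(coverage > 0, mutations / coverage, NA_real_)
  }
  stopifnot(length(reactivity) == length(coverage))
  if (!is.null(normalized)) stopifnot(length(normalized) == length(coverage))
  structure(
    list(coverage = coverage, mutations = mutations,
         reactivity = as.numeric(reactivity),
         normalized = if (is.null(normalized)) NULL else as.numeric(normalized),
         mask_sentinel = mask_sentinel),
    class = "reactivity_profile"
  )
}

#' @export
length.reactivity_profile <- function(x) length(x$coverage)

#' @export
print.reactivity_profile <- function(x, ...) {
  n <- length(x$coverage)
  masked <- sum(is_masked(x))
  cat("<reactivity_profile> ", n, " bases (", masked, " masked), ",
      "median coverage ", stats::median(x$coverage), "\n", sep = "")
  invisible(x)
}

#' Which profile entries are masked?
#'
#' @param p a [reactivity_profile].
#' @param slot which values to test: raw `reactivity` or `normalized`.
#' @return logical vector, `TRUE` where the entry carries the mask sentinel or
#'   is `NA`.
#' @export
is_masked <- function(p, slot = c("reactivity", "normalized")) {
  slot <- match.arg(slot)
  v <- if (slot == "normalized" && !is.null(p$normalized)) p$normalized else p$reactivity
  is.na(v) | v == p$mask_sentinel
}

# values with masked entries dropped
unmasked_values <- function(p, slot = "reactivity") {
  v <- if (slot == "normalized" && !is.null(p$normalized)) p$normalized else p$reactivity
  v[!is_masked(p, if (slot == "normalized" && !is.null(p$normalized)) "normalized" else "reactivity")]
}

#' Probed sequence records
#'
#' A `probed_record` joins a reference sequence to one or more replicate
#' [reactivity_profile]s, an optional merged profile, an optional structure
#' model, QC flags, and primer intervals (1-based inclusive start, exclusive
#' end, i.e. half-open).
#'
#' @param name reference identifier.
#' @param sequence reference sequence.
#' @param replicates list of [reactivity_profile]s, all of the sequence length.
#' @param merged optional merged profile.
#' @param structure optional [rna_structure].
#' @param qc_flags character vector drawn from
#'   `low_coverage, low_replicate_correlation, high_untreated_mutation, low_auroc`.
#' @param primer_spans list of 2-vectors `c(start, end)` (half-open, 1-based).
#' @return an object of class `probed_record`.
#' @export
probed_record <- function(name, sequence, replicates, merged = NULL,
                          structure = NULL, qc_flags = character(0),
                          primer_spans = list()) {
  sequence <- normalize_sequence(sequence)
  L <- nchar(sequence)
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  for (p in replicates) {
    stopifnot(inherits(p, "reactivity_profile"))
    if (length(p$coverage) != L)
      stop("replicate length ", length(p$coverage),
           " does not match sequence length ", L)
  }
  bad <- setdiff(qc_flags, qc_flag_vocabulary)
  if (length(bad))
    stop("unknown qc flags: ", paste(bad, collapse = ", "))
  for (sp in primer_spans) {
    if (sp[1L] < 1L || sp[2L] > L + 1L || sp[1L] >= sp[2L])
      stop("primer span outside sequence bounds")
  }
  structure(
    list(name = as.character(name), sequence = sequence,
         replicates = replicates, merged = merged, structure = structure,
         qc_flags = unique(qc_flags), primer_spans = primer_spans),
    class = "probed_record"
  )
}

qc_flag_vocabulary <- c("low_coverage", "low_replicate_correlation",
                        "high_untreated_mutation", "low_auroc")

#' @export
print.probed_record <- function(x, ...) {
  cat("<probed_record> ", x$name, ": ", nchar(x$sequence), " nt, ",
      length(x$replicates), " replicate(s)",
      if (!is.null(x$merged)) ", merged" else "",
      if (!is.null(x$structure)) ", structure" else "", "\n", sep = "")
  if (length(x$qc_flags))
    cat("  flags: ", paste(x$qc_flags, collapse = ", "), "\n", sep = "")
  invisible(x)
}

add_flag <- function(rec, flag) {
  rec$qc_flags <- unique(c(rec$qc_flags, flag))
  rec
}
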