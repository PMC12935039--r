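#' QC configuration for the reactivity filtering pipeline
#'
#' Thresholds of the DMS data processing and filtering pipeline. Defaults are
#' the stringent settings used for in-house probing libraries; see
#' [ribonanza_qc_config()] for the public-database preset.
#'
#' @param min_reads minimum aligned reads, and per-base coverage threshold for
#'   masking (default 3000).
#' @param min_covered_fraction minimum fraction of bases with coverage at
#'   least `min_reads` (default 0.5).
#' @param min_replicate_pearson replicate gate on Pearson correlation
#'   (default 0.8).
#' @param untreated_rate_ceiling mutation-rate ceiling above which a base
#'   suggests a wrong reference (default 0.3).
#' @param norm_percentile percentile used as the normalization maximum
#'   (default 95).
#' @param mask_sentinel sentinel for masked entries (default -1000).
#' @param min_auroc structure-vs-signal AUROC retention threshold
#'   (default 0.8).
#' @param min_signal_to_noise minimum signal-to-noise ratio (mean reactivity of
#'   A/C over G/U bases); `NA` disables the check (used only by the
#'   public-database preset).
#' @param bootstrap_draws number of binomial bootstrap replicates (default 10).
#' @param rng_seed seed for the bootstrap draws.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(min_reads = 3000, min_covered_fraction = 0.5,
                      min_replicate_pearson = 0.8,
                      untreated_rate_ceiling = 0.3,
                      norm_percentile = 95, mask_sentinel = -1000,
                      min_auroc = 0.8, min_signal_to_noise = NA,
                      bootstrap_draws = 10, rng_seed = 1L) {
  stopifnot(min_reads >= 0,
            min_covered_fraction >= 0, min_covered_fraction <= 1,
            min_replicate_pearson >= -1, min_replicate_pearson <= 1,
            untreated_rate_ceiling >= 0, untreated_rate_ceiling <= 1,
            norm_percentile > 0, norm_percentile <= 100,
            min_auroc >= 0, min_auroc <= 1,
            bootstrap_draws >= 1)
  structure(as.list(environment()), class = "qc_config")
}

#' @describeIn qc_config Preset mirroring public-database curation: more than
#'   500 reads and signal-to-noise ratio greater than 1.
#' @export
ribonanza_qc_config <- function() {
  qc_config(min_reads = 500, min_signal_to_noise = 1)
}

#' Coverage filter
#'
#' Drops a record if its total aligned reads fall below `min_reads` or if
#' fewer than `min_covered_fraction` of bases have coverage of at least
#' `min_reads`. Total aligned reads are taken as the maximum per-base coverage
#' (every aligned read covers its best-covered base at most once).
#'
#' @param rec a [probed_record].
#' @param cfg a [qc_config].
#' @return a list with `keep` (logical), `reason` (`NA` or a string), and
#'   `record` (the input, flagged `low_coverage` when dropped).
#' @export
filter_coverage <- function(rec, cfg = qc_config()) {
  stopifnot(inherits(rec, "probed_record"), inherits(cfg, "qc_config"))
  p <- rec$replicates[[1L]]
  if (!length(p$coverage)) stop("empty profile")
  total_reads <- max(p$coverage)
  frac <- mean(p$coverage >= cfg$min_reads)
  keep <- TRUE; reason <- NA_character_
  if (total_reads < cfg$min_reads) {
    keep <- FALSE
    reason <- sprintf("total aligned reads %d < %d", as.integer(total_reads),
                      as.integer(cfg$min_reads))
  } else if (frac < cfg$min_covered_fraction) {
    keep <- FALSE
    reason <- sprintf("only %.0f%% of bases covered at >= %d reads",
                      100 * frac, as.integer(cfg$min_reads))
  }
  if (!keep) rec <- add_flag(rec, "low_coverage")
  list(keep = keep, reason = reason, record = rec)
}

#' Mask unreliable bases
#'
#' Sets the reactivity of every base that is G or U, has coverage below
#' `min_reads`, or lies in a primer span to the mask sentinel, in every
#' replicate. All other entries are untouched.
#'
#' @inheritParams filter_coverage
#' @return the record with masked replicate profiles.
#' @export
mask_profile <- function(rec, cfg = qc_config()) {
  stopifnot(inherits(rec, "probed_record"))
  L <- nchar(rec$sequence)
  base <- strsplit(rec$sequence, "")[[1L]]
  in_primer <- rep(FALSE, L)
  for (sp in rec$primer_spans) {
    if (sp[1L] < 1L || sp[2L] > L + 1L) stop("primer span outside sequence")
    in_primer[seq.int(sp[1L], sp[2L] - 1L)] <- TRUE
  }
  rec$replicates <- lapply(rec$replicates, function(p) {
    if (length(p$coverage) != L) stop("profile length mismatch")
    mask <- base %in% c("G", "U") | p$coverage < cfg$min_reads | in_primer
    p$reactivity[mask] <- cfg$mask_sentinel
    if (!is.null(p$normalized)) p$normalized[mask] <- cfg$mask_sentinel
    p$mask_sentinel <- cfg$mask_sentinel
    p
  })
  if (!is.null(rec$merged)) {
    mask <- base %in% c("G", "U") | rec$merged$coverage < cfg$min_reads | in_primer
    rec$merged$reactivity[mask] <- cfg$mask_sentinel
    if (!is.null(rec$merged$normalized))
      rec$merged$normalized[mask] <- cfg$mask_sentinel
  }
  rec
}

#' Replicate correlation gate and averaging
#'
#' Pearson correlation is computed on raw reactivities at positions unmasked
#' in both replicates. A single replicate passes through unchanged. When any
#' pairwise correlation falls below the threshold the record is rejected with
#' flag `low_replicate_correlation`; otherwise the merged profile is the
#' element-wise mean of unmasked values (masked wherever any replicate is
#' masked), with coverage and mutation counts summed across replicates.
#'
#' @inheritParams filter_coverage
#' @return a list with `keep`, `pearson` (vector of pairwise correlations, or
#'   `NULL` for a single replicate) and `record` (with `merged` set when kept).
#' @export
merge_replicates <- function(rec, cfg = qc_config()) {
  stopifnot(inherits(rec, "probed_record"))
  reps <- rec$replicates
  if (length(reps) == 1L) {
    rec$merged <- reps[[1L]]
    return(list(keep = TRUE, pearson = NULL, record = rec))
  }
  combos <- utils::combn(length(reps), 2L)
  r <- apply(combos, 2L, function(idx) {
    a <- reps[[idx[1L]]]; b <- reps[[idx[2L]]]
    ok <- !is_masked(a) & !is_masked(b)
    if (sum(ok) < 3L)
      stop("fewer than 3 jointly unmasked positions; correlation undefined")
    stats::cor(a$reactivity[ok], b$reactivity[ok])
  })
  if (any(r < cfg$min_replicate_pearson)) {
    rec <- add_flag(rec, "low_replicate_correlation")
    return(list(keep = FALSE, pearson = r, record = rec))
  }
  masked <- Reduce(`|`, lapply(reps, is_masked))
  react <- rowMeans(do.call(cbind, lapply(reps, `[[`, "reactivity")))
  react[masked] <- cfg$mask_sentinel
  merged <- reactivity_profile(
    coverage = Reduce(`+`, lapply(reps, `[[`, "coverage")),
    mutations = Reduce(`+`, lapply(reps, `[[`, "mutations")),
    reactivity = react, mask_sentinel = cfg$mask_sentinel)
  rec$merged <- merged
  list(keep = TRUE, pearson = r, record = rec)
}

#' Percentile normalization
#'
#' Divides unmasked reactivities by their `norm_percentile`-th percentile
#' (linear interpolation between order statistics) and clips values above the
#' divisor to 1. Masked entries keep the sentinel.
#'
#' @param p a [reactivity_profile].
#' @param cfg a [qc_config].
#' @return the profile with its `normalized` slot filled.
#' @export
normalize_profile <- function(p, cfg = qc_config()) {
  stopifnot(inherits(p, "reactivity_profile"))
  masked <- is_masked(p)
  vals <- p$reactivity[!masked]
  if (!length(vals)) stop("no unmasked values to normalize")
  if (any(vals < 0)) stop("unmasked reactivities must be nonnegative")
  divisor <- stats::quantile(vals, cfg$norm_percentile / 100, type = 7,
                             names = FALSE)
  if (divisor == 0) stop("normalization divisor is zero (all unmasked values zero)")
  norm <- pmin(p$reactivity / divisor, 1)
  norm[masked] <- cfg$mask_sentinel
  p$normalized <- norm
  p
}

#' Flag abnormally high mutation rates
#'
#' Mutation rates above `untreated_rate_ceiling` in the untreated control
#' (or, when no control is available, in the treated profile — a weaker check)
#' suggest an inaccurate reference sequence; such records are flagged
#' `high_untreated_mutation` for discard.
#'
#' @param treated treated-sample [reactivity_profile].
#' @param untreated optional untreated control profile.
#' @param cfg a [qc_config].
#' @return a list with `flagged` (logical) and `positions` (indices over the
#'   ceiling).
#' @export
flag_mutation_anomaly <- function(treated, untreated = NULL,
                                  cfg = qc_config()) {
  p <- if (!is.null(untreated)) untreated else treated
  rate <- ifelse(p$coverage > 0, p$mutations / p$coverage, 0)
  pos <- which(rate > cfg$untreated_rate_ceiling)
  list(flagged = length(pos) > 0L, positions = pos)
}

#' Binomial bootstrap of a reactivity profile
#'
#' Models the mutation fraction at each unmasked base as
#' `Binomial(coverage, rate) / coverage` and draws `bootstrap_draws`
#' resampled profiles; masked bases keep the sentinel. Reproducible under
#' `cfg$rng_seed`.
#'
#' @inheritParams normalize_profile
#' @return list of `bootstrap_draws` [reactivity_profile]s.
#' @export
bootstrap_profiles <- function(p, cfg = qc_config()) {
  stopifnot(inherits(p, "reactivity_profile"))
  masked <- is_masked(p)
  if (any(!masked & p$coverage == 0))
    stop("unmasked base with zero coverage")
  set.seed(cfg$rng_seed)
  rate <- ifelse(masked, 0, p$mutations / pmax(p$coverage, 1))
  lapply(seq_len(cfg$bootstrap_draws), function(d) {
    draw <- stats::rbinom(length(rate), size = p$coverage, prob = rate) /
      pmax(p$coverage, 1)
    draw[masked] <- cfg$mask_sentinel
    reactivity_profile(coverage = p$coverage,
                       mutations = round(draw * p$coverage),
                       reactivity = draw, mask_sentinel = cfg$mask_sentinel)
  })
}

#' AUROC retention filter
#'
#' Computes the AUROC between the record's structure model and its merged
#' (preferably normalized) profile via [auroc()]; records with AUROC below
#' `min_auroc` are dropped and flagged `low_auroc`.
#'
#' @inheritParams filter_coverage
#' @return list with `keep`, `auroc`, and `record`.
#' @export
filter_by_auroc <- function(rec, cfg = qc_config()) {
  stopifnot(inherits(rec, "probed_record"))
  if (is.null(rec$structure)) stop("record has no structure model")
  p <- if (!is.null(rec$merged)) rec$merged else rec$replicates[[1L]]
  a <- auroc(rec$structure, p)
  keep <- a >= cfg$min_auroc
  if (!keep) rec <- add_flag(rec, "low_auroc")
  list(keep = keep, auroc = a, record = rec)
}

signal_to_noise <- function(rec) {
  base <- strsplit(rec$sequence, "")[[1L]]
  p <- rec$replicates[[1L]]
  rate <- ifelse(p$coverage > 0, p$mutations / p$coverage, NA_real_)
  ac <- mean(rate[base %in% c("A", "C")], na.rm = TRUE)
  gu <- mean(rate[base %in% c("G", "U")], na.rm = TRUE)
  if (!is.finite(gu) || gu == 0) return(Inf)
  ac / gu
}

#' Run the full QC/filtering pipeline
#'
#' Fixed order: coverage filter, mutation-anomaly check, masking, replicate
#' gate and merge, percentile normalization, optional folding through
#' `engine`, and the AUROC retention filter (applied when a structure is
#' available). Re-running the pipeline on its own kept records reproduces
#' them.
#'
#' @param records list of [probed_record]s.
#' @param cfg a [qc_config].
#' @param engine optional folding engine, a
#'   `function(sequence, profile) -> rna_structure`, used to model records
#'   that carry no structure (see [nussinov_engine()]).
#' @param untreated optional named list of untreated control profiles.
#' @return list with `kept` (processed records) and `report` (one row per
#'   input record: decision and reason).
#' @export
qc_pipeline <- function(records, cfg = qc_config(), engine = NULL,
                        untreated = NULL) {
  report <- data.frame(reference = character(0), kept = logical(0),
                       stage = character(0), detail = character(0),
                       auroc = numeric(0), stringsAsFactors = FALSE)
  kept <- list()
  for (rec in records) {
    row <- data.frame(reference = rec$name, kept = FALSE, stage = NA_character_,
                      detail = NA_character_, auroc = NA_real_,
                      stringsAsFactors = FALSE)
    cov <- filter_coverage(rec, cfg)
    if (!cov$keep) {
      row$stage <- "coverage"; row$detail <- cov$reason
      report <- rbind(report, row); next
    }
    rec <- cov$record
    ut <- if (!is.null(untreated)) untreated[[rec$name]] else NULL
    anom <- flag_mutation_anomaly(rec$replicates[[1L]], ut, cfg)
    if (anom$flagged) {
      row$stage <- "mutation_anomaly"
      row$detail <- paste("rate >", cfg$untreated_rate_ceiling, "at",
                          paste(utils::head(anom$positions, 5L), collapse = ","))
      report <- rbind(report, row); next
    }
    if (!is.na(cfg$min_signal_to_noise) &&
        signal_to_noise(rec) <= cfg$min_signal_to_noise) {
      row$stage <- "signal_to_noise"; row$detail <- "S/N below threshold"
      report <- rbind(report, row); next
    }
    rec <- mask_profile(rec, cfg)
    mg <- merge_replicates(rec, cfg)
    if (!mg$keep) {
      row$stage <- "replicate_correlation"
      row$detail <- paste("pearson", paste(round(mg$pearson, 3), collapse = ","))
      report <- rbind(report, row); next
    }
    rec <- mg$record
    rec$merged <- normalize_profile(rec$merged, cfg)
    if (is.null(rec$structure) && !is.null(engine)) {
      rec$structure <- engine(rec$sequence, rec$merged)
    }
    if (!is.null(rec$structure)) {
      au <- filter_by_auroc(rec, cfg)
      row$auroc <- au$auroc
      if (!au$keep) {
        row$stage <- "auroc"
        row$detail <- paste("auroc", round(au$auroc, 3))
        report <- rbind(report, row); next
      }
      rec <- au$record
    }
    row$kept <- TRUE; row$stage <- "kept"
    report <- rbind(report, row)
    kept[[rec$name]] <- rec
  }
  list(kept = kept, report = report)
}
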