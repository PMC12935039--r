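#' Simulation configuration
#'
#' Settings for the synthetic-data generator. Defaults emulate the probing
#' conditions the QC pipeline assumes: 3000 reads per base and a two-class
#' DMS signal whose A/C mutation-rate means are 0.006 at paired bases and
#' 0.03 at unpaired bases.
#'
#' @param n_records number of molecules to simulate.
#' @param length_range 2-vector, inclusive range of sequence lengths.
#' @param gc_content expected G+C fraction in `[0, 1]`.
#' @param reads_per_base mean read coverage (default 3000).
#' @param paired_ac_rate mean mutation rate of paired A/C bases
#'   (default 0.006).
#' @param unpaired_ac_rate mean mutation rate of unpaired A/C bases
#'   (default 0.03).
#' @param rate_dispersion coefficient of variation of the per-base true
#'   rates, drawn from a moment-matched Beta distribution (default 0.3).
#' @param replicate_noise multiplicative log-normal jitter (sdlog) applied to
#'   each replicate's true rates (default 0.05).
#' @param seed RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_records = 10, length_range = c(80, 160),
                       gc_content = 0.5, reads_per_base = 3000,
                       paired_ac_rate = 0.006, unpaired_ac_rate = 0.03,
                       rate_dispersion = 0.3, replicate_noise = 0.05,
                       seed = 1L) {
  stopifnot(paired_ac_rate >= 0, paired_ac_rate < unpaired_ac_rate,
            unpaired_ac_rate <= 1,
            gc_content >= 0, gc_content <= 1,
            length_range[1L] <= length_range[2L], length_range[1L] >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate random RNA sequences
#'
#' Lengths are uniform over `length_range`; bases are i.i.d. with G and C
#' probability `gc_content / 2` each and A and U probability
#' `(1 - gc_content) / 2` each. Seeded and reproducible.
#'
#' @param cfg a [sim_config].
#' @return named character vector of sequences.
#' @export
generate_sequences <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
         G = cfg$gc_content / 2, U = (1 - cfg$gc_content) / 2)
  lens <- sample(seq.int(cfg$length_range[1L], cfg$length_range[2L]),
                 cfg$n_records, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1L))
  names(seqs) <- sprintf("sim_%03d", seq_len(cfg$n_records))
  seqs
}

base_codes <- c(A = 0L, C = 1L, G = 2L, U = 3L, N = 4L)

#' Reactivity-guided Nussinov folding
#'
#' Maximum-weight Nussinov dynamic program over canonical pairs (GC = 3,
#' AU = 2, GU = 1) with hairpin loop constraint `j - i - 1 >= min_loop`.
#' When a reactivity profile is supplied, pairing base `b` additionally costs
#' `lambda` times its normalized reactivity, steering reactive (likely
#' unpaired) bases out of helices. Traceback is deterministic: the leftmost
#' base pairs with its smallest admissible partner achieving the optimum.
#'
#' This is the bundled baseline folding engine used for synthetic ground
#' truth and as the default refolding engine in segmentation; external
#' thermodynamic engines can be plugged in via [command_engine()].
#'
#' @param sequence RNA sequence over `A,C,G,U` (`N` never pairs).
#' @param reactivity optional [reactivity_profile]; its `normalized` slot
#'   (or raw reactivity if not normalized) supplies the pseudo-penalty,
#'   masked bases contributing zero.
#' @param min_loop minimum hairpin loop length (default 3).
#' @param lambda weight of the reactivity pseudo-penalty (default 2).
#' @param name identifier for the returned structure.
#' @return an [rna_structure].
#' @export
nussinov_fold <- function(sequence, reactivity = NULL, min_loop = 3,
                          lambda = 2, name = "fold") {
  sequence <- normalize_sequence(sequence)
  code <- unname(base_codes[strsplit(sequence, "")[[1L]]])
  L <- length(code)
  penalty <- rep(0, L)
  if (!is.null(reactivity)) {
    stopifnot(inherits(reactivity, "reactivity_profile"))
    if (length(reactivity$coverage) != L)
      stop("reactivity profile length mismatch")
    slot <- if (!is.null(reactivity$normalized)) "normalized" else "reactivity"
    v <- if (slot == "normalized") reactivity$normalized else reactivity$reactivity
    m <- is_masked(reactivity, slot)
    penalty <- ifelse(m, 0, lambda * v)
  }
  res <- .nussinov_dp(code, penalty, as.integer(min_loop))
  pairs <- if (res$n_pairs > 0L) res$pairs[seq_len(res$n_pairs), , drop = FALSE]
           else NULL
  s <- rna_structure(name, sequence, pairs)
  attr(s, "score") <- res$score
  s
}

#' Folding-engine interfaces
#'
#' A folding engine is any `function(sequence, profile) -> rna_structure`.
#' `nussinov_engine()` wraps the bundled [nussinov_fold()];
#' `command_engine()` adapts an external command that reads a FASTA file and
#' a reactivity CSV and writes a CT file; the command template may reference
#' `{fasta}`, `{csv}` and `{ct}` placeholders.
#'
#' @param min_loop,lambda passed to [nussinov_fold()].
#' @return a folding-engine function.
#' @export
nussinov_engine <- function(min_loop = 3, lambda = 2) {
  function(sequence, profile = NULL) {
    nussinov_fold(sequence, profile, min_loop = min_loop, lambda = lambda)
  }
}

#' @rdname nussinov_engine
#' @param template command template containing `{fasta}`, `{csv}` and `{ct}`.
#' @export
command_engine <- function(template) {
  force(template)
  function(sequence, profile = NULL) {
    fasta <- tempfile(fileext = ".fasta")
    csv <- tempfile(fileext = ".csv")
    ct <- tempfile(fileext = ".ct")
    on.exit(unlink(c(fasta, csv, ct)), add = TRUE)
    write_fasta(c(query = sequence), fasta)
    if (!is.null(profile)) {
      write_reactivity_csv(list(probed_record("query", sequence,
                                              list(profile))), csv)
    } else {
      writeLines("reference,position,base,coverage,mutations,reactivity,normalized", csv)
    }
    cmd <- template
    cmd <- gsub("{fasta}", fasta, cmd, fixed = TRUE)
    cmd <- gsub("{csv}", csv, cmd, fixed = TRUE)
    cmd <- gsub("{ct}", ct, cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0L || !file.exists(ct))
      stop("folding engine command failed: ", cmd)
    parse_ct(file = ct)
  }
}

# Beta draw with given mean and coefficient of variation
rbeta_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  v <- (cv * mean)^2
  v <- min(v, mean * (1 - mean) * 0.99)
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' Simulate DMS probing of a structure
#'
#' For each A/C base a true mutation rate is drawn from a Beta distribution
#' with mean `paired_ac_rate` (paired bases) or `unpaired_ac_rate` (unpaired
#' bases) and coefficient of variation `rate_dispersion`. Two replicates are
#' then drawn independently: each applies a log-normal jitter
#' (`replicate_noise`) to the true rates and samples mutation counts as
#' `Binomial(reads_per_base, rate)`. G and U bases are masked with the
#' sentinel in every replicate. Seeded and reproducible.
#'
#' @param s an [rna_structure] (the generating ground truth).
#' @param cfg a [sim_config].
#' @param seed optional override of `cfg$seed` (used when simulating many
#'   records from one configuration).
#' @return a [probed_record] with two replicates and the generating
#'   structure attached.
#' @export
simulate_probing <- function(s, cfg = sim_config(), seed = cfg$seed) {
  stopifnot(inherits(s, "rna_structure"), inherits(cfg, "sim_config"))
  set.seed(seed)
  L <- nchar(s$sequence)
  base <- strsplit(s$sequence, "")[[1L]]
  is_ac <- base %in% c("A", "C")
  paired <- !is.na(partner_vector(s))
  rate <- rep(0, L)
  n_p <- sum(is_ac & paired); n_u <- sum(is_ac & !paired)
  rate[is_ac & paired] <- rbeta_mean_cv(n_p, cfg$paired_ac_rate,
                                        cfg$rate_dispersion)
  rate[is_ac & !paired] <- rbeta_mean_cv(n_u, cfg$unpaired_ac_rate,
                                         cfg$rate_dispersion)
  reps <- lapply(1:2, function(r) {
    jitter <- if (cfg$replicate_noise > 0)
      stats::rlnorm(L, -cfg$replicate_noise^2 / 2, cfg$replicate_noise)
    else rep(1, L)
    rr <- pmin(rate * jitter, 1)
    cov <- rep(cfg$reads_per_base, L)
    mut <- stats::rbinom(L, cov, rr)
    react <- mut / cov
    react[!is_ac] <- -1000
    reactivity_profile(coverage = cov, mutations = mut, reactivity = react)
  })
  probed_record(s$name, s$sequence, reps, structure = s)
}

#' Simulate a full synthetic dataset
#'
#' Generates sequences, folds each with the bundled Nussinov engine to obtain
#' ground-truth structures, and simulates two-replicate probing data for each.
#'
#' @param cfg a [sim_config].
#' @param min_loop hairpin constraint for the ground-truth fold.
#' @return list of [probed_record]s with structures attached.
#' @export
simulate_dataset <- function(cfg = sim_config(), min_loop = 3) {
  seqs <- generate_sequences(cfg)
  out <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    s <- nussinov_fold(seqs[[k]], min_loop = min_loop, name = names(seqs)[k])
    out[[k]] <- simulate_probing(s, cfg, seed = cfg$seed + k)
  }
  names(out) <- names(seqs)
  out
}
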