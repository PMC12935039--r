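two_hairpins <- function() {
  # ((((....))))....((((....))))  (L = 28)
  parse_dotbracket(c(">hp2",
                     "GGGGAAAACCCCAAAAGGGGAAAACCCC",
                     "((((....))))....((((....))))"))[[1L]]
}

test_that("closed boundaries are exactly the positions no pair spans", {
  s <- two_hairpins()
  expect_equal(find_closed_boundaries(s), 12:16)

  hp <- parse_dotbracket(c(">hp", "GGGGGAAACCCCC", "(((((...)))))"))[[1L]]
  expect_equal(find_closed_boundaries(hp), integer(0))

  free <- rna_structure("f", "ACGUACGU")
  expect_equal(find_closed_boundaries(free), 1:7)

  # brute-force cross-check on random structures (pseudoknots included)
  set.seed(31)
  for (rep in 1:50) {
    s <- random_nested_structure(sample(20:60, 1L))
    L <- nchar(s$sequence)
    got <- find_closed_boundaries(s)
    want <- Filter(function(c_) {
      !any(s$pairs[, 1L] <= c_ & s$pairs[, 2L] > c_)
    }, seq_len(L - 1L))
    expect_equal(got, as.integer(want))
  }
})

test_that("short records come back whole; toy structure splits cleanly", {
  s <- random_nested_structure(200)
  frags <- segment_long_record(s, min_len = 150, max_len = 300)
  expect_length(frags, 1L)
  expect_equal(frags[[1L]]$span, c(1L, 200L))

  s2 <- two_hairpins()
  frags2 <- segment_long_record(s2, min_len = 10, max_len = 14)
  expect_length(frags2, 2L)
  expect_equal(nrow(frags2[[1L]]$restricted$pairs), 4L)
  expect_equal(nrow(frags2[[2L]]$restricted$pairs), 4L)
  # union of fragment pairs reindexed back equals parent pairs
  back <- rbind(frags2[[1L]]$restricted$pairs + frags2[[1L]]$span[1L] - 1L,
                frags2[[2L]]$restricted$pairs + frags2[[2L]]$span[1L] - 1L)
  expect_equal(back[order(back[, 1L]), ],
               s2$pairs[order(s2$pairs[, 1L]), ], ignore_attr = TRUE)
})

test_that("fragment pairs are conserved and profiles are exact slices", {
  set.seed(53)
  for (rep in 1:30) {
    s <- random_nested_structure(sample(250:500, 1L))
    prof <- make_profile(rep(5000L, nchar(s$sequence)),
                         reactivity = stats::runif(nchar(s$sequence), 0, 0.2))
    rec <- probed_record(s$name, s$sequence, list(prof), merged = prof,
                         structure = s)
    frags <- suppressWarnings(
      segment_long_record(rec, min_len = 60, max_len = 120))
    # spans tile the parent
    spans <- t(vapply(frags, `[[`, integer(2L), "span"))
    expect_equal(spans[1L, 1L], 1L)
    expect_equal(spans[nrow(spans), 2L], nchar(s$sequence))
    if (nrow(spans) > 1L)
      expect_equal(spans[-1L, 1L], spans[-nrow(spans), 2L] + 1L)
    # cuts at closed boundaries only
    bounds <- find_closed_boundaries(s)
    expect_true(all(spans[-nrow(spans), 2L] %in% bounds))
    # pair union equals parent pairs
    back <- do.call(rbind, lapply(frags, function(f)
      f$restricted$pairs + f$span[1L] - 1L))
    expect_equal(back[order(back[, 1L]), , drop = FALSE],
                 s$pairs[order(s$pairs[, 1L]), , drop = FALSE],
                 ignore_attr = TRUE)
    # sliced profiles concatenate to the parent profile
    cat_react <- unlist(lapply(frags, function(f) f$profile$reactivity))
    expect_equal(cat_react, prof$reactivity)
    # restriction is exact, so pre-refold F1 against the parent slice is 1
    for (f in frags) {
      expect_equal(pair_prf(f$restricted, f$restricted)$f1, 1)
    }
  }
})

test_that("validation refolds with the engine and applies both thresholds", {
  set.seed(60)
  cfg <- sim_config(n_records = 1, length_range = c(320, 380), seed = 14)
  seqs <- generate_sequences(cfg)
  s <- nussinov_fold(seqs[[1L]], name = names(seqs)[1L])
  rec <- simulate_probing(s, cfg)
  qcc <- qc_config()
  rec <- mask_profile(rec, qcc)
  rec <- merge_replicates(rec, qcc)$record
  rec$merged <- normalize_profile(rec$merged, qcc)
  frags <- suppressWarnings(
    segment_long_record(rec, min_len = 80, max_len = 160))
  done <- lapply(frags, validate_fragment, engine = nussinov_engine(),
                 cfg = qcc)
  expect_true(all(vapply(done, function(f) !is.na(f$retained), logical(1L))))
  for (f in done) {
    expect_true(f$retained == (f$auroc > 0.8 && f$f1_vs_parent > 0.8))
  }
  # ideal synthetic signal: every fragment of this record is retained
  expect_true(all(vapply(done, `[[`, logical(1L), "retained")))
})

test_that("a fragment whose refold disagrees is dropped", {
  s <- two_hairpins()
  prof <- make_profile(rep(5000L, 28L),
                       reactivity = stats::runif(28, 0, 0.05))
  f <- fragment_record("toy", c(1L, 12L), substr(s$sequence, 1, 12),
                       s$pairs[s$pairs[, 2L] <= 12L, , drop = FALSE],
                       efoldkit:::slice_profile(prof, 1L, 12L))
  # an engine that returns a clashing structure
  wrong_engine <- function(sequence, profile = NULL) {
    rna_structure("wrong", sequence, rbind(c(2L, 9L)))
  }
  out <- validate_fragment(f, engine = wrong_engine, cfg = qc_config())
  expect_false(out$retained)
  expect_lt(out$f1_vs_parent, 0.8)
})
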