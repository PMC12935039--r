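test_that("coverage filter applies both the total-read and fraction rules", {
  cfg <- qc_config()
  seq10 <- "ACACACACAC"
  keep <- probed_record("k", seq10, list(make_profile(rep(5000L, 10L))))
  expect_true(filter_coverage(keep, cfg)$keep)

  # 4 of 10 bases covered at >= 3000: 0.4 < 0.5 -> drop
  cov <- c(rep(5000L, 4L), rep(1000L, 6L))
  part <- probed_record("p", seq10, list(make_profile(cov)))
  res <- filter_coverage(part, cfg)
  expect_false(res$keep)
  expect_true("low_coverage" %in% res$record$qc_flags)

  # total aligned reads below 3000 -> drop
  low <- probed_record("l", seq10, list(make_profile(rep(2999L, 10L))))
  expect_false(filter_coverage(low, cfg)$keep)
})

test_that("masking hits G/U bases, low coverage, and primer spans only", {
  cfg <- qc_config()
  seqx <- "GACUAC"
  cov <- c(10000L, 2999L, 4000L, 9000L, 9000L, 9000L)
  rec <- probed_record("m", seqx, list(make_profile(cov)),
                       primer_spans = list(c(5L, 6L)))
  masked <- mask_profile(rec, cfg)$replicates[[1L]]
  r <- masked$reactivity
  expect_equal(r[1], -1000)   # G base despite high coverage
  expect_equal(r[2], -1000)   # A base, coverage 2999
  expect_equal(r[4], -1000)   # U base
  expect_equal(r[5], -1000)   # primer span
  expect_equal(r[3], 4000 * 0.01 / 4000)  # C base untouched
  expect_equal(r[6], 0.01)
  expect_error(mask_profile(probed_record("x", "AC",
                                          list(make_profile(c(1L, 1L))),
                                          primer_spans = list(c(2L, 5L))),
                            cfg))
})

test_that("replicate gate uses jointly unmasked Pearson and averages counts", {
  cfg <- qc_config()
  seqx <- paste(rep("AC", 10), collapse = "")
  r <- seq(0.01, 0.2, length.out = 20)
  p1 <- make_profile(rep(5000L, 20L), reactivity = r)
  p2 <- make_profile(rep(5000L, 20L), reactivity = r)
  rec <- probed_record("r", seqx, list(p1, p2))
  res <- merge_replicates(rec, cfg)
  expect_true(res$keep)
  expect_equal(res$pearson, 1)
  expect_equal(res$record$merged$reactivity, r)
  expect_equal(res$record$merged$coverage, rep(10000, 20L))

  # perfect anticorrelation -> rejected
  p3 <- make_profile(rep(5000L, 20L), reactivity = rev(r))
  bad <- merge_replicates(probed_record("b", seqx, list(p1, p3)), cfg)
  expect_false(bad$keep)
  expect_true("low_replicate_correlation" %in% bad$record$qc_flags)

  # single replicate passes through unchanged
  single <- merge_replicates(probed_record("s", seqx, list(p1)), cfg)
  expect_true(single$keep)
  expect_equal(single$record$merged$reactivity, p1$reactivity)

  # fewer than 3 jointly unmasked positions: correlation undefined
  pm <- make_profile(rep(5000L, 20L), reactivity = c(r[1:2], rep(-1000, 18)))
  expect_error(merge_replicates(probed_record("u", seqx, list(pm, pm)), cfg),
               "unmasked")
})

test_that("correlations just below/above the threshold decide the gate", {
  cfg <- qc_config()
  seqx <- paste(rep("AC", 25), collapse = "")
  set.seed(101)
  base <- stats::runif(50, 0, 0.2)
  target_r <- function(rho) {
    # mix base with independent noise to tune the correlation
    noise <- stats::runif(50, 0, 0.2)
    f <- function(a) stats::cor(base, a * base + (1 - a) * noise) - rho
    a <- stats::uniroot(f, c(0.001, 0.999))$root
    a * base + (1 - a) * noise
  }
  lo <- target_r(0.79); hi <- target_r(0.81)
  mk <- function(v) make_profile(rep(5000L, 50L), reactivity = v)
  expect_false(merge_replicates(probed_record("lo", seqx,
                                              list(mk(base), mk(lo))),
                                cfg)$keep)
  expect_true(merge_replicates(probed_record("hi", seqx,
                                             list(mk(base), mk(hi))),
                               cfg)$keep)
})

test_that("percentile normalization divides, clips, and keeps the sentinel", {
  cfg <- qc_config()
  # constant profile: everything normalizes to 1
  p <- make_profile(rep(5000L, 10L), reactivity = rep(0.04, 10L))
  expect_equal(normalize_profile(p, cfg)$normalized, rep(1, 10L))

  # 0.001 * (1..20): type-7 95th percentile = 0.019 + 0.05 * 0.001
  vals <- 0.001 * (1:20)
  p2 <- make_profile(rep(5000L, 20L), reactivity = vals)
  n2 <- normalize_profile(p2, cfg)$normalized
  divisor <- 0.01905
  expect_equal(n2[1:19], pmin(vals[1:19] / divisor, 1))
  expect_equal(n2[20], 1)  # 0.020 clips

  # masked entries stay sentinel
  p3 <- make_profile(rep(5000L, 4L), reactivity = c(0.1, -1000, 0.2, 0.3))
  expect_equal(normalize_profile(p3, cfg)$normalized[2], -1000)

  # all-zero unmasked values: divisor zero is an error
  p4 <- make_profile(rep(5000L, 4L), reactivity = rep(0, 4L))
  expect_error(normalize_profile(p4, cfg), "divisor")
})

test_that("masked positions never influence statistics", {
  cfg <- qc_config()
  set.seed(77)
  vals <- stats::runif(30, 0, 0.3)
  p <- make_profile(rep(5000L, 30L), reactivity = vals)
  n_ref <- normalize_profile(p, cfg)$normalized
  # appending masked positions changes nothing at the unmasked ones
  p_aug <- make_profile(rep(5000L, 40L),
                        reactivity = c(vals, rep(-1000, 10)))
  n_aug <- normalize_profile(p_aug, cfg)$normalized
  expect_equal(n_aug[1:30], n_ref)

  s <- random_nested_structure(30)
  s_aug <- rna_structure(s$name,
                         paste0(s$sequence, paste(rep("A", 10), collapse = "")),
                         s$pairs)
  expect_equal(auroc(s_aug, p_aug), auroc(s, p))
})

test_that("mutation anomaly is flagged above the rate ceiling", {
  cfg <- qc_config()
  ut <- make_profile(rep(1000L, 5L), mutations = c(10L, 350L, 5L, 8L, 2L))
  res <- flag_mutation_anomaly(make_profile(rep(1000L, 5L)), ut, cfg)
  expect_true(res$flagged)
  expect_equal(res$positions, 2L)
  ok <- make_profile(rep(1000L, 5L), mutations = rep(100L, 5L))
  expect_false(flag_mutation_anomaly(make_profile(rep(1000L, 5L)), ok,
                                     cfg)$flagged)
  # without an untreated control the treated profile is checked instead
  hot <- make_profile(rep(1000L, 5L), mutations = c(0L, 0L, 400L, 0L, 0L))
  expect_true(flag_mutation_anomaly(hot, NULL, cfg)$flagged)
})

test_that("binomial bootstrap is seeded, unbiased, and respects masks", {
  cfg <- qc_config(bootstrap_draws = 10, rng_seed = 42)
  p <- make_profile(rep(3000L, 50L), mutations = rep(90L, 50L))  # rate 0.03
  draws1 <- bootstrap_profiles(p, cfg)
  draws2 <- bootstrap_profiles(p, cfg)
  expect_length(draws1, 10L)
  expect_equal(draws1[[3L]]$reactivity, draws2[[3L]]$reactivity)

  # closed-form binomial sd: sqrt(r (1 - r) / N)
  big <- qc_config(bootstrap_draws = 1000, rng_seed = 7)
  many <- bootstrap_profiles(p, big)
  at1 <- vapply(many, function(d) d$reactivity[1L], numeric(1L))
  expect_equal(mean(at1), 0.03, tolerance = 0.01)
  expect_equal(stats::sd(at1), sqrt(0.03 * 0.97 / 3000), tolerance = 0.1)

  pm <- make_profile(rep(3000L, 4L), reactivity = c(0.03, -1000, 0.05, 0.01))
  bm <- bootstrap_profiles(pm, cfg)
  expect_true(all(vapply(bm, function(d) d$reactivity[2L] == -1000,
                         logical(1L))))
})

test_that("AUROC filter keeps concordant records and flags the rest", {
  cfg <- qc_config()
  s <- rna_structure("s", paste(rep("AC", 10), collapse = ""),
                     cbind(1:5, 20:16))
  paired <- !is.na(efoldkit:::partner_vector(s))
  good <- make_profile(rep(5000L, 20L),
                       reactivity = ifelse(paired, 0.005, 0.05))
  rec <- probed_record("g", s$sequence, list(good), merged = good,
                       structure = s)
  res <- filter_by_auroc(rec, cfg)
  expect_true(res$keep)
  expect_equal(res$auroc, 1)

  flat <- make_profile(rep(5000L, 20L), reactivity = rep(0.02, 20L))
  bad <- probed_record("b", s$sequence, list(flat), merged = flat,
                       structure = s)
  res2 <- filter_by_auroc(bad, cfg)  # all ties: AUROC 0.5 < 0.8
  expect_false(res2$keep)
  expect_true("low_auroc" %in% res2$record$qc_flags)
})

test_that("the ribonanza-style preset relaxes reads and adds an S/N gate", {
  preset <- ribonanza_qc_config()
  expect_equal(preset$min_reads, 500)
  expect_equal(preset$min_signal_to_noise, 1)
  rec <- probed_record("r", "ACGU", list(make_profile(rep(600L, 4L))))
  expect_true(filter_coverage(rec, preset)$keep)
  expect_false(filter_coverage(rec, qc_config())$keep)
})

test_that("the pipeline is order-fixed and a no-op on its own output", {
  set.seed(12)
  cfg <- qc_config()
  recs <- simulate_dataset(sim_config(n_records = 6, length_range = c(60, 90),
                                      seed = 3))
  out <- qc_pipeline(recs, cfg)
  expect_true(nrow(out$report) == 6L)
  expect_gt(length(out$kept), 0L)
  again <- qc_pipeline(out$kept, cfg)
  expect_equal(length(again$kept), length(out$kept))
  for (nm in names(out$kept)) {
    expect_equal(again$kept[[nm]]$merged$normalized,
                 out$kept[[nm]]$merged$normalized)
  }
})

test_that("normalization does not change AUROC (rank invariance)", {
  set.seed(21)
  recs <- simulate_dataset(sim_config(n_records = 4, length_range = c(60, 80),
                                      seed = 9))
  cfg <- qc_config()
  for (rec in recs) {
    rec <- mask_profile(rec, cfg)
    m <- merge_replicates(rec, cfg)
    if (!m$keep) next
    raw <- m$record$merged
    norm <- normalize_profile(raw, cfg)
    raw$normalized <- NULL
    expect_equal(auroc(rec$structure, raw), auroc(rec$structure, norm))
  }
})
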