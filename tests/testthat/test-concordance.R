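test_that("pair_prf counts exact pair matches", {
  seq10 <- "GGGGAAUCCC"
  ref <- rna_structure("r", seq10, rbind(c(1, 10), c(2, 9)))
  expect_equal(pair_prf(ref, ref)$f1, 1)

  pred <- rna_structure("p", seq10, rbind(c(1, 10), c(2, 9), c(3, 8)))
  ref2 <- rna_structure("r", seq10, rbind(c(1, 10), c(2, 9), c(4, 7)))
  pr <- pair_prf(pred, ref2)
  expect_equal(pr$tp, 2)
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 2 / 3)
  expect_equal(pr$f1, 2 / 3)

  empty <- rna_structure("e", seq10)
  expect_equal(pair_prf(empty, empty)$f1, 1)
  expect_equal(pair_prf(empty, ref)$f1, 0)
  expect_equal(pair_prf(ref, empty)$f1, 0)
  expect_error(pair_prf(ref, rna_structure("s", "ACGU")), "length")
})

test_that("pair_prf swaps precision and recall under argument exchange", {
  set.seed(13)
  for (rep in 1:50) {
    L <- sample(20:40, 1L)
    a <- random_nested_structure(L)
    b <- random_nested_structure(L)
    b <- rna_structure(b$name, a$sequence, b$pairs)  # same sequence
    ab <- pair_prf(a, b); ba <- pair_prf(b, a)
    expect_equal(ab$precision, ba$recall)
    expect_equal(ab$recall, ba$precision)
    expect_equal(ab$f1, ba$f1)
  }
})

test_that("pair_prf matches direct set arithmetic on random pairs", {
  set.seed(29)
  for (rep in 1:200) {
    L <- sample(15:45, 1L)
    pred <- random_nested_structure(L)
    ref <- random_nested_structure(L)
    ref <- rna_structure(ref$name, pred$sequence, ref$pairs)
    pk <- paste(pred$pairs[, 1L], pred$pairs[, 2L])
    rk <- paste(ref$pairs[, 1L], ref$pairs[, 2L])
    tp <- sum(pk %in% rk)
    pr <- pair_prf(pred, ref)
    expect_equal(pr$tp, tp)
    expect_equal(pr$fp, length(pk) - tp)
    expect_equal(pr$fn, length(rk) - tp)
  }
})

test_that("auroc separates paired from unpaired by reactivity rank", {
  s <- rna_structure("s", "ACAC", rbind(c(1, 4)))  # 1,4 paired; 2,3 unpaired
  hi <- make_profile(rep(5000L, 4L), reactivity = c(0.1, 0.9, 0.8, 0.2))
  expect_equal(auroc(s, hi), 1)
  tie <- make_profile(rep(5000L, 4L), reactivity = rep(0.5, 4L))
  expect_equal(auroc(s, tie), 0.5)
  mix <- make_profile(rep(5000L, 4L), reactivity = c(0.8, 0.9, 0.1, 0.2))
  expect_equal(auroc(s, mix), 0.5)  # exhaustive pairwise: 2 of 4 concordant
  # one class empty after masking
  allpair <- rna_structure("p", "ACGU", rbind(c(1, 4), c(2, 3)))
  expect_error(auroc(allpair, make_profile(rep(5000L, 4L))), "class empty")
})

test_that("auroc is invariant to strictly monotone transforms", {
  set.seed(5)
  for (rep in 1:30) {
    s <- random_nested_structure(30)
    r <- stats::runif(30)
    p1 <- make_profile(rep(5000L, 30L), reactivity = r)
    p2 <- make_profile(rep(5000L, 30L), reactivity = exp(3 * r) + 1)
    if (all(!is.na(c(auroc(s, p1))))) expect_equal(auroc(s, p1), auroc(s, p2))
  }
})

test_that("auroc equals trapezoidal ROC integration with ties", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(5:50, 1L)
    # discretized scores force ties
    score <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lab) || all(lab)) next
    seqx <- paste(rep("A", n), collapse = "")
    pairs <- cbind(which(!lab), n + seq_len(sum(!lab)))
    s <- rna_structure("x", paste(rep("A", 2 * n), collapse = ""),
                       pairs)
    # restrict profile to first n bases paired-state known; build directly
    prof <- make_profile(rep(5000L, 2 * n),
                         reactivity = c(score, rep(-1000, n)))
    expect_equal(auroc(s, prof), roc_trapezoid(score, lab), tolerance = 1e-9)
  }
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  s <- random_nested_structure(60)
  r <- stats::runif(60)
  prof <- make_profile(rep(5000L, 60L), reactivity = r)
  lab <- is.na(efoldkit:::partner_vector(s))
  ours <- auroc(s, prof)
  theirs <- as.numeric(pROC::auc(pROC::roc(lab, r, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("aggregation is the per-structure mean, not pooled counts", {
  r1 <- list(precision = 1, recall = 1, f1 = 1)
  r2 <- list(precision = 0, recall = 0, f1 = 0)
  agg <- aggregate_metrics(list(r1, r2))
  expect_equal(agg$f1, 0.5)
  expect_equal(aggregate_metrics(list(r1))$f1, 1)

  # counterexample: big structure all wrong, small structure all right
  seq40 <- paste(rep("G", 20), paste(rep("C", 20), collapse = ""), collapse = "")
  seq40 <- paste0(paste(rep("G", 20), collapse = ""),
                  paste(rep("C", 20), collapse = ""))
  big_ref <- rna_structure("b", seq40, cbind(1:10, 40:31))
  big_pred <- rna_structure("b", seq40, cbind(11:20, 30:21))
  small_ref <- rna_structure("s", "GGGAAACCC", cbind(1:3, 9:7))
  pr_big <- pair_prf(big_pred, big_ref)
  pr_small <- pair_prf(small_ref, small_ref)
  macro <- aggregate_metrics(list(pr_big, pr_small))$precision
  pooled <- (pr_big$tp + pr_small$tp) /
    (pr_big$tp + pr_small$tp + pr_big$fp + pr_small$fp)
  expect_equal(macro, 0.5)
  expect_false(isTRUE(all.equal(macro, pooled)))
})
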