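test_that("pair input channels follow the Kronecker indicator layout", {
  P <- build_pair_input("ACGU", min_loop = 4)
  expect_equal(dim(P), c(4L, 4L, 17L))
  # (i, j) = (1, 4) is (A, U): channel 4 * 0 + 3 + 1 = 4
  expect_equal(P[1, 4, 4], 1)
  expect_equal(sum(P[1, 4, 1:16]), 1)
  # one-hot completeness at every cell
  expect_true(all(abs(apply(P[, , 1:16], c(1, 2), sum) - 1) < 1e-12))
  # N bases spread uniformly
  Pn <- build_pair_input("ANGU", min_loop = 0)
  expect_equal(sum(Pn[2, 1, 1:16]), 1)
  expect_equal(max(Pn[2, 1, 1:16]), 0.25)
  expect_error(build_pair_input(""), "empty|illegal")
})

test_that("the energy channel sums decayed stacks and respects min_loop", {
  P <- build_pair_input("GGGAAACCC", min_loop = 4)
  # 1-based (3, 7): central G-C plus two outward G-C stacks, inward stops
  expect_equal(P[3, 7, 17], 3 + 3 * exp(-0.5) + 3 * exp(-2),
               tolerance = 1e-12)
  sep <- abs(outer(1:9, 1:9, `-`))
  expect_true(all(P[, , 17][sep < 4] == 0))
})

test_that("forward output is a deterministic symmetric probability grid", {
  m <- efold(tiny_efold_config(), seed = 3)
  set.seed(51)
  seqx <- paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = "")
  g1 <- efold_forward(m, seqx)
  g2 <- efold_forward(m, seqx)
  expect_equal(dim(g1), c(30L, 30L))
  expect_true(all(g1 >= 0 & g1 <= 1))
  expect_identical(unclass(g1), unclass(g2))
  expect_equal(unclass(g1), t(unclass(g1)))
})

test_that("analytic gradients match finite differences", {
  set.seed(61)
  seqx <- paste(sample(c("A", "C", "G", "U"), 14, TRUE), collapse = "")
  target <- pairs_to_matrix(rna_structure("t", seqx,
                                          rbind(c(1, 14), c(2, 13))))
  for (variant in c("full", "ablation1", "ablation2")) {
    m <- efold(tiny_efold_config(variant = variant), seed = 3)
    # nudge all parameters off zero so no ReLU sits exactly at its kink
    set.seed(62)
    m$params <- lapply(m$params, function(p) p + stats::rnorm(length(p), 0, 0.03))
    lg <- efoldkit:::efold_loss_grads(m, seqx, target)
    expect_true(all(vapply(lg$grads, function(g) all(is.finite(g)),
                           logical(1L))))
    set.seed(63)
    for (nm in sample(names(m$params), min(12L, length(m$params)))) {
      idx <- sample(length(m$params[[nm]]), 1L)
      eps <- 1e-5
      m2 <- m
      m2$params[[nm]][idx] <- m$params[[nm]][idx] + eps
      l1 <- efoldkit:::efold_loss_grads(m2, seqx, target)$loss
      m2$params[[nm]][idx] <- m$params[[nm]][idx] - eps
      l0 <- efoldkit:::efold_loss_grads(m2, seqx, target)$loss
      num <- (l1 - l0) / (2 * eps)
      ana <- lg$grads[[nm]][idx]
      expect_equal(ana, num, tolerance = 1e-3,
                   label = paste("grad", variant, nm))
    }
  }
})

test_that("calibrated defaults reproduce the published parameter counts", {
  cfg <- efold_config()
  expect_identical(count_parameters(cfg), 1493420L)
  expect_identical(count_parameters(make_ablation(cfg, 1)), 595100L)
  expect_identical(count_parameters(make_ablation(cfg, 2)), 992720L)
})

test_that("per-block parameter arithmetic is self-consistent", {
  # the non-block glue (embedding + decoder in abl2; decoder in abl1) is
  # constant, so block counts scale linearly in n_blocks
  c2 <- function(n) count_parameters(efold_config(n_blocks = n,
                                                  variant = "ablation2"))
  expect_equal(c2(4) - c2(2), 2 * (c2(2) - c2(1)))
  cf <- function(n) count_parameters(efold_config(n_blocks = n))
  expect_equal(cf(4) - cf(2), 2 * (cf(2) - cf(1)))
})

test_that("ablations reduce parameters in the published order", {
  cfg <- efold_config()
  n_full <- count_parameters(cfg)
  n_a1 <- count_parameters(make_ablation(cfg, 1))
  n_a2 <- count_parameters(make_ablation(cfg, 2))
  expect_true(n_a1 < n_a2 && n_a2 < n_full)
  expect_error(make_ablation(cfg, 3), "1 or 2")
})

test_that("ablation 1 still yields an LxL grid, independent of attention", {
  cfg_a <- tiny_efold_config(variant = "ablation1")
  cfg_b <- tiny_efold_config(variant = "ablation1", attn_heads = 8,
                             seq_dim = 32)
  m_a <- efold(cfg_a, seed = 5)
  m_b <- efold(cfg_b, seed = 5)
  set.seed(55)
  seqx <- paste(sample(c("A", "C", "G", "U"), 20, TRUE), collapse = "")
  g_a <- efold_forward(m_a, seqx)
  g_b <- efold_forward(m_b, seqx)
  expect_equal(dim(g_a), c(20L, 20L))
  # attention-related fields do not touch ablation 1's parameters or output
  expect_identical(unclass(g_a), unclass(g_b))
})

test_that("a tiny model memorizes a single repeated example", {
  set.seed(71)
  seqx <- "GGGGGAAAACCCCCAAGGGAAAACCC"
  s <- nussinov_fold(seqx, name = "memo")
  m <- efold(tiny_efold_config(), seed = 9)
  fit <- train_model(m, train_config(epochs = 150, lr = 3e-3,
                                     effective_batch = 1, avg_last_k = 1,
                                     seed = 9),
                     list(s))
  expect_lt(utils::tail(fit$loss, 1), 0.02)
  expect_lt(utils::tail(fit$loss, 1), fit$loss[1])
})
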