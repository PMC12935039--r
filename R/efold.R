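#' Model configuration for the pairing-matrix network
#'
#' Architectural hyperparameters of the two-channel sequence/pair network.
#' The stated backbone: a learned embedding of width `seq_dim = 64`; a block
#' repeated `n_blocks = 4` times whose sequence channel runs
#' relative-position multihead attention (with a bias projected from the pair
#' representation), a feed-forward layer, a pointwise/depthwise/pointwise 1D
#' convolution (hidden width 128, output width back to `seq_dim`), another
#' feed-forward layer, and a two-layer transition MLP, with skip connections
#' throughout; the pair channel receives an outer-product update from the
#' sequence channel, runs a dilated 2D ResNet with two residual blocks, and a
#' two-layer pair transition. A final 2D residual-block head maps the
#' 17-channel pair representation to a single-channel pairing matrix.
#'
#' The pair representation is kept at `pair_channels = 17` end to end (the
#' Kronecker input width), so the decoder head is byte-for-byte shareable
#' across the full model and both ablations. Free widths not fixed by the
#' published description (`attn_heads`, `ff_dim`, `conv_kernel`,
#' `seq_trans_dim`, `outer_dim`, `resnet_hidden`, `pair_trans_dim`,
#' `head_dim`, `head_hidden`) default to the calibrated values under which
#' the full model and its two ablations instantiate to exactly 1,493,420,
#' 595,100 and 992,720 trainable parameters; see the methods vignette.
#'
#' @param seq_dim sequence embedding width (default 64).
#' @param n_blocks number of repeated blocks (default 4).
#' @param attn_heads attention heads; must divide `seq_dim` (default 8).
#' @param relpos_max clipping offset of the learned relative-position bias
#'   (default 64), so inference generalizes beyond training lengths.
#' @param ff_dim feed-forward hidden width (default 192).
#' @param conv_hidden depthwise conv width (default 128).
#' @param conv_kernel depthwise kernel size, odd (default 7).
#' @param seq_trans_dim sequence transition hidden width (default 75).
#' @param outer_dim outer-product projection width (default 109).
#' @param pair_channels pair-representation width, fixed at 17.
#' @param pair_resnet_blocks residual blocks in the pair trunk (default 2).
#' @param resnet_hidden pair-trunk hidden conv width (default 179).
#' @param dilation_rates dilation per pair residual block (default `c(1, 2)`).
#' @param pair_trans_dim pair transition hidden width (default 86).
#' @param head_dim decoder head conv width (default 197).
#' @param head_hidden decoder residual-block hidden width (default 159).
#' @param pair_threshold probability threshold for calling pairs
#'   (default 0.5).
#' @param min_loop minimum hairpin loop: pairs with `|i - j| < min_loop`
#'   are forbidden at postprocessing (default 4).
#' @param canonical_only restrict called pairs to AU/GC/GU (default FALSE).
#' @param variant `"full"`, `"ablation1"` (no blocks: Kronecker input straight
#'   to the unchanged decoder) or `"ablation2"` (no pair CNNs or pair-bias
#'   feedback; one pair representation built from the last block's sequence
#'   features).
#' @return object of class `efold_config`.
#' @export
efold_config <- function(seq_dim = 64, n_blocks = 4, attn_heads = 8,
                         relpos_max = 64, ff_dim = 192, conv_hidden = 128,
                         conv_kernel = 7, seq_trans_dim = 75, outer_dim = 109,
                         pair_channels = 17, pair_resnet_blocks = 2,
                         resnet_hidden = 179, dilation_rates = c(1, 2),
                         pair_trans_dim = 86, head_dim = 197,
                         head_hidden = 159, pair_threshold = 0.5,
                         min_loop = 4, canonical_only = FALSE,
                         variant = "full") {
  stopifnot(seq_dim > 0, n_blocks >= 0, attn_heads > 0,
            seq_dim %% attn_heads == 0, conv_kernel %% 2 == 1,
            pair_channels == 17,
            length(dilation_rates) == pair_resnet_blocks,
            variant %in% c("full", "ablation1", "ablation2"))
  structure(as.list(environment()), class = "efold_config")
}

#' Derive an ablation configuration
#'
#' Ablation 1 removes all blocks and passes the Kronecker-constructed pair
#' representation directly to the unchanged decoder head. Ablation 2 removes
#' the pairwise CNNs (pair trunk and pair transition) from every block —
#' which also removes the pair-bias feedback into attention — and derives a
#' single pair representation from the last block's sequence features via the
#' outer-product module, feeding the same decoder.
#'
#' @param cfg an [efold_config].
#' @param which 1 or 2.
#' @return the modified configuration.
#' @export
make_ablation <- function(cfg, which) {
  stopifnot(inherits(cfg, "efold_config"))
  if (!which %in% c(1, 2)) stop("which must be 1 or 2")
  cfg$variant <- paste0("ablation", which)
  cfg
}

seq_onehot <- function(sequence) {
  ch <- strsplit(normalize_sequence(sequence), "")[[1L]]
  L <- length(ch)
  oh <- matrix(0, L, 4L, dimnames = list(NULL, c("A", "C", "G", "U")))
  for (b in c("A", "C", "G", "U")) oh[ch == b, b] <- 1
  oh[ch == "N", ] <- 0.25
  oh
}

# complementarity weights for the energy channel
comp_weight <- function(a, b) {
  key <- paste0(a, b)
  w <- c(AU = 2, UA = 2, GC = 3, CG = 3, GU = 0.8, UG = 0.8)
  out <- unname(w[key])
  out[is.na(out)] <- 0
  out
}

#' Kronecker pair input
#'
#' Builds the L-by-L-by-17 pair representation: channels 1-16 are one-hot
#' base-combination indicators (channel `4 * code(s_i) + code(s_j) + 1` with
#' codes A=0, C=1, G=2, U=3; `N` contributes a uniform soft one-hot), and
#' channel 17 is a stacking-energy map: for each `(i, j)` the sum of
#' Gaussian-decayed complementarity weights `exp(-d^2/2) * c(s_{i-d}, s_{j+d})`
#' walking outward and `exp(-d^2/2) * c(s_{i+d}, s_{j-d})` walking inward,
#' each walk truncated at the first non-complementary encounter or the
#' sequence bound (AU/UA = 2, GC/CG = 3, GU/UG = 0.8); entries with
#' `|i - j| < min_loop` are zero.
#'
#' @param sequence RNA sequence.
#' @param min_loop sharp-loop cutoff for the energy channel (default 4).
#' @return numeric array `c(L, L, 17)`.
#' @export
build_pair_input <- function(sequence, min_loop = 4) {
  oh <- seq_onehot(sequence)
  L <- nrow(oh)
  if (L == 0L) stop("empty sequence")
  P <- array(0, c(L, L, 17L))
  ch <- 0L
  for (a in 1:4) for (b in 1:4) {
    ch <- ch + 1L
    P[, , (a - 1L) * 4L + b] <- outer(oh[, a], oh[, b])
  }
  ch <- strsplit(normalize_sequence(sequence), "")[[1L]]
  cw <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (abs(i - j) < min_loop) next
    tot <- 0
    d <- 0L
    repeat {  # outward walk
      ii <- i - d; jj <- j + d
      if (ii < 1L || jj > L) break
      w <- comp_weight(ch[ii], ch[jj])
      if (w == 0) break
      tot <- tot + exp(-d^2 / 2) * w
      d <- d + 1L
    }
    d <- 1L
    repeat {  # inward walk
      ii <- i + d; jj <- j - d
      if (ii >= jj) break
      w <- comp_weight(ch[ii], ch[jj])
      if (w == 0) break
      tot <- tot + exp(-d^2 / 2) * w
      d <- d + 1L
    }
    cw[i, j] <- tot
  }
  P[, , 17L] <- cw
  P
}

# ---- parameter construction ------------------------------------------------

param_shapes <- function(cfg) {
  d <- cfg$seq_dim; h <- cfg$attn_heads; K <- cfg$relpos_max
  f <- cfg$ff_dim; chid <- cfg$conv_hidden; k <- cfg$conv_kernel
  t_ <- cfg$seq_trans_dim; oc <- cfg$outer_dim; pc <- cfg$pair_channels
  wr <- cfg$resnet_hidden; tp <- cfg$pair_trans_dim
  wh <- cfg$head_dim; u <- cfg$head_hidden
  shapes <- list()
  add <- function(name, dims) shapes[[name]] <<- dims
  mlp <- function(pre, din, hid, dout) {
    add(paste0(pre, "ln.g"), din); add(paste0(pre, "ln.b"), din)
    add(paste0(pre, "W1"), c(din, hid)); add(paste0(pre, "b1"), hid)
    add(paste0(pre, "W2"), c(hid, dout)); add(paste0(pre, "b2"), dout)
  }
  outer_mod <- function(pre) {
    add(paste0(pre, "Wa"), c(d, oc)); add(paste0(pre, "ba"), oc)
    add(paste0(pre, "Wb"), c(d, oc)); add(paste0(pre, "bb"), oc)
    add(paste0(pre, "Wo"), c(oc, pc)); add(paste0(pre, "bo"), pc)
  }
  if (cfg$variant != "ablation1") {
    add("embed.W", c(4L, d)); add("embed.b", d)
    for (bl in seq_len(cfg$n_blocks)) {
      pre <- sprintf("block%d.", bl)
      add(paste0(pre, "attn.ln.g"), d); add(paste0(pre, "attn.ln.b"), d)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) add(paste0(pre, "attn.", nm), c(d, d))
      for (nm in c("bq", "bk", "bv", "bo")) add(paste0(pre, "attn.", nm), d)
      add(paste0(pre, "attn.rel"), c(h, 2L * K + 1L))
      if (cfg$variant == "full") {
        add(paste0(pre, "attn.Wpb"), c(pc, h)); add(paste0(pre, "attn.bpb"), h)
      }
      mlp(paste0(pre, "ff1."), d, f, d)
      add(paste0(pre, "conv.ln.g"), d); add(paste0(pre, "conv.ln.b"), d)
      add(paste0(pre, "conv.Wp1"), c(d, chid)); add(paste0(pre, "conv.bp1"), chid)
      add(paste0(pre, "conv.Kd"), c(k, chid)); add(paste0(pre, "conv.bd"), chid)
      add(paste0(pre, "conv.Wp2"), c(chid, d)); add(paste0(pre, "conv.bp2"), d)
      mlp(paste0(pre, "ff2."), d, f, d)
      mlp(paste0(pre, "strans."), d, t_, d)
      if (cfg$variant == "full") {
        outer_mod(paste0(pre, "outer."))
        for (rb in seq_len(cfg$pair_resnet_blocks)) {
          rpre <- sprintf("%spres%d.", pre, rb)
          add(paste0(rpre, "K1"), c(9L * pc, wr)); add(paste0(rpre, "b1"), wr)
          add(paste0(rpre, "K2"), c(9L * wr, pc)); add(paste0(rpre, "b2"), pc)
        }
        mlp(paste0(pre, "ptrans."), pc, tp, pc)
      }
    }
    if (cfg$variant == "ablation2") outer_mod("outer.")
  }
  add("head.Kin", c(9L * pc, wh)); add("head.bin", wh)
  add("head.ln.g", wh); add("head.ln.b", wh)
  add("head.K1", c(9L * wh, u)); add("head.b1", u)
  add("head.K2", c(9L * u, wh)); add("head.b2", wh)
  add("head.Kout", c(wh, 1L)); add("head.bout", 1L)
  shapes
}

init_params <- function(cfg, seed = 1L) {
  set.seed(seed)
  shapes <- param_shapes(cfg)
  params <- lapply(names(shapes), function(nm) {
    dims <- shapes[[nm]]
    if (grepl("ln\\.g$", nm)) return(rep(1, dims))
    if (grepl("\\.b[a-z0-9]*$", nm) || grepl("ln\\.b$", nm))
      return(rep(0, prod(dims)))
    if (grepl("attn\\.rel$", nm)) return(matrix(0, dims[1L], dims[2L]))
    fan_in <- dims[1L]
    matrix(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims[1L], dims[2L])
  })
  names(params) <- names(shapes)
  params
}

#' Construct a pairing-matrix network
#'
#' Instantiates the network described by an [efold_config] with seeded random
#' initial weights, returning an S3 model object with `print()`, `coef()`,
#' `predict()` and [count_parameters()] methods. Untrained weights produce
#' near-uniform scores; see [train_model()].
#'
#' @param config an [efold_config].
#' @param seed initialization seed.
#' @return object of class `efold`.
#' @export
efold <- function(config = efold_config(), seed = 1L) {
  stopifnot(inherits(config, "efold_config"))
  structure(list(config = config, params = init_params(config, seed)),
            class = "efold")
}

#' Count trainable parameters
#'
#' Total number of trainable scalar parameters of a model (or of the model a
#' configuration would instantiate), obtained by summing the sizes of every
#' parameter array.
#'
#' @param x an `efold` model or an [efold_config].
#' @return integer parameter count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "efold_config")) x <- efold(x)
  stopifnot(inherits(x, "efold"))
  sum(vapply(x$params, length, integer(1L)))
}

#' @export
print.efold <- function(x, ...) {
  cfg <- x$config
  cat("<efold> variant=", cfg$variant, ", blocks=", cfg$n_blocks,
      ", seq_dim=", cfg$seq_dim, ", heads=", cfg$attn_heads, "\n", sep = "")
  cat("  trainable parameters: ",
      format(count_parameters(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' @export
coef.efold <- function(object, ...) object$params

# ---- forward pass ----------------------------------------------------------

mlp_fwd <- function(x, pm, pre) {
  ln <- ln_fwd(x, pm[[paste0(pre, "ln.g")]], pm[[paste0(pre, "ln.b")]])
  h1 <- lin_fwd(ln$y, pm[[paste0(pre, "W1")]], pm[[paste0(pre, "b1")]])
  a1 <- nn_relu(h1)
  y <- lin_fwd(a1, pm[[paste0(pre, "W2")]], pm[[paste0(pre, "b2")]])
  list(y = x + y, cache = list(x = x, ln = ln, a1 = a1))
}

mlp_bwd <- function(cache, pm, pre, dy, G) {
  l2 <- lin_bwd(cache$a1, pm[[paste0(pre, "W2")]], dy)
  gacc(G, paste0(pre, "W2"), l2$dW); gacc(G, paste0(pre, "b2"), l2$db)
  da1 <- nn_relu_bwd(cache$a1, l2$dx)
  l1 <- lin_bwd(cache$ln$y, pm[[paste0(pre, "W1")]], da1)
  gacc(G, paste0(pre, "W1"), l1$dW); gacc(G, paste0(pre, "b1"), l1$db)
  lb <- ln_bwd(cache$ln, pm[[paste0(pre, "ln.g")]], l1$dx)
  gacc(G, paste0(pre, "ln.g"), lb$dg); gacc(G, paste0(pre, "ln.b"), lb$db)
  dy + lb$dx  # skip connection
}

attn_fwd <- function(x, Pflat, pm, pre, cfg) {
  d <- cfg$seq_dim; h <- cfg$attn_heads; dh <- d %/% h
  L <- nrow(x)
  ln <- ln_fwd(x, pm[[paste0(pre, "ln.g")]], pm[[paste0(pre, "ln.b")]])
  Q <- lin_fwd(ln$y, pm[[paste0(pre, "Wq")]], pm[[paste0(pre, "bq")]])
  Km <- lin_fwd(ln$y, pm[[paste0(pre, "Wk")]], pm[[paste0(pre, "bk")]])
  V <- lin_fwd(ln$y, pm[[paste0(pre, "Wv")]], pm[[paste0(pre, "bv")]])
  idx <- relpos_index(L, cfg$relpos_max)
  rel <- pm[[paste0(pre, "rel")]]
  use_bias <- !is.null(Pflat)
  if (use_bias) {
    PB <- lin_fwd(Pflat, pm[[paste0(pre, "Wpb")]], pm[[paste0(pre, "bpb")]])
  } else PB <- NULL
  A <- vector("list", h); ctx <- matrix(0, L, d)
  for (hd in seq_len(h)) {
    cols <- (hd - 1L) * dh + seq_len(dh)
    logits <- tcrossprod(Q[, cols, drop = FALSE],
                         Km[, cols, drop = FALSE]) / sqrt(dh)
    logits <- logits + matrix(rel[hd, idx], L, L)
    if (use_bias) logits <- logits + matrix(PB[, hd], L, L)
    A[[hd]] <- row_softmax(logits)
    ctx[, cols] <- A[[hd]] %*% V[, cols, drop = FALSE]
  }
  out <- lin_fwd(ctx, pm[[paste0(pre, "Wo")]], pm[[paste0(pre, "bo")]])
  list(y = x + out,
       cache = list(x = x, ln = ln, Q = Q, K = Km, V = V, A = A, ctx = ctx,
                    idx = idx, use_bias = use_bias, Pflat = Pflat))
}

attn_bwd <- function(cache, pm, pre, cfg, dy, G) {
  d <- cfg$seq_dim; h <- cfg$attn_heads; dh <- d %/% h
  L <- nrow(dy)
  lo <- lin_bwd(cache$ctx, pm[[paste0(pre, "Wo")]], dy)
  gacc(G, paste0(pre, "Wo"), lo$dW); gacc(G, paste0(pre, "bo"), lo$db)
  dctx <- lo$dx
  dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
  drel <- matrix(0, h, ncol(pm[[paste0(pre, "rel")]]))
  dPB <- if (cache$use_bias) matrix(0, L * L, h) else NULL
  for (hd in seq_len(h)) {
    cols <- (hd - 1L) * dh + seq_len(dh)
    A <- cache$A[[hd]]
    dA <- tcrossprod(dctx[, cols, drop = FALSE], cache$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(A, dctx[, cols, drop = FALSE])
    dlog <- softmax_bwd(A, dA)
    dQ[, cols] <- dlog %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dlog, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
    sums <- rowsum(as.vector(dlog), group = as.vector(cache$idx))
    drel[hd, as.integer(rownames(sums))] <-
      drel[hd, as.integer(rownames(sums))] + sums[, 1L]
    if (cache$use_bias) dPB[, hd] <- as.vector(dlog)
  }
  gacc(G, paste0(pre, "rel"), drel)
  dPflat <- NULL
  if (cache$use_bias) {
    lp <- lin_bwd(cache$Pflat, pm[[paste0(pre, "Wpb")]], dPB)
    gacc(G, paste0(pre, "Wpb"), lp$dW); gacc(G, paste0(pre, "bpb"), lp$db)
    dPflat <- lp$dx
  }
  dln <- matrix(0, L, d)
  for (w in list(list("Wq", "bq", dQ), list("Wk", "bk", dK),
                 list("Wv", "bv", dV))) {
    lw <- lin_bwd(cache$ln$y, pm[[paste0(pre, w[[1L]])]], w[[3L]])
    gacc(G, paste0(pre, w[[1L]]), lw$dW); gacc(G, paste0(pre, w[[2L]]), lw$db)
    dln <- dln + lw$dx
  }
  lb <- ln_bwd(cache$ln, pm[[paste0(pre, "ln.g")]], dln)
  gacc(G, paste0(pre, "ln.g"), lb$dg); gacc(G, paste0(pre, "ln.b"), lb$db)
  list(dx = dy + lb$dx, dPflat = dPflat)
}

conv_mod_fwd <- function(x, pm, pre) {
  ln <- ln_fwd(x, pm[[paste0(pre, "ln.g")]], pm[[paste0(pre, "ln.b")]])
  h1 <- lin_fwd(ln$y, pm[[paste0(pre, "Wp1")]], pm[[paste0(pre, "bp1")]])
  a1 <- nn_relu(h1)
  h2 <- dwconv_fwd(a1, pm[[paste0(pre, "Kd")]], pm[[paste0(pre, "bd")]])
  a2 <- nn_relu(h2)
  y <- lin_fwd(a2, pm[[paste0(pre, "Wp2")]], pm[[paste0(pre, "bp2")]])
  list(y = x + y, cache = list(x = x, ln = ln, a1 = a1, a2 = a2))
}

conv_mod_bwd <- function(cache, pm, pre, dy, G) {
  l2 <- lin_bwd(cache$a2, pm[[paste0(pre, "Wp2")]], dy)
  gacc(G, paste0(pre, "Wp2"), l2$dW); gacc(G, paste0(pre, "bp2"), l2$db)
  da2 <- nn_relu_bwd(cache$a2, l2$dx)
  dw <- dwconv_bwd(cache$a1, pm[[paste0(pre, "Kd")]], da2)
  gacc(G, paste0(pre, "Kd"), dw$dK); gacc(G, paste0(pre, "bd"), dw$db)
  da1 <- nn_relu_bwd(cache$a1, dw$dx)
  l1 <- lin_bwd(cache$ln$y, pm[[paste0(pre, "Wp1")]], da1)
  gacc(G, paste0(pre, "Wp1"), l1$dW); gacc(G, paste0(pre, "bp1"), l1$db)
  lb <- ln_bwd(cache$ln, pm[[paste0(pre, "ln.g")]], l1$dx)
  gacc(G, paste0(pre, "ln.g"), lb$dg); gacc(G, paste0(pre, "ln.b"), lb$db)
  dy + lb$dx
}

outer_fwd <- function(x, pm, pre, L, pc) {
  a <- lin_fwd(x, pm[[paste0(pre, "Wa")]], pm[[paste0(pre, "ba")]])
  b <- lin_fwd(x, pm[[paste0(pre, "Wb")]], pm[[paste0(pre, "bb")]])
  W <- pm[[paste0(pre, "Wo")]]; bo <- pm[[paste0(pre, "bo")]]
  upd <- array(0, c(L, L, pc))
  for (m in seq_len(pc)) {
    upd[, , m] <- a %*% (t(b) * W[, m]) + bo[m]
  }
  list(upd = upd, cache = list(x = x, a = a, b = b))
}

outer_bwd <- function(cache, pm, pre, dUpd, G) {
  W <- pm[[paste0(pre, "Wo")]]
  a <- cache$a; b <- cache$b
  pc <- ncol(W); oc <- nrow(W)
  L <- nrow(a)
  da <- matrix(0, L, oc); db_ <- matrix(0, L, oc)
  dW <- matrix(0, oc, pc); dbo <- numeric(pc)
  for (m in seq_len(pc)) {
    dm <- dUpd[, , m]
    dbo[m] <- sum(dm)
    Tm <- dm %*% b          # L x oc
    da <- da + sweep(Tm, 2L, W[, m], `*`)
    Um <- crossprod(dm, a)  # L x oc
    db_ <- db_ + sweep(Um, 2L, W[, m], `*`)
    dW[, m] <- colSums(a * Tm)
  }
  gacc(G, paste0(pre, "Wo"), dW); gacc(G, paste0(pre, "bo"), dbo)
  la <- lin_bwd(cache$x, pm[[paste0(pre, "Wa")]], da)
  gacc(G, paste0(pre, "Wa"), la$dW); gacc(G, paste0(pre, "ba"), la$db)
  lb <- lin_bwd(cache$x, pm[[paste0(pre, "Wb")]], db_)
  gacc(G, paste0(pre, "Wb"), lb$dW); gacc(G, paste0(pre, "bb"), lb$db)
  la$dx + lb$dx
}

pair_res_fwd <- function(P, pm, pre, dil) {
  c1 <- conv2d_fwd(P, pm[[paste0(pre, "K1")]], pm[[paste0(pre, "b1")]], dil)
  H <- nn_relu(c1$y)
  c2 <- conv2d_fwd(H, pm[[paste0(pre, "K2")]], pm[[paste0(pre, "b2")]], dil)
  list(y = P + c2$y, cache = list(c1 = c1, H = H, c2 = c2))
}

pair_res_bwd <- function(cache, pm, pre, dil, dY, G) {
  b2 <- conv2d_bwd(cache$c2, pm[[paste0(pre, "K2")]], dY, dil)
  gacc(G, paste0(pre, "K2"), b2$dK); gacc(G, paste0(pre, "b2"), b2$db)
  dH <- array(nn_relu_bwd(cache$H, b2$dP), dim(cache$H))
  b1 <- conv2d_bwd(cache$c1, pm[[paste0(pre, "K1")]], dH, dil)
  gacc(G, paste0(pre, "K1"), b1$dK); gacc(G, paste0(pre, "b1"), b1$db)
  dY + b1$dP
}

head_fwd <- function(P, pm) {
  L <- dim(P)[1L]
  cin <- conv2d_fwd(P, pm[["head.Kin"]], pm[["head.bin"]], 1L)
  X <- nn_relu(cin$y)
  Xf <- matrix(X, L * L, dim(X)[3L])
  ln <- ln_fwd(Xf, pm[["head.ln.g"]], pm[["head.ln.b"]])
  Xn <- array(ln$y, dim(X))
  c1 <- conv2d_fwd(Xn, pm[["head.K1"]], pm[["head.b1"]], 1L)
  H <- nn_relu(c1$y)
  c2 <- conv2d_fwd(H, pm[["head.K2"]], pm[["head.b2"]], 1L)
  R <- Xn + c2$y
  Rf <- matrix(R, L * L, dim(R)[3L])
  logits <- matrix(lin_fwd(Rf, pm[["head.Kout"]], pm[["head.bout"]]), L, L)
  list(logits = logits,
       cache = list(P = P, cin = cin, X = X, ln = ln, Xn = Xn,
                    c1 = c1, H = H, c2 = c2, Rf = Rf))
}

head_bwd <- function(cache, pm, dlogits, G) {
  L <- nrow(dlogits)
  wh <- length(pm[["head.bin"]])
  lo <- lin_bwd(cache$Rf, pm[["head.Kout"]], matrix(dlogits, L * L, 1L))
  gacc(G, "head.Kout", lo$dW); gacc(G, "head.bout", lo$db)
  dR <- array(lo$dx, c(L, L, wh))
  b2 <- conv2d_bwd(cache$c2, pm[["head.K2"]], dR, 1L)
  gacc(G, "head.K2", b2$dK); gacc(G, "head.b2", b2$db)
  dH <- array(nn_relu_bwd(cache$H, b2$dP), dim(cache$H))
  b1 <- conv2d_bwd(cache$c1, pm[["head.K1"]], dH, 1L)
  gacc(G, "head.K1", b1$dK); gacc(G, "head.b1", b1$db)
  dXn <- b1$dP + dR  # skip connection
  lb <- ln_bwd(cache$ln, pm[["head.ln.g"]], matrix(dXn, L * L, wh))
  gacc(G, "head.ln.g", lb$dg); gacc(G, "head.ln.b", lb$db)
  dX <- array(nn_relu_bwd(matrix(cache$X, L * L, wh), lb$dx), c(L, L, wh))
  bin_ <- conv2d_bwd(cache$cin, pm[["head.Kin"]], dX, 1L)
  gacc(G, "head.Kin", bin_$dK); gacc(G, "head.bin", bin_$db)
  bin_$dP
}

gacc <- function(G, name, val) {
  cur <- G$g[[name]]
  G$g[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

block_fwd <- function(x, P, pm, bl, cfg) {
  pre <- sprintf("block%d.", bl)
  L <- nrow(x); pc <- cfg$pair_channels
  full <- cfg$variant == "full"
  Pflat <- if (full) matrix(P, L * L, pc) else NULL
  at <- attn_fwd(x, Pflat, pm, paste0(pre, "attn."), cfg)
  f1 <- mlp_fwd(at$y, pm, paste0(pre, "ff1."))
  cv <- conv_mod_fwd(f1$y, pm, paste0(pre, "conv."))
  f2 <- mlp_fwd(cv$y, pm, paste0(pre, "ff2."))
  st <- mlp_fwd(f2$y, pm, paste0(pre, "strans."))
  cache <- list(at = at$cache, f1 = f1$cache, cv = cv$cache, f2 = f2$cache,
                st = st$cache)
  x <- st$y
  if (full) {
    om <- outer_fwd(x, pm, paste0(pre, "outer."), L, pc)
    P <- P + om$upd
    cache$om <- om$cache
    cache$res <- vector("list", cfg$pair_resnet_blocks)
    for (rb in seq_len(cfg$pair_resnet_blocks)) {
      rs <- pair_res_fwd(P, pm, sprintf("%spres%d.", pre, rb),
                         cfg$dilation_rates[rb])
      P <- rs$y
      cache$res[[rb]] <- rs$cache
    }
    Pf <- matrix(P, L * L, pc)
    pt <- mlp_fwd(Pf, pm, paste0(pre, "ptrans."))
    P <- array(pt$y, c(L, L, pc))
    cache$pt <- pt$cache
  }
  list(x = x, P = P, cache = cache)
}

block_bwd <- function(cache, pm, bl, cfg, dx, dP, G) {
  pre <- sprintf("block%d.", bl)
  full <- cfg$variant == "full"
  pc <- cfg$pair_channels
  if (full) {
    L <- dim(dP)[1L]
    dPf <- mlp_bwd(cache$pt, pm, paste0(pre, "ptrans."),
                   matrix(dP, L * L, pc), G)
    dP <- array(dPf, c(L, L, pc))
    for (rb in rev(seq_len(cfg$pair_resnet_blocks))) {
      dP <- pair_res_bwd(cache$res[[rb]], pm, sprintf("%spres%d.", pre, rb),
                         cfg$dilation_rates[rb], dP, G)
    }
    dx <- dx + outer_bwd(cache$om, pm, paste0(pre, "outer."), dP, G)
  }
  dx <- mlp_bwd(cache$st, pm, paste0(pre, "strans."), dx, G)
  dx <- mlp_bwd(cache$f2, pm, paste0(pre, "ff2."), dx, G)
  dx <- conv_mod_bwd(cache$cv, pm, paste0(pre, "conv."), dx, G)
  dx <- mlp_bwd(cache$f1, pm, paste0(pre, "ff1."), dx, G)
  ab <- attn_bwd(cache$at, pm, paste0(pre, "attn."), cfg, dx, G)
  if (full && !is.null(ab$dPflat)) {
    L <- as.integer(round(sqrt(nrow(ab$dPflat))))
    dP <- dP + array(ab$dPflat, c(L, L, pc))
  }
  list(dx = ab$dx, dP = dP)
}

efold_forward_cache <- function(model, sequence, pair_input = NULL) {
  cfg <- model$config; pm <- model$params
  sequence <- normalize_sequence(sequence)
  L <- nchar(sequence)
  if (L < 1L) stop("empty sequence")
  P0 <- if (is.null(pair_input)) build_pair_input(sequence, cfg$min_loop)
        else pair_input
  caches <- list()
  x <- NULL
  if (cfg$variant == "ablation1") {
    P <- P0
  } else {
    oh <- seq_onehot(sequence)
    x <- lin_fwd(oh, pm[["embed.W"]], pm[["embed.b"]])
    caches$oh <- oh
    P <- P0
    caches$blocks <- vector("list", cfg$n_blocks)
    for (bl in seq_len(cfg$n_blocks)) {
      bf <- block_fwd(x, P, pm, bl, cfg)
      x <- bf$x; P <- bf$P
      caches$blocks[[bl]] <- bf$cache
    }
    if (cfg$variant == "ablation2") {
      om <- outer_fwd(x, pm, "outer.", L, cfg$pair_channels)
      P <- om$upd
      caches$om2 <- om$cache
    }
  }
  hd <- head_fwd(P, pm)
  Z <- (hd$logits + t(hd$logits)) / 2
  caches$head <- hd$cache
  list(scores = nn_sigmoid(Z), logits = Z, caches = caches, P0 = P0)
}

#' Run the network forward
#'
#' Computes the L-by-L pairing-probability grid for a sequence. The output
#' logits are symmetrized as `(Z + t(Z)) / 2` before the sigmoid, so the
#' score grid is symmetric; evaluation is deterministic (no dropout or
#' stochastic layers).
#'
#' @param model an `efold` model.
#' @param sequence RNA sequence (any length; training typically caps length,
#'   inference does not).
#' @return numeric L-by-L matrix of pairing probabilities in `[0, 1]`, of
#'   class `pair_score_grid`.
#' @export
efold_forward <- function(model, sequence) {
  stopifnot(inherits(model, "efold"))
  out <- efold_forward_cache(model, sequence)
  structure(out$scores, class = c("pair_score_grid", "matrix", "array"))
}

# BCE loss against a 0/1 pairing matrix and gradients for all parameters
efold_loss_grads <- function(model, sequence, target, pair_input = NULL) {
  cfg <- model$config; pm <- model$params
  fw <- efold_forward_cache(model, sequence, pair_input)
  L <- nrow(target)
  stopifnot(all(dim(fw$scores) == dim(target)))
  eps <- 1e-12
  s <- fw$scores
  loss <- -mean(target * log(s + eps) + (1 - target) * log(1 - s + eps))
  dZs <- (s - target) / (L * L)
  dZ <- (dZs + t(dZs)) / 2  # symmetrization backward
  G <- new.env(parent = emptyenv())
  G$g <- list()
  dP <- head_bwd(fw$caches$head, pm, dZ, G)
  if (cfg$variant == "ablation2") {
    dx <- outer_bwd(fw$caches$om2, pm, "outer.", dP, G)
    dP <- array(0, dim(dP))
  } else if (cfg$variant == "full") {
    dx <- matrix(0, L, cfg$seq_dim)
  }
  if (cfg$variant != "ablation1") {
    for (bl in rev(seq_len(cfg$n_blocks))) {
      bb <- block_bwd(fw$caches$blocks[[bl]], pm, bl, cfg, dx, dP, G)
      dx <- bb$dx; dP <- bb$dP
    }
    le <- lin_bwd(fw$caches$oh, pm[["embed.W"]], dx)
    gacc(G, "embed.W", le$dW); gacc(G, "embed.b", le$db)
  }
  # parameters untouched by this variant's graph get zero grads
  grads <- G$g
  for (nm in setdiff(names(pm), names(grads)))
    grads[[nm]] <- array(0, dim(as.array(pm[[nm]])))
  list(loss = loss, grads = grads[names(pm)], scores = fw$scores)
}

#' Predict a secondary structure
#'
#' Runs the network forward and converts the score grid into a valid
#' structure through constrained postprocessing ([apply_constraints()] and
#' [call_pairs()]).
#'
#' @param object an `efold` model.
#' @param sequence RNA sequence.
#' @param constraints a [constraint_spec]; defaults follow the model config.
#' @param ... unused.
#' @return an [rna_structure].
#' @export
predict.efold <- function(object, sequence,
                          constraints = constraint_spec(
                            min_loop = object$config$min_loop,
                            canonical_only = object$config$canonical_only,
                            threshold = object$config$pair_threshold),
                          ...) {
  g <- efold_forward(object, sequence)
  g <- apply_constraints(g, sequence, constraints)
  call_pairs(g, constraints, sequence = sequence)
}
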