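#' Training configuration
#'
#' The published recipe at its defaults: binary cross entropy on the full
#' pairing matrix, Adam with learning rate 3e-4, micro-batch 1 with gradient
#' accumulation to an effective batch of 256, 15 epochs, and element-wise
#' averaging of the last five epoch checkpoints for the final weights.
#' Desk-scale runs shrink `effective_batch` and raise `lr`/`epochs` as
#' documented in the methods vignette.
#'
#' @param epochs training epochs (default 15).
#' @param lr Adam learning rate (default 3e-4).
#' @param micro_batch examples per forward/backward pass (fixed at 1: no
#'   padding is ever needed).
#' @param effective_batch examples accumulated per optimizer step
#'   (default 256).
#' @param avg_last_k checkpoints averaged into the final weights
#'   (default 5).
#' @param seed RNG seed controlling shuffling (and any fresh
#'   initialization).
#' @param max_train_len maximum training sequence length (default 1024).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 15, lr = 3e-4, micro_batch = 1,
                         effective_batch = 256, avg_last_k = 5, seed = 1L,
                         max_train_len = 1024) {
  stopifnot(micro_batch == 1, effective_batch >= 1,
            effective_batch %% micro_batch == 0, avg_last_k <= epochs,
            epochs >= 1, lr > 0)
  structure(as.list(environment()), class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a pairing-matrix model
#'
#' Desk-scale single-device loop: per-example binary cross entropy between
#' the score grid and the 0/1 reference pairing matrix, gradients accumulated
#' over `effective_batch` examples per Adam step, data reshuffled every
#' epoch. Fully seeded: two runs with the same seed and data produce
#' identical checkpoints.
#'
#' @param model an `efold` model (its current weights are the starting
#'   point).
#' @param tcfg a [train_config].
#' @param data list of training examples; each element either an
#'   [rna_structure] or a `list(sequence =, structure =)` pair.
#' @param checkpoint_dir optional directory; when given, per-epoch
#'   checkpoints are saved as `epoch_<n>.rds` via [save_checkpoint()].
#' @param verbose print per-epoch mean loss.
#' @return list with the trained `model`, `checkpoints` (list of per-epoch
#'   parameter lists), `final` (model with the last `avg_last_k` checkpoints
#'   averaged), and `loss` (per-epoch mean BCE).
#' @export
train_model <- function(model, tcfg = train_config(), data,
                        checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "efold"), inherits(tcfg, "train_config"),
            length(data) >= 1L)
  examples <- lapply(data, function(d) {
    s <- if (inherits(d, "rna_structure")) d else d$structure
    stopifnot(inherits(s, "rna_structure"))
    if (nchar(s$sequence) > tcfg$max_train_len)
      stop("training sequence longer than max_train_len (",
           tcfg$max_train_len, ")")
    list(sequence = s$sequence, target = pairs_to_matrix(s),
         pair_input = build_pair_input(s$sequence, model$config$min_loop))
  })
  set.seed(tcfg$seed)
  params <- model$params
  state <- adam_init(params)
  accum <- NULL; n_acc <- 0L
  checkpoints <- vector("list", tcfg$epochs)
  epoch_loss <- numeric(tcfg$epochs)
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(length(examples))
    losses <- numeric(length(ord))
    for (ii in seq_along(ord)) {
      ex <- examples[[ord[ii]]]
      model$params <- params
      lg <- efold_loss_grads(model, ex$sequence, ex$target, ex$pair_input)
      if (!is.finite(lg$loss))
        stop("non-finite loss at epoch ", ep, ", example ", ord[ii])
      losses[ii] <- lg$loss
      if (is.null(accum)) {
        accum <- lg$grads
      } else {
        for (nm in names(accum)) accum[[nm]] <- accum[[nm]] + lg$grads[[nm]]
      }
      n_acc <- n_acc + 1L
      if (n_acc == tcfg$effective_batch) {
        for (nm in names(accum)) accum[[nm]] <- accum[[nm]] / n_acc
        st <- adam_step(params, accum, state, tcfg$lr)
        params <- st$params; state <- st$state
        accum <- NULL; n_acc <- 0L
      }
    }
    epoch_loss[ep] <- mean(losses)
    checkpoints[[ep]] <- params
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(list(config = model$config, params = params),
                      file.path(checkpoint_dir, sprintf("epoch_%d.rds", ep)))
    }
    if (verbose)
      message(sprintf("epoch %d/%d  mean BCE %.5f", ep, tcfg$epochs,
                      epoch_loss[ep]))
  }
  model$params <- params
  final <- model
  final$params <- average_checkpoints(
    checkpoints[seq.int(tcfg$epochs - tcfg$avg_last_k + 1L, tcfg$epochs)])
  final_model <- model
  final_model$params <- final$params
  list(model = model, checkpoints = checkpoints, final = final_model,
       loss = epoch_loss)
}

#' Average checkpoints element-wise
#'
#' Element-wise arithmetic mean of every parameter array across checkpoints
#' of identical architecture; used to form the final weights from the last
#' few epochs.
#'
#' @param ckpts list of parameter lists (or `efold` models).
#' @return a parameter list of the same shapes.
#' @export
average_checkpoints <- function(ckpts) {
  stopifnot(length(ckpts) >= 1L)
  plists <- lapply(ckpts, function(c_) if (inherits(c_, "efold")) c_$params else c_)
  nm0 <- names(plists[[1L]])
  for (p in plists) {
    if (!identical(names(p), nm0)) stop("checkpoint parameter names differ")
    for (nm in nm0)
      if (!identical(dim(as.array(p[[nm]])), dim(as.array(plists[[1L]][[nm]]))))
        stop("parameter shape mismatch for ", nm)
  }
  out <- plists[[1L]]
  for (nm in nm0) {
    acc <- Reduce(`+`, lapply(plists, `[[`, nm))
    out[[nm]] <- acc / length(plists)
  }
  out
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single file holding the named parameter arrays together
#' with the embedded model configuration (R serialization).
#'
#' @param ckpt a list with `config` and `params`, or an `efold` model.
#' @param path file path.
#' @export
save_checkpoint <- function(ckpt, path) {
  if (inherits(ckpt, "efold")) ckpt <- list(config = ckpt$config,
                                            params = ckpt$params)
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()`: an `efold` model.
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  structure(list(config = ckpt$config, params = ckpt$params),
            class = "efold")
}

#' Evaluate a model on a test set
#'
#' Predicts each structure (forward pass plus constrained postprocessing),
#' scores it against the reference with [pair_prf()], and aggregates with
#' [aggregate_metrics()] (per-structure mean, not pooled counts). Records
#' whose prediction fails are counted as skipped and excluded from the
#' aggregation.
#'
#' @param model an `efold` model.
#' @param testset nonempty list of [rna_structure] references.
#' @return list with `summary` (mean precision/recall/f1, n, n_skipped) and
#'   `per_record` (data frame of per-structure metrics).
#' @export
evaluate_testset <- function(model, testset) {
  stopifnot(length(testset) >= 1L)
  rows <- list(); results <- list(); skipped <- 0L
  for (s in testset) {
    pred <- tryCatch(predict(model, s$sequence), error = function(e) NULL)
    if (is.null(pred)) { skipped <- skipped + 1L; next }
    pr <- pair_prf(pred, s)
    results[[length(results) + 1L]] <- pr
    rows[[length(rows) + 1L]] <- data.frame(
      name = s$name, length = nchar(s$sequence), tp = pr$tp, fp = pr$fp,
      fn = pr$fn, precision = pr$precision, recall = pr$recall, f1 = pr$f1,
      stringsAsFactors = FALSE)
  }
  if (!length(results)) stop("no record could be evaluated")
  agg <- aggregate_metrics(results)
  agg$n_skipped <- skipped
  list(summary = agg, per_record = do.call(rbind, rows))
}
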