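#' Denoising training loss for one masked sample
#'
#' Noises the masked block at a step t, predicts the injected noise with
#' the network, and returns the mean squared error over the masked
#' atoms' coordinate and atom-type channels (the only channels noise is
#' added to).
#'
#' @param emb a training-mode `tmc_embedding`.
#' @param model a `tmcdiff_model`.
#' @param t diffusion step; if NULL, sampled uniformly from 1..T.
#' @param rng RNG stream or integer seed.
#' @param with_grads also compute parameter gradients.
#' @return scalar loss, or (with `with_grads`) list with `loss`, `grads`.
#' @export
training_loss <- function(emb, model, t = NULL, rng = 1L, with_grads = FALSE) {
  if (!is.function(rng)) rng <- make_rng(rng)
  if (!any(emb$masked)) stop("sample has no masked atoms")
  if (is.null(t)) t <- rng("int", 1L, lo = 1L, hi = model$schedule$T)
  fd <- forward_diffuse(emb, t, model$schedule, rng)
  fw <- model_forward(fd$emb, t, model)
  m <- model$cfg$m
  res_r <- fw$eps_r - fd$eps$r
  res_h <- fw$eps_h[, seq_len(m), drop = FALSE] - fd$eps$h
  denom <- length(res_r) + length(res_h)
  loss <- (sum(res_r^2) + sum(res_h^2)) / denom
  if (!with_grads) return(loss)
  list(loss = loss,
       grads = model_backward(model, fw, 2 * res_r / denom, 2 * res_h / denom))
}

## ---- parameter-tree utilities ----------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- tree_map(f, a[[nm]])
    out
  } else f(a)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}

adam_init <- function(params) {
  zeros <- tree_map(function(x) x * 0, params)
  list(t = 0L, m = zeros, v = tree_map(function(x) x * 0, params))
}

## normalise heterogeneous sample formats to training embeddings
prepare_training_embeddings <- function(samples, l_max) {
  lapply(samples, function(s) {
    if (inherits(s, "tmc_embedding")) return(s)
    if (!is.null(s$complex) && !is.null(s$masked))
      return(build_embedding(s$complex, s$masked, l_max = l_max))
    stop("unrecognised training sample format")
  })
}

#' Train the GVP denoiser on masked samples
#'
#' Stochastic training: one Adam update per sample, with the diffusion
#' step drawn uniformly per example. Returns the fitted model carrying
#' its per-epoch loss curve.
#'
#' @param model a `tmcdiff_model` from [gvp_denoiser()] (may already be
#'   partially trained; training resumes from its stored step count).
#' @param samples list of training samples: training-mode embeddings, or
#'   lists with `complex` (a `tmc`) and `masked` (ligand indices).
#' @param epochs passes over the sample list.
#' @param lr Adam learning rate.
#' @param seed integer seed (shuffling, step draws, noise).
#' @param verbose print the per-epoch loss.
#' @return the trained `tmcdiff_model`.
#' @export
train_denoiser <- function(model, samples, epochs = 30L, lr = 3e-3,
                           seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "tmcdiff_model"))
  embs <- prepare_training_embeddings(samples, model$cfg$l_max)
  if (length(embs) == 0L) stop("no training samples")
  for (e in embs) {
    if (!identical(e$vocab[seq_len(model$cfg$m)], model$vocab))
      stop("corpus/model element vocabulary mismatch")
  }
  rng <- make_rng(substream_seed(seed, model$trained_steps))
  state <- if (is.null(model$adam_state)) adam_init(model$params)
           else model$adam_state
  for (ep in seq_len(epochs)) {
    ord <- order(rng("unif", length(embs)))
    tot <- 0
    for (i in ord) {
      out <- training_loss(embs[[i]], model, rng = rng, with_grads = TRUE)
      st <- adam_step(model$params, out$grads, state, lr)
      model$params <- st$params
      state <- st$state
      tot <- tot + out$loss
      model$trained_steps <- model$trained_steps + 1L
    }
    model$loss <- c(model$loss, tot / length(embs))
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", ep, epochs,
                      tot / length(embs)))
  }
  model$adam_state <- state
  model
}

## ---- S3 methods -------------------------------------------------------

#' @export
print.tmcdiff_model <- function(x, ...) {
  cat(sprintf(
    "<tmcdiff_model> GVP denoiser: %d layers, %d scalar / %d vector channels\n",
    x$cfg$layers, x$cfg$ds, x$cfg$dv))
  cat(sprintf("  schedule: %s, T = %d; vocabulary: %d elements\n",
              x$schedule$kind, x$schedule$T, length(x$vocab)))
  cat(sprintf("  trained steps: %d%s\n", x$trained_steps,
              if (length(x$loss))
                sprintf(", last epoch loss %.4f", utils::tail(x$loss, 1))
              else " (untrained)"))
  invisible(x)
}

#' @export
summary.tmcdiff_model <- function(object, ...) {
  np <- sum(unlist(tree_map(length, object$params)))
  structure(list(cfg = object$cfg, n_params = np,
                 schedule = object$schedule,
                 trained_steps = object$trained_steps,
                 loss = object$loss),
            class = "summary.tmcdiff_model")
}

#' @export
print.summary.tmcdiff_model <- function(x, ...) {
  cat(sprintf("GVP denoiser with %d parameters\n", x$n_params))
  cat(sprintf("  layers %d, scalar width %d, vector channels %d\n",
              x$cfg$layers, x$cfg$ds, x$cfg$dv))
  cat(sprintf("  schedule %s (T = %d), trained steps %d\n",
              x$schedule$kind, x$schedule$T, x$trained_steps))
  if (length(x$loss))
    cat(sprintf("  loss: first %.4f -> last %.4f over %d epochs\n",
                x$loss[1], utils::tail(x$loss, 1), length(x$loss)))
  invisible(x)
}

#' @export
plot.tmcdiff_model <- function(x, ...) {
  if (!length(x$loss)) stop("model has no recorded loss curve")
  graphics::plot(seq_along(x$loss), x$loss, type = "b",
                 xlab = "epoch", ylab = "mean denoising loss",
                 main = "tmcdiff training loss", ...)
  invisible(x)
}

#' Predict injected noise with a fitted denoiser
#'
#' @param object a `tmcdiff_model`.
#' @param emb a `tmc_embedding` with initialised masked block.
#' @param t diffusion step.
#' @param ... unused.
#' @return list with `r` and `h` noise predictions for the masked atoms.
#' @export
predict.tmcdiff_model <- function(object, emb, t, ...) {
  predict_noise(emb, t, object)
}

#' Generate ligands from a fitted denoiser
#'
#' `simulate()` draws `nsim` independent complexes for a frozen context;
#' each draw uses a distinct seed derived from `seed`.
#'
#' @param object a `tmcdiff_model`.
#' @param nsim number of complexes to generate.
#' @param seed integer seed.
#' @param context a `tmc_context`.
#' @param ldg denticity partition for the generated ligands.
#' @param sizes heavy atoms per generated ligand.
#' @param ... forwarded to [sample_ligands()].
#' @return list of `tmc_generated` objects (length `nsim`).
#' @export
simulate.tmcdiff_model <- function(object, nsim = 1, seed = 1L,
                                   context, ldg, sizes, ...) {
  lapply(seq_len(nsim), function(k)
    sample_ligands(context, ldg, sizes, object,
                   seed = as.integer(substream_seed(seed, k)), ...))
}

#' Save / load a denoiser checkpoint
#'
#' Self-describing JSON container holding layer hyperparameters, the
#' element vocabulary, schedule metadata, training state and all weights.
#'
#' @param model a `tmcdiff_model`.
#' @param path file path.
#' @return `path` invisibly (`save`); a `tmcdiff_model` (`load`).
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    format = "tmcdiff-checkpoint-1",
    cfg = model$cfg,
    schedule = list(T = model$schedule$T, kind = model$schedule$kind),
    vocab = model$vocab,
    trained_steps = model$trained_steps,
    loss = model$loss,
    params = tree_map(function(x) {
      if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
      else list(dim = length(x), data = as.numeric(x))
    }, model$params)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(p$format, "tmcdiff-checkpoint-1"))
    stop("not a tmcdiff checkpoint: ", path)
  rebuild <- function(node) {
    if (is.list(node) && !is.null(node$dim) && !is.null(node$data)) {
      if (length(node$dim) == 2) matrix(node$data, node$dim[1], node$dim[2])
      else as.numeric(node$data)
    } else lapply(node, rebuild)
  }
  model <- gvp_denoiser(layers = p$cfg$layers, ds = p$cfg$ds, dv = p$cfg$dv,
                        l_max = p$cfg$l_max, n_freq = p$cfg$n_freq,
                        schedule = make_schedule(p$schedule$T, p$schedule$kind),
                        vocab = p$vocab)
  model$params <- rebuild(p$params)
  model$trained_steps <- as.integer(p$trained_steps)
  model$loss <- as.numeric(p$loss)
  model
}
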