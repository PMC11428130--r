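## Geometric-vector-perceptron noise predictor.
##
## Per-atom features are a rotation-invariant scalar channel vector s and
## rotation-equivariant 3D vector channels V. Vector channels are stored
## as a (3N) x dv matrix with row 3(i-1)+axis for atom i, so channel
## mixing is plain matrix multiplication. Scalars only ever see vector
## norms, which makes every scalar O(3)-invariant and every vector
## channel O(3)-equivariant by construction.
##
## The network is trained by explicit reverse-mode differentiation: each
## forward helper returns a cache, each *_backward consumes it. A
## finite-difference test guards the gradients.

silu <- function(x) x / (1 + exp(-x))
dsilu <- function(x) { s <- 1 / (1 + exp(-x)); s * (1 + x * (1 - s)) }
sigmoid_ <- function(x) 1 / (1 + exp(-x))

## ---- single GVP unit -------------------------------------------------

gvp_init <- function(dsi, dvi, dso, dvo, rng, out_scale = 1) {
  dh <- max(dvi, dvo)
  rmat <- function(nr, nc, fan) matrix(rng("norm", nr * nc) / sqrt(fan), nr, nc)
  list(
    W_h = rmat(dvi, dh, dvi),
    W_mu = rmat(dh, dvo, dh) * out_scale,
    W_s = rmat(dsi + dh, dso, dsi + dh) * out_scale,
    b_s = numeric(dso),
    W_g = rmat(dso, dvo, dso),
    b_g = numeric(dvo)
  )
}

## S: N x dsi, Vm: 3N x dvi, grp: rep(1:N, each = 3)
gvp_forward <- function(p, S, Vm, grp, act = TRUE) {
  Vh <- Vm %*% p$W_h
  nh <- sqrt(rowsum(Vh^2, grp) + 1e-8)
  Scat <- cbind(S, nh)
  Sm <- sweep(Scat %*% p$W_s, 2, p$b_s, "+")
  Sout <- if (act) silu(Sm) else Sm
  G <- sigmoid_(sweep(Sm %*% p$W_g, 2, p$b_g, "+"))
  Vmu <- Vh %*% p$W_mu
  Vout <- Vmu * G[grp, , drop = FALSE]
  list(S = Sout, V = Vout,
       cache = list(S_in = S, Vm = Vm, Vh = Vh, nh = nh, Scat = Scat,
                    Sm = Sm, G = G, Vmu = Vmu, grp = grp, act = act))
}

gvp_backward <- function(p, cache, dSout, dVout) {
  grp <- cache$grp
  Gx <- cache$G[grp, , drop = FALSE]
  dVmu <- dVout * Gx
  dG <- rowsum(cache$Vmu * dVout, grp)
  dGpre <- dG * cache$G * (1 - cache$G)
  dSm <- dGpre %*% t(p$W_g)
  if (cache$act) dSm <- dSm + dSout * dsilu(cache$Sm)
  else dSm <- dSm + dSout
  dW_g <- t(cache$Sm) %*% dGpre
  db_g <- colSums(dGpre)
  dW_s <- t(cache$Scat) %*% dSm
  db_s <- colSums(dSm)
  dScat <- dSm %*% t(p$W_s)
  dsi <- ncol(cache$S_in)
  dS <- dScat[, seq_len(dsi), drop = FALSE]
  dnh <- dScat[, dsi + seq_len(ncol(cache$nh)), drop = FALSE]
  dVh <- dVmu %*% t(p$W_mu) + (dnh / cache$nh)[grp, , drop = FALSE] * cache$Vh
  dW_mu <- t(cache$Vh) %*% dVmu
  dW_h <- t(cache$Vm) %*% dVh
  dVm <- dVh %*% t(p$W_h)
  list(dS = dS, dVm = dVm,
       grads = list(W_h = dW_h, W_mu = dW_mu, W_s = dW_s, b_s = db_s,
                    W_g = dW_g, b_g = db_g))
}

## ---- model constructor ----------------------------------------------

#' Construct an (untrained) GVP denoiser
#'
#' The noise-prediction network phi: scalar/vector features per atom,
#' updated by geometric-vector-perceptron blocks with message passing
#' over the complete graph (every atom except the atom itself is a
#' neighbour; the metal participates like any other atom). Mean
#' aggregation keeps the network well-behaved from 6 to 200 atoms.
#'
#' @param layers number of message-passing layers.
#' @param ds scalar channel width.
#' @param dv number of 3D vector channels.
#' @param l_max maximum ligand codes (must match the embeddings used).
#' @param n_freq sinusoidal frequencies in the diffusion-step encoding.
#' @param schedule a `noise_schedule` (stored with the model).
#' @param seed integer seed for weight initialisation.
#' @param vocab element vocabulary (defaults to the 15 heavy elements).
#' @return object of class `tmcdiff_model` (untrained; see
#'   [train_denoiser()]).
#' @export
gvp_denoiser <- function(layers = 5L, ds = 128L, dv = 16L, l_max = 12L,
                         n_freq = 6L, schedule = make_schedule(),
                         seed = 1L, vocab = element_vocabulary()) {
  m <- length(vocab)
  ds_in <- m + l_max + 6L + 1L + 2L * n_freq + 1L
  rng <- make_rng(seed)
  params <- list(input = gvp_init(ds_in, 1L, ds, dv, rng))
  for (l in seq_len(layers)) {
    params[[paste0("msg", l)]] <- gvp_init(2L * ds + 1L, dv + 1L, ds, dv, rng)
    params[[paste0("upd", l)]] <- gvp_init(ds, dv, ds, dv, rng)
  }
  params$W_out <- matrix(rng("norm", ds * m) * 0.01 / sqrt(ds), ds, m)
  params$b_out <- numeric(m)
  params$W_vout <- matrix(rng("norm", dv) * 0.01 / sqrt(dv), dv, 1)
  structure(list(
    cfg = list(layers = as.integer(layers), ds = as.integer(ds),
               dv = as.integer(dv), l_max = as.integer(l_max),
               n_freq = as.integer(n_freq), m = m),
    params = params,
    schedule = schedule,
    vocab = vocab,
    loss = numeric(0),
    trained_steps = 0L
  ), class = "tmcdiff_model")
}

## ---- featurization ---------------------------------------------------

#' Initial scalar and vector features of an embedding
#'
#' Scalars: scaled one-hot atom types (factor 0.25), ligand and denticity
#' codes (factor 1), the masked flag, a sinusoidal encoding of the
#' diffusion step and the fraction t/T. Vectors: one channel, the scaled
#' displacement from the metal (factor 0.1). All scalars are exactly
#' O(3)-invariant (no coordinate-derived scalar enters here; the input
#' GVP's norm path derives them) and the vector channel is equivariant.
#'
#' @param emb a `tmc_embedding` with defined coordinates and `h_a`.
#' @param t integer diffusion step.
#' @param model a `tmcdiff_model` (for widths and schedule length).
#' @param T_override schedule length used to normalise t (defaults to the
#'   model schedule's T).
#' @return list with `S` (N x ds_in), `Vm` (3N x 1) and `grp`.
#' @export
featurize <- function(emb, t, model, T_override = NULL) {
  stopifnot(inherits(emb, "tmc_embedding"))
  n <- length(emb$elements)
  T_ <- if (is.null(T_override)) model$schedule$T else T_override
  tau <- t / T_
  k <- model$cfg$n_freq
  freqs <- 2^(seq_len(k) - 1)
  tenc <- c(sin(2 * pi * freqs * tau), cos(2 * pi * freqs * tau))
  r <- emb$coords
  if (anyNA(r) || anyNA(emb$h_a))
    stop("embedding has unset coordinates or atom types; initialise the masked block first")
  ## no r-derived scalars here: the input GVP's norm path supplies them,
  ## which keeps every initial scalar bit-identical under rotation
  S <- cbind(0.25 * emb$h_a, emb$h_L, emb$h_c, as.numeric(emb$masked),
             matrix(tenc, n, 2 * k, byrow = TRUE), tau)
  Vm <- matrix(t(0.1 * r), ncol = 1)   # rows: atom-major, xyz within atom
  list(S = unname(S), Vm = Vm, grp = rep(seq_len(n), each = 3L))
}

## complete-graph ordered pair indices (no self edges)
pair_index <- function(n) {
  if (n < 2L) stop(tmcdiff_error("no_neighbours",
    "message passing needs at least two atoms"))
  idx <- expand.grid(j = seq_len(n), i = seq_len(n))
  keep <- idx$i != idx$j
  list(i = idx$i[keep], j = idx$j[keep])
}

vrows <- function(atoms) rep(3L * (atoms - 1L), each = 3L) + seq_len(3L)

## ---- full forward pass ----------------------------------------------

model_forward <- function(emb, t, model, T_override = NULL) {
  ft <- featurize(emb, t, model, T_override)
  n <- length(emb$elements)
  pr <- pair_index(n)
  ri <- emb$coords[pr$i, , drop = FALSE]
  rj <- emb$coords[pr$j, , drop = FALSE]
  dvec <- rj - ri
  d <- sqrt(rowSums(dvec^2))
  unit <- dvec / (d + 1e-8)
  P <- length(pr$i)
  grpP <- rep(seq_len(P), each = 3L)
  vr_j <- vrows(pr$j)
  vr_i <- vrows(pr$i)
  unit_flat <- matrix(t(unit), ncol = 1)

  caches <- list()
  f <- gvp_forward(model$params$input, ft$S, ft$Vm, ft$grp)
  caches$input <- f$cache
  S <- f$S; V <- f$V
  L <- model$cfg$layers
  for (l in seq_len(L)) {
    Sp <- cbind(S[pr$i, , drop = FALSE], S[pr$j, , drop = FALSE], 0.1 * d)
    Vp <- cbind(V[vr_j, , drop = FALSE], unit_flat)
    fm <- gvp_forward(model$params[[paste0("msg", l)]], Sp, Vp, grpP)
    Ms <- rowsum(fm$S, pr$i) / (n - 1L)
    Mv <- rowsum(fm$V, vr_i) / (n - 1L)
    S1 <- S + Ms; V1 <- V + Mv
    fu <- gvp_forward(model$params[[paste0("upd", l)]], S1, V1, ft$grp)
    caches[[paste0("msg", l)]] <- fm$cache
    caches[[paste0("upd", l)]] <- fu$cache
    S <- S1 + fu$S
    V <- V1 + fu$V
  }
  m_rows <- which(emb$masked)
  eps_h <- sweep(S[m_rows, , drop = FALSE] %*% model$params$W_out, 2,
                 model$params$b_out, "+")
  Vm_mask <- V[vrows(m_rows), , drop = FALSE]
  eps_r_flat <- Vm_mask %*% model$params$W_vout
  eps_r <- matrix(eps_r_flat, ncol = 3, byrow = TRUE)
  list(eps_r = eps_r, eps_h = eps_h,
       state = list(S = S, V = V, caches = caches, pr = pr, grp = ft$grp,
                    grpP = grpP, vr_i = vr_i, vr_j = vr_j, n = n,
                    m_rows = m_rows, Vm_mask = Vm_mask, d = d))
}

#' Predict the injected noise for the masked atoms
#'
#' Runs the GVP network on the embedding at step t and reads the
#' coordinate noise from the final vector features and the atom-type
#' noise from the final scalars, for masked atoms only. Deterministic for
#' fixed weights and input.
#'
#' @param emb a `tmc_embedding` (masked block initialised).
#' @param t integer diffusion step.
#' @param model a `tmcdiff_model`.
#' @param T_override schedule length for t-normalisation.
#' @return list with `r` (n_masked x 3) and `h` (n_masked x m).
#' @export
predict_noise <- function(emb, t, model, T_override = NULL) {
  if (!any(emb$masked)) stop("no masked atoms to predict noise for")
  if (ncol(emb$h_a) != model$cfg$m)
    stop("embedding/model atom-type channel mismatch")
  fw <- model_forward(emb, t, model, T_override)
  list(r = fw$eps_r, h = fw$eps_h[, seq_len(model$cfg$m), drop = FALSE])
}

## ---- full backward pass ----------------------------------------------

## deps_r: n_masked x 3, deps_h: n_masked x m -> gradients for all params
model_backward <- function(model, fw, deps_r, deps_h) {
  st <- fw$state
  p <- model$params
  grads <- list()
  S_dim <- model$cfg$ds
  n <- st$n

  dS <- matrix(0, n, S_dim)
  dV <- matrix(0, 3L * n, model$cfg$dv)
  ## readout
  grads$W_out <- t(st$S[st$m_rows, , drop = FALSE]) %*% deps_h
  grads$b_out <- colSums(deps_h)
  dS[st$m_rows, ] <- deps_h %*% t(p$W_out)
  deps_r_flat <- matrix(t(deps_r), ncol = 1)
  grads$W_vout <- t(st$Vm_mask) %*% deps_r_flat
  dV[vrows(st$m_rows), ] <- dV[vrows(st$m_rows), ] + deps_r_flat %*% t(p$W_vout)

  L <- model$cfg$layers
  pr <- st$pr
  for (l in L:1) {
    bu <- gvp_backward(p[[paste0("upd", l)]], st$caches[[paste0("upd", l)]],
                       dS, dV)
    grads[[paste0("upd", l)]] <- bu$grads
    dS1 <- dS + bu$dS       # residual: S = S1 + upd(S1)
    dV1 <- dV + bu$dVm
    ## S1 = S0 + Ms, V1 = V0 + Mv
    dMs <- dS1[pr$i, , drop = FALSE] / (n - 1L)
    dMv <- dV1[st$vr_i, , drop = FALSE] / (n - 1L)
    bm <- gvp_backward(p[[paste0("msg", l)]], st$caches[[paste0("msg", l)]],
                       dMs, dMv)
    grads[[paste0("msg", l)]] <- bm$grads
    ds_ <- S_dim
    dS0 <- dS1 +
      rowsum_fixed(bm$dS[, seq_len(ds_), drop = FALSE], pr$i, n) +
      rowsum_fixed(bm$dS[, ds_ + seq_len(ds_), drop = FALSE], pr$j, n)
    dV0 <- dV1 + rowsum_fixed(bm$dVm[, seq_len(model$cfg$dv), drop = FALSE],
                              st$vr_j, 3L * n)
    dS <- dS0; dV <- dV0
  }
  bi <- gvp_backward(p$input, st$caches$input, dS, dV)
  grads$input <- bi$grads
  grads
}

## rowsum over groups that may be missing some levels; returns nlev rows
rowsum_fixed <- function(x, grp, nlev) {
  out <- matrix(0, nlev, ncol(x))
  rs <- rowsum(x, grp)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' One message-passing stack applied to explicit features
#'
#' Exposed for testing and inspection: applies `n_layers` rounds of
#' complete-graph message passing (mean aggregation, residual updates,
#' scalar/vector exchange inside each GVP block) to given features.
#'
#' @param features list with `S` (N x ds) and `Vm` (3N x dv).
#' @param coords N x 3 coordinates.
#' @param model a `tmcdiff_model` whose layer widths match `features`.
#' @param n_layers number of layers to apply (default: all).
#' @return list with updated `S` and `Vm`.
#' @export
message_pass <- function(features, coords, model, n_layers = NULL) {
  n <- nrow(coords)
  pr <- pair_index(n)
  d <- sqrt(rowSums((coords[pr$j, , drop = FALSE] -
                     coords[pr$i, , drop = FALSE])^2))
  unit <- (coords[pr$j, , drop = FALSE] - coords[pr$i, , drop = FALSE]) /
    (d + 1e-8)
  unit_flat <- matrix(t(unit), ncol = 1)
  grp <- rep(seq_len(n), each = 3L)
  grpP <- rep(seq_along(pr$i), each = 3L)
  vr_j <- vrows(pr$j); vr_i <- vrows(pr$i)
  S <- features$S; V <- features$Vm
  L <- if (is.null(n_layers)) model$cfg$layers else n_layers
  for (l in seq_len(L)) {
    Sp <- cbind(S[pr$i, , drop = FALSE], S[pr$j, , drop = FALSE], 0.1 * d)
    Vp <- cbind(V[vr_j, , drop = FALSE], unit_flat)
    fm <- gvp_forward(model$params[[paste0("msg", l)]], Sp, Vp, grpP)
    S1 <- S + rowsum(fm$S, pr$i) / (n - 1L)
    V1 <- V + rowsum(fm$V, vr_i) / (n - 1L)
    fu <- gvp_forward(model$params[[paste0("upd", l)]], S1, V1, grp)
    S <- S1 + fu$S
    V <- V1 + fu$V
  }
  list(S = S, Vm = V)
}
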