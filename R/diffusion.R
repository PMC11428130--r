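#' Variance-preserving noise schedule
#'
#' Signal coefficients `alpha_t` decrease monotonically from 1 at t = 0 to
#' approximately 0 at t = T, with `alpha_t^2 + sigma_t^2 = 1` at every
#' step (variance-preserving convention). Two shapes are provided: the
#' default power-2 polynomial and a cosine schedule.
#'
#' @param T number of diffusion steps (>= 1).
#' @param kind `"polynomial"` (default) or `"cosine"`.
#' @param s clipping margin keeping coefficients inside (0, 1) for
#'   t = 1..T.
#' @return object of class `noise_schedule`: list with `T`, `kind`,
#'   `alpha` and `sigma` (numeric vectors indexed t = 0..T, so
#'   `alpha[t + 1]` is the coefficient at step t).
#' @export
make_schedule <- function(T = 1000L, kind = "polynomial", s = 1e-4) {
  stopifnot(T >= 1)
  kinds <- c("polynomial", "cosine")
  if (!kind %in% kinds)
    stop(sprintf("unknown schedule kind '%s'; available: %s",
                 kind, paste(kinds, collapse = ", ")))
  t <- seq_len(T) / T
  a <- switch(kind,
    polynomial = 1 - t^2,
    cosine = cos(pi / 2 * (t + s) / (1 + s))
  )
  a <- (1 - 2 * s) * pmin(pmax(a, 0), 1) + s
  alpha <- c(1, a)
  sigma <- sqrt(pmax(0, 1 - alpha^2))
  structure(list(T = as.integer(T), kind = kind,
                 alpha = alpha, sigma = sigma),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> %s, T = %d, alpha range [%.2g, %.2g]\n",
              x$kind, x$T, min(x$alpha[-1]), max(x$alpha[-1])))
  invisible(x)
}

#' Forward diffusion of the masked block
#'
#' Replaces the coordinates and atom-type channels of the masked atoms by
#' `alpha_t * x + sigma_t * eps` with standard-normal noise; the context
#' atoms and the ligand/denticity code `h_Lc` are untouched. The injected
#' noise is returned for loss computation.
#'
#' @param emb a training-mode `tmc_embedding`.
#' @param t integer step in 0..T (t = 0 is the identity).
#' @param schedule a `noise_schedule`.
#' @param rng an RNG stream from the package's seeded-stream helper, or an
#'   integer seed.
#' @return list with `emb` (noised embedding) and `eps` (list `r`, `h`
#'   over masked atoms).
#' @export
forward_diffuse <- function(emb, t, schedule, rng = 1L) {
  stopifnot(inherits(emb, "tmc_embedding"))
  if (!is.function(rng)) rng <- make_rng(rng)
  t <- as.integer(t)
  if (t < 0L || t > schedule$T)
    stop(sprintf("step t = %d outside 0..%d", t, schedule$T))
  m_rows <- which(emb$masked)
  nm <- length(m_rows)
  if (nm == 0L) stop("embedding has no masked atoms")
  a <- schedule$alpha[t + 1L]
  s <- schedule$sigma[t + 1L]
  eps_r <- matrix(rng("norm", nm * 3L), nm, 3)
  eps_h <- matrix(rng("norm", nm * ncol(emb$h_a)), nm, ncol(emb$h_a))
  emb$coords[m_rows, ] <- a * emb$coords[m_rows, , drop = FALSE] + s * eps_r
  emb$h_a[m_rows, ] <- a * emb$h_a[m_rows, , drop = FALSE] + s * eps_h
  list(emb = emb, eps = list(r = eps_r, h = eps_h))
}

## clip ranges applied to the denoised estimate of the clean signal
## (coordinates: maximum radius from the metal; h: per-channel box)
.x0_clip <- list(r = c(0, 15), h = c(-2, 3))

#' Generate ligands by ancestral sampling under a frozen context
#'
#' Placeholder atoms are initialised from a standard normal and denoised
#' over the reverse trajectory of the schedule; only the masked
#' coordinates and atom-type channels are updated, the context is frozen
#' and returned byte-identical. Atom types are decoded by argmax at the
#' end (ties toward the lowest channel index).
#'
#' Noise is drawn per generated ligand from independent substreams of the
#' seed (adding a ligand does not perturb earlier ligands' draws), in a
#' context-canonical SO(3) frame so that sampling commutes with rigid
#' rotations of the context.
#'
#' @param context a `tmc_context`.
#' @param ldg integer partition: denticity per generated ligand (must sum
#'   to the context's free coordination number).
#' @param sizes heavy-atom count per generated ligand.
#' @param model a trained `tmcdiff_model`.
#' @param seed integer seed.
#' @param steps number of reverse steps (default: the model schedule's T).
#' @return object of class `tmc_generated`: `elements`, `coords` (full
#'   assembled structure, original frame), `context_rows`, `gen_rows`
#'   (row indices per generated ligand), `ldg`, `complex` (a `tmc`, or
#'   NULL when the raw output cannot be interpreted as a valid complex,
#'   e.g. a generated atom decoded to a metal) and `seed`.
#' @export
sample_ligands <- function(context, ldg, sizes, model, seed = 1L,
                           steps = NULL) {
  stopifnot(inherits(context, "tmc_context"), inherits(model, "tmcdiff_model"))
  ldg <- sort(as.integer(ldg), decreasing = TRUE)
  cn_free <- context$cn_target - context$cn_c
  if (sum(ldg) != cn_free)
    stop(tmcdiff_error("denticity_budget", sprintf(
      "denticity budget mismatch: sum(ldg) = %d but CN_g = %d",
      sum(ldg), cn_free)))
  sched <- model$schedule
  if (!is.null(steps) && steps != sched$T)
    sched <- make_schedule(steps, sched$kind)
  T_ <- sched$T

  emb <- build_embedding(context$complex, context$masked, ldg = ldg,
                         sizes = sizes, l_max = model$cfg$l_max)
  if (!identical(emb$vocab[seq_len(model$cfg$m)], model$vocab))
    stop("model/context element vocabulary mismatch")
  m <- model$cfg$m
  ctx_rows <- which(!emb$masked)
  Q <- context_frame(emb$coords[setdiff(ctx_rows, emb$metal_row), , drop = FALSE])

  ## pre-draw all noise per ligand substream: init + T reverse-step draws
  gen <- emb$gen_rows
  nm_tot <- sum(emb$masked)
  r_cur <- matrix(0, nm_tot, 3)
  h_cur <- matrix(0, nm_tot, m)
  noise_r <- vector("list", length(gen))
  noise_h <- vector("list", length(gen))
  off <- 0L
  for (g in seq_along(gen)) {
    ng <- length(gen[[g]])
    rg <- make_rng(substream_seed(seed, g))
    z0r <- matrix(rg("norm", ng * 3L), ng, 3) %*% t(Q)
    z0h <- matrix(rg("norm", ng * m), ng, m)
    rows <- off + seq_len(ng)
    r_cur[rows, ] <- z0r
    h_cur[rows, ] <- z0h
    noise_r[[g]] <- array(rg("norm", T_ * ng * 3L), c(T_, ng, 3L))
    noise_h[[g]] <- array(rg("norm", T_ * ng * m), c(T_, ng, m))
    off <- off + ng
  }

  m_rows <- which(emb$masked)
  emb$coords[m_rows, ] <- r_cur
  emb$h_a[m_rows, ] <- h_cur

  for (t in T_:1L) {
    ab_t <- sched$alpha[t + 1L]; sb_t <- sched$sigma[t + 1L]
    ab_s <- sched$alpha[t];      sb_s <- sched$sigma[t]
    eps_hat <- predict_noise(emb, t, model, T_override = T_)
    x0_r <- (emb$coords[m_rows, , drop = FALSE] - sb_t * eps_hat$r) / ab_t
    x0_h <- (emb$h_a[m_rows, , drop = FALSE] - sb_t * eps_hat$h) / ab_t
    ## clip the clean-signal estimate: by row norm for coordinates (a
    ## per-axis box would break rotational equivariance), per channel for
    ## atom types
    nrm <- sqrt(rowSums(x0_r^2))
    shrink <- pmin(1, .x0_clip$r[2] / pmax(nrm, 1e-12))
    x0_r <- x0_r * shrink
    x0_h <- pmin(pmax(x0_h, .x0_clip$h[1]), .x0_clip$h[2])
    if (!all(is.finite(x0_r)) || !all(is.finite(x0_h)))
      stop(tmcdiff_error("numerical",
        sprintf("non-finite values in reverse trajectory at step %d", t)))
    a_ts <- ab_t / ab_s
    s_ts2 <- max(sb_t^2 - a_ts^2 * sb_s^2, 0)
    denom <- max(sb_t^2, 1e-12)
    c_xt <- a_ts * sb_s^2 / denom
    c_x0 <- ab_s * s_ts2 / denom
    pvar <- s_ts2 * sb_s^2 / denom
    mu_r <- c_xt * emb$coords[m_rows, , drop = FALSE] + c_x0 * x0_r
    mu_h <- c_xt * emb$h_a[m_rows, , drop = FALSE] + c_x0 * x0_h
    if (t > 1L) {
      off <- 0L
      for (g in seq_along(gen)) {
        ng <- length(gen[[g]])
        rows <- off + seq_len(ng)
        zr <- matrix(noise_r[[g]][t, , ], ng, 3) %*% t(Q)
        zh <- matrix(noise_h[[g]][t, , ], ng, m)
        mu_r[rows, ] <- mu_r[rows, ] + sqrt(pvar) * zr
        mu_h[rows, ] <- mu_h[rows, ] + sqrt(pvar) * zh
        off <- off + ng
      }
    }
    emb$coords[m_rows, ] <- mu_r
    emb$h_a[m_rows, ] <- mu_h
  }

  ## decode and assemble in the original (untranslated) frame
  x <- context$complex
  keep_atoms <- which(!(x$ligand_assignment %in% context$masked))
  dec <- max.col(emb$h_a[m_rows, seq_len(m), drop = FALSE], ties.method = "first")
  gen_elements <- model$vocab[dec]
  gen_coords <- sweep(emb$coords[m_rows, , drop = FALSE], 2,
                      -x$coords[x$metal_index, ])
  elements <- c(x$elements[keep_atoms], gen_elements)
  coords <- rbind(x$coords[keep_atoms, , drop = FALSE], gen_coords)
  ngc <- length(keep_atoms)
  gen_rows_out <- lapply(seq_along(gen), function(g)
    ngc + which(rep(seq_along(gen), lengths(gen)) == g))
  cx <- tryCatch(
    suppressWarnings(tmc(elements, coords,
                         source_id = sprintf("%s_gen_seed%d", x$source_id, seed))),
    error = function(e) NULL)
  structure(list(
    elements = elements, coords = coords,
    context_rows = seq_len(ngc), gen_rows = gen_rows_out,
    ldg = ldg, sizes = sizes, seed = seed, complex = cx
  ), class = "tmc_generated")
}

#' @export
print.tmc_generated <- function(x, ...) {
  cat(sprintf("<tmc_generated> %d atoms (%d generated in %d ligand(s)), ldg = %s%s\n",
              length(x$elements), sum(lengths(x$gen_rows)), length(x$gen_rows),
              ldg_string(x$ldg),
              if (is.null(x$complex)) " [not interpretable as a complex]" else ""))
  invisible(x)
}
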