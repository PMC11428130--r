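#' Build the point-cloud embedding of a complex
#'
#' Tensorises a complex as `x = [r, h_a, h_L, h_c]`: coordinates (metal
#' translated to the origin), one-hot atom types over the heavy-element
#' vocabulary, one-hot ligand codes, and one-hot denticity classes (1-6;
#' every atom carries the denticity of the ligand it belongs to, the metal
#' carries the total coordination number). The stored feature scaling
#' factors are (0.1, 0.25, 1.0) for (r, h_a, h_Lc); they are applied at
#' featurization, not to the stored tensors.
#'
#' Two modes exist. In *training* mode (`ldg = NULL`) all original atoms
#' are kept and the atoms of `masked_ligands` are flagged for diffusion.
#' In *generation* mode (`ldg` given) the masked ligands are replaced by
#' `sizes[i]` placeholder atoms per generated ligand, whose coordinates
#' and atom types are unset until the sampler initialises them; `h_c`
#' carries the assigned denticity of each generated ligand.
#'
#' @param x a `tmc` object.
#' @param masked_ligands integer vector of ligand indices to diffuse or
#'   replace (non-empty).
#' @param ldg integer partition of the freed coordination number (one
#'   denticity per generated ligand), or NULL for training mode.
#' @param sizes heavy-atom count per generated ligand (generation mode).
#' @param l_max maximum number of ligand codes (column 1 is the metal).
#' @return an object of class `tmc_embedding`.
#' @export
build_embedding <- function(x, masked_ligands, ldg = NULL, sizes = NULL,
                            l_max = 12L) {
  stopifnot(inherits(x, "tmc"))
  l <- length(x$ligands)
  masked_ligands <- sort(unique(as.integer(masked_ligands)))
  if (length(masked_ligands) == 0L)
    stop(tmcdiff_error("nothing_to_generate",
      "masked ligand set is empty: nothing to diffuse or generate"))
  if (any(masked_ligands < 1L | masked_ligands > l))
    stop("masked ligand index out of range")
  dent <- vapply(x$ligands, function(li) li$denticity, integer(1))
  if (any(dent == 0L)) {
    warning("ligand(s) with denticity 0 present; clamping their denticity class to 1")
    dent[dent == 0L] <- 1L
  }
  cn_g <- sum(dent[masked_ligands])
  cn_total <- sum(dent)

  gen_mode <- !is.null(ldg)
  if (gen_mode) {
    ldg <- sort(as.integer(ldg), decreasing = TRUE)
    if (sum(ldg) != cn_g)
      stop(tmcdiff_error("denticity_budget",
        sprintf("denticity budget mismatch: sum(ldg) = %d but CN_g = %d",
                sum(ldg), cn_g)))
    if (is.null(sizes) || length(sizes) != length(ldg))
      stop("sizes must give one heavy-atom count per generated ligand")
    sizes <- as.integer(sizes)
    ## polydentate ligands need roomy bodies: a bidentate with only 3
    ## atoms tends to come out monodentate, so warn below 2x denticity
    low <- sizes < ldg | (ldg >= 2L & sizes < 2L * ldg)
    if (any(low))
      warning(sprintf(
        "ligand size below denticity requirement for generated ligand(s) %s; generation proceeds but the assigned denticity may not be realised",
        paste(which(low), collapse = ", ")))
  }

  vocab <- element_vocabulary()
  extra <- setdiff(unique(x$elements), vocab)
  vocab <- c(vocab, extra)
  shift <- x$coords[x$metal_index, ]

  if (!gen_mode) {
    keep_atoms <- seq_along(x$elements)
    lig_of <- x$ligand_assignment
    elements <- x$elements
    coords <- sweep(x$coords, 2, shift)
    masked_flag <- lig_of %in% masked_ligands
    dent_of <- ifelse(lig_of == 0L, min(cn_total, 6L), dent[pmax(lig_of, 1L)])
    gen_rows <- split(which(masked_flag), lig_of[masked_flag])
    lig_code <- lig_of   # 0 = metal
  } else {
    ctx_atoms <- which(!(x$ligand_assignment %in% masked_ligands))
    elements <- c(x$elements[ctx_atoms], rep(NA_character_, sum(sizes)))
    coords <- rbind(sweep(x$coords[ctx_atoms, , drop = FALSE], 2, shift),
                    matrix(NA_real_, sum(sizes), 3))
    lig_ctx <- x$ligand_assignment[ctx_atoms]
    ## renumber context ligands 1..k, generated ligands k+1..
    ctx_ids <- sort(unique(lig_ctx[lig_ctx > 0L]))
    lig_code <- c(match(lig_ctx, ctx_ids), rep(seq_along(ldg) + length(ctx_ids),
                                               times = sizes))
    lig_code[is.na(lig_code)] <- 0L   # metal
    dent_ctx <- ifelse(lig_ctx == 0L, min(cn_total, 6L), dent[pmax(lig_ctx, 1L)])
    dent_of <- c(dent_ctx, rep(ldg, times = sizes))
    masked_flag <- c(rep(FALSE, length(ctx_atoms)),
                     rep(TRUE, sum(sizes)))
    gen_rows <- split(which(masked_flag),
                      lig_code[masked_flag])
  }

  n_codes <- max(lig_code) + 1L   # + metal code
  if (n_codes > l_max)
    stop(tmcdiff_error("context_overflow", sprintf(
      "%d ligand codes needed but l_max = %d", n_codes, l_max)))

  n <- length(elements)
  h_a <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  known <- !is.na(elements)
  h_a[cbind(which(known), match(elements[known], vocab))] <- 1
  h_a[!known, ] <- NA_real_
  h_L <- matrix(0, n, l_max)
  h_L[cbind(seq_len(n), lig_code + 1L)] <- 1
  dent_of <- pmin(pmax(dent_of, 1L), 6L)
  h_c <- matrix(0, n, 6L)
  h_c[cbind(seq_len(n), dent_of)] <- 1

  structure(list(
    elements = elements, coords = coords,
    h_a = h_a, h_L = h_L, h_c = h_c,
    masked = masked_flag,
    metal_row = which(lig_code == 0L),
    ligand_code = lig_code,
    gen_rows = gen_rows,
    ldg = if (gen_mode) ldg else sort(dent[masked_ligands], decreasing = TRUE),
    cn_g = cn_g, cn_total = cn_total,
    vocab = vocab,
    scaling = c(r = 0.1, h_a = 0.25, h_Lc = 1.0),
    metal_shift = shift,
    source_id = x$source_id
  ), class = "tmc_embedding")
}

#' @export
print.tmc_embedding <- function(x, ...) {
  cat(sprintf(
    "<tmc_embedding> %d atoms (%d masked), %d ligand codes, CN_g = %d, ldg = %s\n",
    length(x$elements), sum(x$masked), max(x$ligand_code), x$cn_g,
    ldg_string(x$ldg)))
  invisible(x)
}

#' Decode an embedding back to elements and ligand assignment
#'
#' Atom types by argmax over `h_a`, ligand codes by argmax over `h_L`
#' (ties resolved toward the lowest channel index).
#'
#' @param emb a `tmc_embedding` with defined `h_a`.
#' @return list with `elements` and `ligand_assignment` (0 = metal).
#' @export
decode_embedding <- function(emb) {
  stopifnot(inherits(emb, "tmc_embedding"))
  ia <- max.col(emb$h_a, ties.method = "first")
  il <- max.col(emb$h_L, ties.method = "first")
  list(elements = emb$vocab[ia], ligand_assignment = il - 1L)
}

#' Freeze the context of a complex for scaffold-conditioned generation
#'
#' The context is the metal plus the ligands *not* being regenerated. It
#' is immutable during sampling; the sampler copies the context atoms
#' into its output byte-identically.
#'
#' @param x a `tmc` object.
#' @param masked_ligands ligand indices to drop/regenerate (possibly all).
#' @param cn_target total coordination number of the target complex
#'   (default: the coordination number of `x`).
#' @return an object of class `tmc_context`.
#' @export
tmc_context <- function(x, masked_ligands, cn_target = NULL) {
  stopifnot(inherits(x, "tmc"))
  l <- length(x$ligands)
  masked_ligands <- sort(unique(as.integer(masked_ligands)))
  if (any(masked_ligands < 1L | masked_ligands > l))
    stop("masked ligand index out of range")
  dent <- vapply(x$ligands, function(li) li$denticity, integer(1))
  if (is.null(cn_target)) cn_target <- sum(dent)
  structure(list(
    complex = x,
    masked = masked_ligands,
    cn_c = sum(dent) - sum(dent[masked_ligands]),
    cn_g = sum(dent[masked_ligands]),
    cn_target = cn_target
  ), class = "tmc_context")
}

#' @export
print.tmc_context <- function(x, ...) {
  cat(sprintf("<tmc_context> %s centre, CN_c = %d, CN_g = %d\n",
              x$complex$elements[x$complex$metal_index],
              x$cn_target - x$cn_g, x$cn_g))
  invisible(x)
}
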