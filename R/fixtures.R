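## Deterministic synthetic fixture corpora.
##
## Template ligands are defined "as coordinated": coordinates live in a
## local frame with the metal at the origin and donors on ideal
## coordination vectors, so placing a ligand is a rigid rotation of the
## whole template. Bond distances are chosen so that perception with the
## default tolerances reproduces the intended connectivity and no
## non-donor atom falls inside the metal-donor cutoff.

.template_library <- local({
  ## monodentate bodies extend along +z (donor toward the metal at origin)
  hex <- function() {
    ## pyridine-like ring in the xz-plane, N at (0, 0, 2)
    th <- c(0, 60, 120, 240, 300) * pi / 180
    rbind(c(0, 0, 2),
          cbind(1.39 * sin(th), 0, 3.39 + 1.39 * cos(th)))
  }
  arc2 <- function(u, v) {
    ## two bridging carbons on the great-circle arc between unit vectors
    ## u, v at radius 3.0 (outside the metal-donor cutoff for carbon)
    w <- (v - sum(u * v) * u) / sqrt(1 - sum(u * v)^2)
    rbind(3.0 * (u * cos(pi / 6) + w * sin(pi / 6)),
          3.0 * (u * cos(pi / 3) + w * sin(pi / 3)))
  }
  ez <- c(0, 0, 1); ex <- c(1, 0, 0); ey <- c(0, 1, 0)
  chelate4 <- function(el_donor) {
    ## ethylenediamine/glycolato-like chelate: donor-C-C-donor with the
    ## donors on +z and +x at 2.0 and the backbone on the connecting arc
    list(elements = c(el_donor, "C", "C", el_donor),
         coords = rbind(2.0 * ez, arc2(ez, ex), 2.0 * ex),
         donors = c(1L, 4L))
  }
  tpl <- list(
    aqua      = list(elements = "O",  coords = rbind(c(0, 0, 2.0)),  donors = 1L),
    ammine    = list(elements = "N",  coords = rbind(c(0, 0, 2.0)),  donors = 1L),
    chloro    = list(elements = "Cl", coords = rbind(c(0, 0, 2.3)),  donors = 1L),
    ## diatomic distances are kept near 1.3 (long for a triple bond) so a
    ## jittered bond never drops under the 0.7x covalent-sum clash floor
    carbonyl  = list(elements = c("C", "O"),
                     coords = rbind(c(0, 0, 2.0), c(0, 0, 3.28)), donors = 1L),
    cyano     = list(elements = c("C", "N"),
                     coords = rbind(c(0, 0, 2.0), c(0, 0, 3.28)), donors = 1L),
    pyridyl   = list(elements = c("N", rep("C", 5)), coords = hex(), donors = 1L),
    thioether = list(elements = c("S", "C", "C"),
                     coords = rbind(c(0, 0, 2.3), c(1.45, 0, 3.37),
                                    c(-1.45, 0, 3.37)), donors = 1L),
    en        = chelate4("N"),
    glyox     = chelate4("O"),
    dien      = list(elements = c("N", "C", "C", "N", "C", "C", "N"),
                     coords = rbind(2.0 * ez, arc2(ez, ex), 2.0 * ex,
                                    arc2(ex, ey), 2.0 * ey),
                     donors = c(1L, 4L, 7L)),
    trieth    = list(elements = c("O", "C", "C", "O", "C", "C", "O"),
                     coords = rbind(2.0 * ez, arc2(ez, ex), 2.0 * ex,
                                    arc2(ex, ey), 2.0 * ey),
                     donors = c(1L, 4L, 7L)),
    tetraaza  = list(elements = c("N", "C", "C", "N", "C", "C", "N", "C", "C", "N"),
                     coords = rbind(2.0 * ez, arc2(ez, ex), 2.0 * ex,
                                    arc2(ex, ey), 2.0 * ey,
                                    arc2(ey, -ex), 2.0 * (-ex)),
                     donors = c(1L, 4L, 7L, 10L)),
    ## crown-ether-like hexadentate wrapping all six octahedral vertices
    hexaoxa   = list(elements = c("O", "C", "C", "O", "C", "C", "O", "C", "C",
                                  "O", "C", "C", "O", "C", "C", "O"),
                     coords = rbind(2.0 * ez, arc2(ez, ex), 2.0 * ex,
                                    arc2(ex, ey), 2.0 * ey,
                                    arc2(ey, -ex), 2.0 * (-ex),
                                    arc2(-ex, -ey), 2.0 * (-ey),
                                    arc2(-ey, -ez), 2.0 * (-ez)),
                     donors = c(1L, 4L, 7L, 10L, 13L, 16L))
  )
  lapply(tpl, function(t) {
    t$denticity <- length(t$donors)
    t$size <- length(t$elements)
    t
  })
})

#' Fixture ligand templates
#'
#' @param name template name; `ligand_template()` with no argument lists
#'   the available templates with their denticities and sizes.
#' @return a template (list with `elements`, `coords`, `donors`,
#'   `denticity`, `size`) or, with no argument, a data frame catalogue.
#' @export
ligand_template <- function(name) {
  if (missing(name)) {
    return(data.frame(
      name = names(.template_library),
      denticity = vapply(.template_library, `[[`, integer(1), "denticity"),
      size = vapply(.template_library, `[[`, integer(1), "size"),
      row.names = NULL))
  }
  t <- .template_library[[name]]
  if (is.null(t)) stop("unknown ligand template: ", name)
  t$name <- name
  t
}

.geometry_vectors <- list(
  octahedral = rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
                     c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1)),
  trigonal_planar = rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                          c(-0.5, -sqrt(3) / 2, 0)),
  tetrahedral = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                      c(-1, -1, 1)) / sqrt(3),
  square_planar = rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)),
  trigonal_bipyramidal = rbind(c(0, 0, 1), c(1, 0, 0),
                               c(-0.5, sqrt(3) / 2, 0),
                               c(-0.5, -sqrt(3) / 2, 0), c(0, 0, -1)),
  square_pyramidal = rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
                           c(-1, 0, 0), c(0, -1, 0))
)

## assign coordination vertices to a template: first available (ordered)
## vertex subset whose pairwise angles match the template's donor angles
## within `tol_deg`
assign_vertices <- function(template, vertices, available, tol_deg = 20) {
  k <- template$denticity
  donors <- template$coords[template$donors, , drop = FALSE]
  du <- donors / sqrt(rowSums(donors^2))
  want <- acos(pmin(1, pmax(-1, du %*% t(du))))
  if (k == 1L) return(available[1L])
  subsets <- utils::combn(available, k, simplify = FALSE)
  for (s in subsets) {
    perms <- permutations_of(s)
    for (p in perms) {
      vu <- vertices[p, , drop = FALSE]
      got <- acos(pmin(1, pmax(-1, vu %*% t(vu))))
      if (max(abs(got - want)) >= tol_deg * pi / 180) next
      ## angles can match a mirror image; require a proper rigid fit too
      R <- kabsch_rotation(du, vu)
      if (max(sqrt(rowSums((du %*% t(R) - vu)^2))) < 2 * sin(tol_deg * pi / 360))
        return(p)
    }
  }
  stop(tmcdiff_error("geometry_mismatch",
    "no vertex assignment matches the template's donor angles"))
}

permutations_of <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Build a toy transition-metal complex from template ligands
#'
#' Donor atoms are placed on the ideal coordination vectors of the chosen
#' geometry at their template metal distances (about 2.0 Angstrom), ligand
#' bodies are rigidly attached, and a small Gaussian jitter is applied to
#' every ligand atom. Deterministic for a fixed seed.
#'
#' @param metal metal element symbol.
#' @param templates list of templates (from [ligand_template()]) or a
#'   character vector of template names.
#' @param geometry one of `"octahedral"`, `"trigonal_planar"`,
#'   `"tetrahedral"`, `"square_planar"`, `"trigonal_bipyramidal"`,
#'   `"square_pyramidal"`.
#' @param seed integer seed.
#' @param jitter Gaussian jitter amplitude in Angstrom (default 0.05).
#' @param rotate apply a uniform random global rotation.
#' @param source_id provenance tag.
#' @return a `tmc` object.
#' @export
make_toy_complex <- function(metal, templates, geometry = "octahedral",
                             seed = 1L, jitter = 0.05, rotate = FALSE,
                             source_id = NULL) {
  if (is.character(templates)) templates <- lapply(templates, ligand_template)
  verts <- .geometry_vectors[[geometry]]
  if (is.null(verts))
    stop("unknown geometry: ", geometry, " (expected one of ",
         paste(names(.geometry_vectors), collapse = ", "), ")")
  dent <- vapply(templates, `[[`, integer(1), "denticity")
  if (sum(dent) != nrow(verts))
    stop(tmcdiff_error("geometry_mismatch", sprintf(
      "denticity sum %d incompatible with %s geometry (CN %d)",
      sum(dent), geometry, nrow(verts))))
  rng <- make_rng(seed)
  available <- seq_len(nrow(verts))
  elements <- metal
  coords <- rbind(c(0, 0, 0))
  for (li in seq_along(templates)) {
    tpl <- templates[[li]]
    sel <- assign_vertices(tpl, verts, available)
    available <- setdiff(available, sel)
    donors <- tpl$coords[tpl$donors, , drop = FALSE]
    du <- donors / sqrt(rowSums(donors^2))
    if (tpl$denticity == 1L) {
      R <- rotation_between(du[1, ], verts[sel, ])
      ## twist the body about the donor axis to keep ring planes apart
      R <- rotation_about(verts[sel, ], (li - 1) * pi / 2) %*% R
    } else {
      R <- kabsch_rotation(du, verts[sel, , drop = FALSE])
    }
    placed <- tpl$coords %*% t(R)
    placed <- placed + jitter * matrix(rng("norm", length(placed)),
                                       nrow(placed), 3)
    elements <- c(elements, tpl$elements)
    coords <- rbind(coords, placed)
  }
  if (rotate) {
    Q <- random_rotation(rng)
    coords <- coords %*% t(Q)
  }
  if (is.null(source_id))
    source_id <- sprintf("toy_%s_%s_seed%d", metal, geometry, seed)
  tmc(elements, coords, source_id = source_id)
}

#' Generate a deterministic toy corpus with masking expansion
#'
#' Draws `n` octahedral complexes over the seven training metals with
#' random template mixtures (the joint size/denticity distribution has
#' polydentate ligands systematically larger than monodentate ones) and
#' expands each complex by multi-ligand masking.
#'
#' @param n number of complexes.
#' @param seed integer seed.
#' @param all_monodentate restrict ligands to monodentate templates (each
#'   complex then expands to 63 masking samples).
#' @return list with `complexes` (list of `tmc`) and `samples` (masking
#'   expansion from [expand_training_set()]).
#' @export
make_corpus <- function(n, seed = 1L, all_monodentate = FALSE) {
  stopifnot(n >= 1)
  rng <- make_rng(seed)
  cat_ <- ligand_template()
  mono <- cat_$name[cat_$denticity == 1]
  complexes <- vector("list", n)
  for (i in seq_len(n)) {
    metal <- .training_metals[rng("int", 1L, lo = 1L, hi = 7L)]
    if (all_monodentate) {
      names_ <- mono[rng("int", 6L, lo = 1L, hi = length(mono))]
    } else {
      ## draw templates until denticities sum to exactly 6
      names_ <- character(0); left <- 6L
      while (left > 0L) {
        ok <- cat_$name[cat_$denticity <= left]
        pick <- ok[rng("int", 1L, lo = 1L, hi = length(ok))]
        names_ <- c(names_, pick)
        left <- left - cat_$denticity[cat_$name == pick]
      }
    }
    complexes[[i]] <- make_toy_complex(
      metal, names_, geometry = "octahedral",
      seed = as.integer(substream_seed(seed, i)),
      source_id = sprintf("corpus_seed%d_%03d", seed, i))
  }
  samples <- expand_training_set(complexes, assign_sizes = TRUE,
                                 seed = as.integer(substream_seed(seed, 0L)))
  list(complexes = complexes, samples = samples)
}

#' Parameter-recovery training task
#'
#' Builds complexes in which the masked ligand is always a single nitrogen
#' atom at exactly 2.0 Angstrom from the metal, trans to a sulfur marker
#' ligand; the four remaining context ligands are jittered oxygens. The
#' whole complex is randomly rotated per sample, so the only thing a
#' denoiser can learn is "place one atom at 2.0 Angstrom trans to the
#' sulfur". Metals cycle over Fe, Co, Ni (balanced).
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @return list of samples; each has `complex` (a `tmc`), `masked`
#'   (the ligand index of the nitrogen to regenerate) and `target_u`
#'   (unit vector from metal to the target position).
#' @export
make_recovery_task <- function(n = 500L, seed = 1L) {
  metals <- c("Fe", "Co", "Ni")
  rng <- make_rng(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    metal <- metals[((i - 1L) %% 3L) + 1L]
    ## sulfur marker on +z, target nitrogen exactly trans at 2.0
    s_pos <- c(0, 0, 2.3)
    n_pos <- c(0, 0, -2.0)
    o_dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
    o_pos <- 2.0 * o_dirs + 0.05 * matrix(rng("norm", 12L), 4, 3)
    Q <- random_rotation(rng)
    coords <- rbind(c(0, 0, 0), s_pos, o_pos, n_pos) %*% t(Q)
    el <- c(metal, "S", rep("O", 4), "N")
    x <- tmc(el, coords, source_id = sprintf("recovery_%04d", i))
    ## the nitrogen is the ligand containing the last atom
    masked <- x$ligand_assignment[length(el)]
    out[[i]] <- list(complex = x, masked = masked,
                     target_u = as.numeric(Q %*% c(0, 0, -1)))
  }
  out
}
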