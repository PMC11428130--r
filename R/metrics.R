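## Generation quality metrics and structural analyses.
##
## All ratios are reported with exact integer numerators and denominators
## so that ratios of concatenated batches equal count-weighted means.

ratio_ <- function(num, den, flags = NULL) {
  list(value = if (den > 0) num / den else NA_real_,
       num = as.integer(num), den = as.integer(den), flags = flags)
}

## normalise a "ligand" to list(elements, coords)
as_ligand_block <- function(x) {
  if (is.list(x) && !is.null(x$elements) && !is.null(x$coords) &&
      !inherits(x, "tmc"))
    return(list(elements = x$elements, coords = as.matrix(x$coords)))
  stop("expected a ligand block with $elements and $coords")
}

#' Extract ligands of a complex as element/coordinate blocks
#'
#' @param x a `tmc` or `tmc_generated` object.
#' @param generated_only for `tmc_generated`, return only the generated
#'   ligands (default) rather than all ligands.
#' @return list of ligand blocks (`elements`, `coords`).
#' @export
extract_ligands <- function(x, generated_only = TRUE) {
  if (inherits(x, "tmc")) {
    return(lapply(x$ligands, function(l)
      list(elements = x$elements[l$atoms],
           coords = x$coords[l$atoms, , drop = FALSE])))
  }
  if (inherits(x, "tmc_generated")) {
    rows <- if (generated_only) x$gen_rows
            else c(list(x$context_rows[-1]), x$gen_rows)
    return(lapply(rows, function(r)
      list(elements = x$elements[r], coords = x$coords[r, , drop = FALSE])))
  }
  stop("expected a tmc or tmc_generated object")
}

## internal bond graph of a ligand block (metal-free)
ligand_graph <- function(lig, tolerance = 0.4) {
  n <- length(lig$elements)
  b <- tryCatch(perceive_bonds(lig, tolerance = tolerance),
                error = function(e) NULL)
  list(n = n, bonds = b)
}

#' Chemical validity of generated ligands
#'
#' A ligand is valid when every atom is a non-metal element of the
#' curated set and no atom's internal connectivity exceeds its maximum
#' plausible valence (hydrogen-free degree screen on the perceived bond
#' graph; e.g. a five-coordinate carbon fails).
#'
#' @param ligands list of ligand blocks (see [extract_ligands()]).
#' @param tolerance bond-perception tolerance.
#' @return ratio record: `value`, `num`, `den` and per-ligand `flags`.
#' @export
ligand_validity <- function(ligands, tolerance = 0.4) {
  if (length(ligands) == 0L) stop("empty ligand list")
  ok <- vapply(ligands, function(l) {
    l <- as_ligand_block(l)
    if (length(l$elements) == 0L) return(FALSE)
    if (!all(l$elements %in% names(.max_valence))) return(FALSE)
    g <- ligand_graph(l, tolerance)
    if (is.null(g$bonds)) return(FALSE)
    deg <- tabulate(c(g$bonds[, 1], g$bonds[, 2]), nbins = g$n)
    all(deg <= .max_valence[l$elements])
  }, logical(1))
  ratio_(sum(ok), length(ok), flags = ok)
}

#' Connectivity of valid ligands
#'
#' A ligand counts as connected when its internal bond graph has exactly
#' one component. By the metric's definition the denominator is the set
#' of ligands previously judged valid.
#'
#' @param valid_ligands list of ligand blocks already judged valid.
#' @param tolerance bond-perception tolerance.
#' @return ratio record.
#' @export
ligand_connectivity <- function(valid_ligands, tolerance = 0.4) {
  if (length(valid_ligands) == 0L) return(ratio_(0L, 0L))
  ok <- vapply(valid_ligands, function(l) {
    l <- as_ligand_block(l)
    g <- ligand_graph(l, tolerance)
    if (g$n == 1L) return(TRUE)
    if (is.null(g$bonds) || nrow(g$bonds) == 0L) return(FALSE)
    gr <- igraph::make_empty_graph(g$n, directed = FALSE)
    gr <- igraph::add_edges(gr, t(g$bonds))
    igraph::components(gr)$no == 1L
  }, logical(1))
  ratio_(sum(ok), length(ok), flags = ok)
}

#' Validity of whole generated complexes
#'
#' A complex is valid iff (a) every generated ligand is chemically valid
#' and internally connected, (b) the realised total denticity equals the
#' target coordination number, (c) no inter-atomic distance falls below
#' 0.7 times the covalent-radius sum (steric clash), and (d) every
#' generated ligand has at least one donor within the metal cutoff. The
#' four rules are individually toggleable for auditability.
#'
#' @param complexes list of `tmc` or `tmc_generated` objects.
#' @param cn_target target coordination number (default 6; for plain
#'   `tmc` inputs their own coordination number is used).
#' @param checks subset of `c("ligands", "denticity", "clash", "donor")`.
#' @return ratio record with per-complex `flags`.
#' @export
complex_validity <- function(complexes, cn_target = 6L,
                             checks = c("ligands", "denticity", "clash",
                                        "donor")) {
  ok <- vapply(complexes, function(x) {
    cx <- if (inherits(x, "tmc")) x else x$complex
    if (is.null(cx)) return(FALSE)
    gen_ligs <- extract_ligands(x, generated_only = TRUE)
    target <- if (inherits(x, "tmc")) coordination_number(x)
              else if (!is.null(x$cn_target)) x$cn_target else cn_target
    if ("ligands" %in% checks) {
      lv <- ligand_validity(gen_ligs)
      if (lv$num < lv$den) return(FALSE)
      lc <- ligand_connectivity(gen_ligs)
      if (lc$num < lc$den) return(FALSE)
    }
    if ("denticity" %in% checks &&
        coordination_number(cx) != target) return(FALSE)
    if ("clash" %in% checks) {
      d <- as.matrix(stats::dist(cx$coords))
      lim <- 0.7 * (outer(covalent_radius(cx$elements),
                          covalent_radius(cx$elements), "+"))
      diag(d) <- Inf
      if (any(d < lim)) return(FALSE)
    }
    if ("donor" %in% checks) {
      ## every ligand of the assembled complex must coordinate
      dent <- vapply(cx$ligands, function(l) l$denticity, integer(1))
      if (any(dent == 0L)) return(FALSE)
    }
    TRUE
  }, logical(1))
  ratio_(sum(ok), length(ok), flags = ok)
}

#' Canonical SMILES of a ligand block
#'
#' Hydrogen-free canonical SMILES via OpenBabel, on the perceived bond
#' graph with unit bond orders (the corpus is hydrogen-stripped, so
#' strings are compared as hydrogen-free skeleton identifiers).
#'
#' @param lig a ligand block, or a list of them.
#' @return character vector of canonical SMILES (`NA` when conversion
#'   fails).
#' @export
ligand_smiles <- function(lig) {
  if (!is.null(lig$elements)) lig <- list(lig)
  vapply(lig, function(l) {
    l <- as_ligand_block(l)
    mol <- write_sdf(l$elements, l$coords, path = NULL, title = "lig")
    out <- tryCatch(
      ChemmineOB::convertFormat("SDF", "CAN", mol),
      error = function(e) NA_character_)
    if (is.na(out) || !nzchar(out)) return(NA_character_)
    strsplit(trimws(out), "[\t ]")[[1]][1]
  }, character(1))
}

#' Novelty of generated ligands
#'
#' Fraction of generated ligand strings absent from the training set
#' (exact canonical-string match; stereochemistry is not compared).
#'
#' @param generated_smiles character vector.
#' @param training_smiles character vector.
#' @return ratio record.
#' @export
novelty <- function(generated_smiles, training_smiles) {
  n <- length(generated_smiles)
  novel <- !(generated_smiles %in% training_smiles)
  ratio_(sum(novel), n, flags = novel)
}

#' Uniqueness of generated ligands
#'
#' Number of distinct ligand strings over all generated ligands.
#'
#' @param generated_smiles character vector.
#' @return ratio record.
#' @export
uniqueness <- function(generated_smiles) {
  n <- length(generated_smiles)
  ratio_(length(unique(generated_smiles)), n)
}

#' Mean metal-donor bond length of a complex
#'
#' @param x a `tmc` object.
#' @param spin_label optional label (e.g. `"HS"`/`"LS"`) carried through
#'   to batch summaries.
#' @return list with `mean` (Angstrom), `distances`, `spin_label`.
#' @export
bond_length_profile <- function(x, spin_label = NA_character_) {
  stopifnot(inherits(x, "tmc"))
  donors <- unlist(lapply(x$ligands, `[[`, "donors"))
  if (length(donors) == 0L)
    stop(tmcdiff_error("no_donors", "complex has no donor atoms"))
  m <- x$coords[x$metal_index, ]
  d <- sqrt(rowSums(sweep(x$coords[donors, , drop = FALSE], 2, m)^2))
  list(mean = mean(d), distances = d, spin_label = spin_label)
}

#' Batch metal-donor bond-length summary
#' @param complexes list of `tmc`.
#' @param spin_labels optional character vector parallel to `complexes`.
#' @return data frame with one row per complex (`mean_bond`, `spin`).
#' @export
bond_length_summary <- function(complexes, spin_labels = NULL) {
  if (is.null(spin_labels)) spin_labels <- rep(NA_character_, length(complexes))
  data.frame(
    id = vapply(complexes, function(x) x$source_id, character(1)),
    mean_bond = vapply(complexes, function(x) bond_length_profile(x)$mean,
                       numeric(1)),
    spin = spin_labels,
    stringsAsFactors = FALSE)
}

#' RMSD between two conformers after optimal superposition
#'
#' Least-squares RMSD after Kabsch rigid superposition, with the atom
#' correspondence given by input order. Element multisets must agree.
#'
#' @param a,b `tmc` objects or ligand blocks with identical atom counts.
#' @return RMSD in Angstrom.
#' @export
conformer_rmsd <- function(a, b) {
  ea <- a$elements; eb <- b$elements
  if (length(ea) != length(eb))
    stop("atom count mismatch between conformers")
  if (!identical(sort(ea), sort(eb)))
    stop("element multiset mismatch between conformers")
  xa <- as.numeric(t(a$coords))
  xb <- as.numeric(t(b$coords))
  fit <- bio3d::fit.xyz(fixed = xa, mobile = xb,
                        fixed.inds = seq_along(xa),
                        mobile.inds = seq_along(xb))
  sqrt(mean(rowSums(matrix(fit - xa, ncol = 3, byrow = TRUE)^2)))
}

#' Metric bundle for a generated batch
#'
#' Computes the five generation metrics: ligand validity, connectivity
#' (among valid ligands), complex validity, novelty against a training
#' SMILES set, and uniqueness.
#'
#' @param generated list of `tmc_generated` (or `tmc`) objects.
#' @param training_smiles character vector of training-set canonical
#'   SMILES (novelty is `NA` when omitted).
#' @return object of class `generation_report`.
#' @export
generation_report <- function(generated, training_smiles = NULL) {
  ligs <- unlist(lapply(generated, extract_ligands, generated_only = TRUE),
                 recursive = FALSE)
  lv <- ligand_validity(ligs)
  lc <- ligand_connectivity(ligs[lv$flags])
  cv <- complex_validity(generated)
  smi <- ligand_smiles(ligs)
  smi_ok <- smi[!is.na(smi)]
  nv <- if (is.null(training_smiles)) ratio_(0L, 0L)
        else novelty(smi_ok, training_smiles)
  uq <- uniqueness(smi_ok)
  structure(list(p_l_val = lv, p_l_con = lc, p_c_val = cv,
                 p_l_nov = nv, p_l_uniq = uq,
                 smiles = smi, n_complexes = length(generated)),
            class = "generation_report")
}

#' @export
print.generation_report <- function(x, ...) {
  cat(sprintf("<generation_report> %d complex(es)\n", x$n_complexes))
  for (nm in c("p_l_val", "p_l_con", "p_c_val", "p_l_nov", "p_l_uniq")) {
    r <- x[[nm]]
    cat(sprintf("  %-9s %5s  (%d/%d)\n", nm,
                ifelse(is.na(r$value), "NA", sprintf("%.3f", r$value)),
                r$num, r$den))
  }
  invisible(x)
}

#' Aggregate generation reports over independent runs
#'
#' Mean and standard deviation of each metric across runs (the usual
#' 10-independent-runs reporting protocol).
#'
#' @param reports list of `generation_report` objects.
#' @return data frame with `metric`, `mean`, `sd`, `n_runs`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1)
  metrics <- c("p_l_val", "p_l_con", "p_c_val", "p_l_nov", "p_l_uniq")
  vals <- vapply(reports, function(r)
    vapply(metrics, function(m) r[[m]]$value, numeric(1)),
    numeric(length(metrics)))
  vals <- matrix(vals, nrow = length(metrics))
  data.frame(
    metric = metrics,
    mean = rowMeans(vals),
    sd = apply(vals, 1, function(v) if (length(v) > 1) stats::sd(v) else 0),
    n_runs = length(reports),
    row.names = NULL)
}
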