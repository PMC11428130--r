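#' Mononuclear transition-metal complex
#'
#' Constructs a `tmc` object: one d-block metal centre plus hydrogen-free
#' ligand atoms with Cartesian coordinates in Angstrom. Hydrogens are
#' stripped on ingest (the modelling corpus is hydrogen-free; re-addition
#' is delegated to an external backend hook). Bonds are perceived with a
#' covalent-radius rule and ligands are the connected components of the
#' bond graph once the metal vertex is removed.
#'
#' @param elements character vector of element symbols (exactly one d-block
#'   metal; remaining elements must belong to the curated heavy-element set).
#' @param coords numeric matrix, `length(elements)` x 3, Angstrom.
#' @param source_id free-text provenance tag.
#' @param bond_tolerance tolerance (Angstrom) added to the covalent-radius
#'   sum when perceiving bonds.
#' @param metal_tolerance tolerance (Angstrom) for the metal-donor cutoff
#'   (looser than `bond_tolerance` to capture dative bonds).
#' @param strict error (rather than warn) when a ligand has no donor atom.
#' @return an object of class `tmc` with fields `elements`, `coords`,
#'   `metal_index`, `bonds`, `ligands` (list of ligand descriptors),
#'   `ligand_assignment` (per-atom ligand index, 0 for the metal) and
#'   `source_id`.
#' @examples
#' x <- tmc(c("Fe", "N", "N"),
#'          rbind(c(0, 0, 0), c(2, 0, 0), c(-2, 0, 0)))
#' x$ligands[[1]]$denticity
#' @export
tmc <- function(elements, coords, source_id = "",
                bond_tolerance = 0.4, metal_tolerance = 0.6,
                strict = FALSE) {
  stopifnot(is.character(elements), length(elements) >= 2)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(elements) || ncol(coords) != 3)
    stop("coords must be a length(elements) x 3 matrix")
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")

  keep <- elements != "H"
  elements <- elements[keep]
  coords <- coords[keep, , drop = FALSE]

  metal <- which(is_metal(elements))
  if (length(metal) != 1L)
    stop(tmcdiff_error("invalid_complex", sprintf(
      "expected exactly one d-block metal centre, found %d", length(metal))))
  nonmetal <- elements[-metal]
  bad <- setdiff(unique(nonmetal), .element_set_heavy)
  if (length(bad))
    stop(tmcdiff_error("unknown_element", sprintf(
      "element(s) outside the curated set: %s", paste(bad, collapse = ", "))))
  if (length(elements) > 200L)
    stop(tmcdiff_error("invalid_complex",
      sprintf("heavy-atom count %d exceeds 200", length(elements))))

  x <- structure(
    list(elements = elements, coords = coords, metal_index = metal,
         source_id = source_id,
         bond_tolerance = bond_tolerance, metal_tolerance = metal_tolerance),
    class = "tmc")
  x$bonds <- perceive_bonds(x, tolerance = bond_tolerance)
  x <- partition_ligands(x, strict = strict)
  x
}

#' @export
print.tmc <- function(x, ...) {
  dent <- vapply(x$ligands, function(l) l$denticity, integer(1))
  cat(sprintf("<tmc> %s complex, %d heavy atoms, %d ligand(s), CN = %d\n",
              x$elements[x$metal_index], length(x$elements),
              length(x$ligands), sum(dent)))
  cat("  denticities:", paste(dent, collapse = " "), "\n")
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' Perceive bonds by the covalent-radius rule
#'
#' Atoms i and j are bonded iff `d(i, j) <= r_cov(i) + r_cov(j) + tolerance`.
#' The bond list is symmetric and free of self-bonds.
#'
#' @param x a `tmc` object, or a list with `elements` and `coords`.
#' @param tolerance Angstrom added to the covalent-radius sum.
#' @return integer matrix with columns `i`, `j` (i < j), one row per bond.
#' @export
perceive_bonds <- function(x, tolerance = 0.4) {
  el <- x$elements
  xyz <- x$coords
  n <- length(el)
  r <- covalent_radius(el)
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(r, r, "+") + tolerance
  adj <- d <= cut
  adj[!upper.tri(adj)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  m <- cbind(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Partition non-metal atoms into ligands
#'
#' Ligands are the connected components of the perceived bond graph after
#' deleting the metal vertex, ordered by their smallest contained atom
#' index. Each ligand records its donor atoms (atoms within the
#' metal-donor cutoff) and its denticity.
#'
#' @param x a `tmc` object with perceived bonds.
#' @param strict error (instead of warn) on ligands with zero donor atoms.
#' @return `x` with `ligands` and `ligand_assignment` filled in.
#' @export
partition_ligands <- function(x, strict = FALSE) {
  n <- length(x$elements)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(x$bonds)) g <- igraph::add_edges(g, t(x$bonds))
  g <- igraph::delete_vertices(g, x$metal_index)
  comp <- igraph::components(g)$membership
  ## vertex k of the reduced graph is original atom orig[k]
  orig <- setdiff(seq_len(n), x$metal_index)
  groups <- split(orig, comp)
  groups <- groups[order(vapply(groups, min, numeric(1)))]

  assignment <- integer(n)
  ligands <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    atoms <- sort(as.integer(groups[[k]]))
    assignment[atoms] <- k
    donors <- ligand_donors(x, atoms)
    if (length(donors) == 0L) {
      msg <- sprintf("ligand %d (%s) has no atom within the metal cutoff",
                     k, paste(x$elements[atoms], collapse = ""))
      if (strict) stop(tmcdiff_error("dangling_ligand", msg)) else warning(msg)
    }
    ligands[[k]] <- list(
      atoms = atoms,
      donors = donors,
      denticity = length(donors)
    )
  }
  x$ligands <- ligands
  x$ligand_assignment <- assignment
  x
}

## donor atoms of a candidate atom set: within covalent-radius sum of the
## metal plus the (looser) metal tolerance
ligand_donors <- function(x, atoms) {
  m <- x$metal_index
  rm_ <- covalent_radius(x$elements[m])
  d <- sqrt(colSums((t(x$coords[atoms, , drop = FALSE]) - x$coords[m, ])^2))
  cut <- rm_ + covalent_radius(x$elements[atoms]) + x$metal_tolerance
  atoms[d <= cut]
}

#' Denticity of a ligand
#'
#' Counts ligand atoms lying within the metal-donor cutoff of the metal
#' centre (covalent-radius sum plus `metal_tolerance`). The coordination
#' number of the complex is the sum of its ligand denticities.
#'
#' @param x a `tmc` object.
#' @param ligand a ligand descriptor from `x$ligands`, or a ligand index.
#' @return integer denticity (0 is legal and flags a dangling ligand).
#' @export
ligand_denticity <- function(x, ligand) {
  if (is.numeric(ligand)) ligand <- x$ligands[[ligand]]
  length(ligand_donors(x, ligand$atoms))
}

#' Coordination number of a complex
#' @param x a `tmc` object.
#' @return integer, sum of ligand denticities.
#' @export
coordination_number <- function(x) {
  sum(vapply(x$ligands, function(l) l$denticity, integer(1)))
}

#' Read complexes from an XYZ file
#'
#' Standard XYZ (atom count, comment, `element x y z` lines); multi-frame
#' files yield one complex per frame. Hydrogens are stripped on ingest.
#'
#' @param path file path.
#' @param ... forwarded to [tmc()].
#' @return a `tmc` (single frame) or list of `tmc` (multi-frame).
#' @export
read_xyz <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > length(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("malformed XYZ at line %d: expected atom count", i))
    comment <- if (i + 1L <= length(lines)) trimws(lines[i + 1L]) else ""
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    el <- vapply(tok, `[[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    out[[length(out) + 1L]] <- tmc(el, xyz, source_id = comment, ...)
    i <- i + 2L + n
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Write complexes to an XYZ file
#' @param x a `tmc` or list of `tmc`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  if (inherits(x, "tmc")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (c_ in x) {
    writeLines(as.character(length(c_$elements)), con)
    writeLines(c_$source_id, con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", c_$elements,
                       c_$coords[, 1], c_$coords[, 2], c_$coords[, 3]), con)
  }
  invisible(path)
}

#' Read a V2000 SDF/MOL file
#'
#' Bonds recorded in the file are honoured; structures without a bond
#' block fall back to perception. Multi-record SDF yields a list.
#'
#' @param path file path.
#' @param ... forwarded to [tmc()].
#' @return a `tmc` or list of `tmc`.
#' @export
read_sdf <- function(path, ...) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  out <- lapply(recs, function(r) {
    r <- r[r != "$$$$"]
    if (length(r) < 4L || !nzchar(paste(trimws(r), collapse = ""))) return(NULL)
    counts <- r[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    ab <- r[5:(4 + na)]
    el <- trimws(substr(ab, 32, 34))
    xyz <- cbind(as.numeric(substr(ab, 1, 10)),
                 as.numeric(substr(ab, 11, 20)),
                 as.numeric(substr(ab, 21, 30)))
    tmc(el, xyz, source_id = trimws(r[1]), ...)
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 1L) out[[1L]] else out
}

#' Write a complex (or bare atom block) as V2000 MOL/SDF
#'
#' All bonds are written with order 1 (hydrogen-free dative-rich systems do
#' not carry reliable bond orders from geometry alone).
#'
#' @param elements character element symbols.
#' @param coords numeric n x 3 matrix.
#' @param bonds integer matrix (i, j) or NULL to perceive.
#' @param path output path, or NULL to return the text block.
#' @param title record title.
#' @return the MOL text (invisibly if written to `path`).
#' @export
write_sdf <- function(elements, coords, bonds = NULL, path = NULL,
                      title = "tmcdiff") {
  if (is.null(bonds))
    bonds <- perceive_bonds(list(elements = elements, coords = coords))
  n <- length(elements)
  hdr <- c(title, "  tmcdiff", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   coords[, 1], coords[, 2], coords[, 3], elements)
  bl <- if (nrow(bonds)) sprintf("%3d%3d  1  0  0  0  0", bonds[, 1], bonds[, 2]) else character(0)
  txt <- c(hdr, atoms, bl, "M  END", "$$$$")
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}
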