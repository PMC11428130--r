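#' Enumerate multi-ligand maskings of a complex
#'
#' One masking sample per non-empty subset of ligand indices, so a complex
#' with l ligands yields `2^l - 1` samples (63 for six ligands). Ligands
#' are treated as distinguishable by position even when chemically
#' identical. Samples are ordered by subset size, then lexicographically.
#'
#' @param x a `tmc` object with partitioned ligands.
#' @return list of masking samples; each has `parent` (source id), `masked`
#'   (integer ligand indices), `cn_g` (sum of masked-ligand denticities) and
#'   `cn_c` (context coordination number).
#' @examples
#' oct <- make_toy_complex("Fe", rep(list(ligand_template("aqua")), 6),
#'                         geometry = "octahedral", seed = 1)
#' length(enumerate_maskings(oct))  # 63
#' @export
enumerate_maskings <- function(x) {
  l <- length(x$ligands)
  if (l == 0L)
    stop(tmcdiff_error("no_ligands", "no ligands to mask"))
  dent <- vapply(x$ligands, function(li) li$denticity, integer(1))
  cn <- sum(dent)
  out <- list()
  for (k in seq_len(l)) {
    subs <- utils::combn(l, k, simplify = FALSE)
    for (s in subs) {
      out[[length(out) + 1L]] <- list(
        parent = x$source_id,
        masked = s,
        cn_g = sum(dent[s]),
        cn_c = cn - sum(dent[s])
      )
    }
  }
  out
}

#' Enumerate ligand-denticity assignments (integer partitions)
#'
#' All integer partitions of the freed coordination number `cn_g` in
#' canonical non-increasing form, ordered descending-lexicographically,
#' e.g. `enumerate_ldg(3)` gives (3), (2,1), (1,1,1). Each partition is one
#' legal assignment of denticities to the ligands to be generated; counts
#' follow the partition function p(n), so p(6) = 11 assignments exist for
#' total generation and sum(p(1..5)) = 18 for partial generation.
#'
#' @param cn_g positive integer, coordination number to be generated.
#' @return list of integer vectors (non-increasing partitions).
#' @export
enumerate_ldg <- function(cn_g) {
  cn_g <- as.integer(cn_g)
  if (length(cn_g) != 1L || is.na(cn_g) || cn_g <= 0L)
    stop(tmcdiff_error("bad_cng", "cn_g must be a positive integer"))
  if (cn_g > 6L)
    warning(sprintf("cn_g = %d exceeds 6 (octahedral); assuming a higher-coordinate target", cn_g))
  ## descending-lexicographic recursive enumeration
  rec <- function(n, maxpart) {
    if (n == 0L) return(list(integer(0)))
    out <- list()
    for (first in seq.int(min(n, maxpart), 1L)) {
      for (rest in rec(n - first, first))
        out[[length(out) + 1L]] <- c(first, rest)
    }
    out
  }
  rec(cn_g, cn_g)
}

#' Compact string form of a denticity assignment
#' @param ldg integer vector (partition), e.g. `c(2, 1)`.
#' @return string concatenating the digits, e.g. `"21"`.
#' @export
ldg_string <- function(ldg) paste(ldg, collapse = "")

#' Parse a compact denticity string
#' @param s string of digits such as `"21"` or `"111"`.
#' @return integer vector in non-increasing order.
#' @export
parse_ldg <- function(s) {
  v <- as.integer(strsplit(as.character(s), "")[[1]])
  if (anyNA(v) || any(v <= 0)) stop("malformed denticity string: ", s)
  sort(v, decreasing = TRUE)
}

#' Number of denticity assignments available for partial generation
#'
#' Partial generation leaves at least one context ligand, so the freed
#' coordination number ranges over 1..5 for an octahedral complex; the
#' count is `sum(p(1..5)) = 18`.
#'
#' @return integer 18.
#' @export
count_partial_ldg <- function() {
  sum(vapply(1:5, function(n) length(enumerate_ldg(n)), integer(1)))
}

#' Count generation variations of a reference complex
#'
#' Sums, over every non-empty ligand-subset masking, the number of integer
#' partitions of that masking's freed coordination number. A reference
#' bearing two tridentate ligands yields 17 (= p(3) + p(3) + p(6)).
#'
#' @param x a `tmc` object.
#' @return integer count.
#' @export
count_variations <- function(x) {
  ms <- enumerate_maskings(x)
  sum(vapply(ms, function(m) length(enumerate_ldg(m$cn_g)), integer(1)))
}

#' Expand a corpus by multi-ligand masking
#'
#' Concatenates `enumerate_maskings()` over the input complexes, attaching
#' stable provenance ids and, optionally, sampled ligand sizes that follow
#' the corpus size rule (monodentate/bidentate ligands below 10 heavy
#' atoms, polydentate ligands 10-30).
#'
#' @param complexes list of `tmc` objects.
#' @param assign_sizes draw heavy-atom sizes for the masked ligands.
#' @param seed integer seed for size sampling.
#' @return list of masking samples (fields as in [enumerate_maskings()],
#'   plus `complex_index` and optionally `sizes`). Complexes that fail
#'   partitioning are skipped with a warning.
#' @export
expand_training_set <- function(complexes, assign_sizes = FALSE, seed = 1L) {
  out <- list()
  rng <- make_rng(seed)
  for (ci in seq_along(complexes)) {
    ms <- tryCatch(enumerate_maskings(complexes[[ci]]), error = function(e) {
      warning(sprintf("skipping complex %d: %s", ci, conditionMessage(e)))
      NULL
    })
    if (is.null(ms)) next
    for (m in ms) {
      m$complex_index <- ci
      if (!nzchar(m$parent)) m$parent <- sprintf("complex_%d", ci)
      if (assign_sizes) {
        dent <- vapply(complexes[[ci]]$ligands[m$masked],
                       function(l) l$denticity, integer(1))
        m$sizes <- draw_ligand_sizes(dent, rng)
      }
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

#' Draw heavy-atom ligand sizes consistent with the corpus size rule
#'
#' Denticity below 3 draws uniformly from 1..9 heavy atoms; denticity 3 or
#' more draws uniformly from 10..30 (polydentate ligands are larger).
#'
#' @param denticities integer vector.
#' @param rng an RNG stream from `make_rng()`, or an integer seed.
#' @return integer vector of sizes.
#' @export
draw_ligand_sizes <- function(denticities, rng = 1L) {
  if (!is.function(rng)) rng <- make_rng(rng)
  vapply(denticities, function(d) {
    if (d < 3) rng("int", 1L, lo = max(1L, d), hi = 9L)
    else rng("int", 1L, lo = 10L, hi = 30L)
  }, integer(1))
}

#' Write masking samples as a JSON-lines manifest
#' @param samples list of masking samples.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(samples, path) {
  lines <- vapply(samples, function(m) {
    jsonlite::toJSON(list(
      parent = m$parent, masked = m$masked, cn_g = m$cn_g, cn_c = m$cn_c,
      ldg = if (!is.null(m$ldg)) ldg_string(m$ldg) else NULL,
      sizes = m$sizes, seed = m$seed
    ), auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines masking manifest
#' @param path file path.
#' @return list of masking samples.
#' @export
read_manifest <- function(path) {
  lapply(readLines(path), function(l) {
    m <- jsonlite::fromJSON(l)
    m$masked <- as.integer(m$masked)
    if (!is.null(m$ldg)) m$ldg <- parse_ldg(m$ldg)
    m
  })
}

## Small counter-based RNG wrapper: isolates package draws from the global
## RNG state and gives reproducible substreams (used for per-ligand noise).
make_rng <- function(seed) {
  seed <- as.integer(seed) %% 2147483562L
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  local_draw <- function(what, n, lo = 0, hi = 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(env$state)) set.seed(seed)
    else assign(".Random.seed", env$state, envir = globalenv())
    switch(what,
      norm = stats::rnorm(n),
      unif = stats::runif(n, lo, hi),
      int = as.integer(lo + floor(stats::runif(n) * (hi - lo + 1))),
      stop("unknown draw type: ", what))
  }
  local_draw
}

## derive a bounded substream seed from a base seed and a stream index
substream_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807 + 12345) %% 2147483562
}
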