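## Spin-crossover candidate screening: variation enumeration from
## reference complexes, ligand generation, validity filtering, paired
## high-spin / low-spin energies from a pluggable backend, ground-state
## classification and the spin-gap filter.

.hartree_kcal <- 627.509474

#' A high-spin / low-spin energy pair
#'
#' @param id complex identifier.
#' @param e_hs,e_ls total energies of the high-spin and low-spin states
#'   (kcal/mol on a common reference; use `units = "hartree"` to convert).
#' @param ok_hs,ok_ls optimisation success flags; the spin gap is finite
#'   only when both succeeded.
#' @param units `"kcal/mol"` (default) or `"hartree"`.
#' @return object of class `spin_pair` with a `gap` field
#'   (`E_HS - E_LS`, kcal/mol, `NA` unless both optimisations succeeded).
#' @export
spin_pair <- function(id, e_hs, e_ls, ok_hs = TRUE, ok_ls = TRUE,
                      units = "kcal/mol") {
  if (units == "hartree") {
    e_hs <- e_hs * .hartree_kcal
    e_ls <- e_ls * .hartree_kcal
  } else if (units != "kcal/mol") stop("unknown energy units: ", units)
  gap <- if (isTRUE(ok_hs) && isTRUE(ok_ls) &&
             is.finite(e_hs) && is.finite(e_ls)) e_hs - e_ls else NA_real_
  structure(list(id = id, e_hs = e_hs, e_ls = e_ls,
                 ok_hs = ok_hs, ok_ls = ok_ls, gap = gap),
            class = "spin_pair")
}

#' Classify the ground spin state of an energy pair
#'
#' High-spin iff `E_HS < E_LS`, low-spin otherwise; exact ties classify
#' as LS with a warning.
#'
#' @param pair a `spin_pair` with both energies present.
#' @return `"HS"` or `"LS"`.
#' @export
classify_ground_state <- function(pair) {
  stopifnot(inherits(pair, "spin_pair"))
  if (is.na(pair$gap))
    stop(tmcdiff_error("missing_energy",
      sprintf("spin pair '%s' lacks a converged energy for both states",
              pair$id)))
  if (pair$gap == 0) {
    warning(sprintf("spin pair '%s': exact HS/LS tie, classifying as LS",
                    pair$id))
    return("LS")
  }
  if (pair$e_hs < pair$e_ls) "HS" else "LS"
}

#' Retain spin pairs with a small HS/LS gap
#'
#' Keeps pairs whose absolute spin gap is no more than the threshold
#' (boundary inclusive): both HS-ground and LS-ground near-degenerate
#' complexes are spin-crossover candidates.
#'
#' @param pairs list of `spin_pair`.
#' @param threshold gap threshold in kcal/mol (default 10).
#' @return the retained sublist.
#' @export
spin_gap_filter <- function(pairs, threshold = 10) {
  Filter(function(p) !is.na(p$gap) && abs(p$gap) <= threshold, pairs)
}

#' Enumerate generation variations for reference complexes
#'
#' For each reference: every non-empty ligand-subset masking crossed with
#' every integer partition of the freed coordination number, with a
#' heavy-atom size drawn for each generated ligand between its assigned
#' denticity and `max_ligand_size`. Counts reconcile with
#' [count_variations()].
#'
#' @param references list of `tmc` objects.
#' @param max_ligand_size heavy-atom cap per generated ligand (default 10).
#' @param seed integer seed for size draws.
#' @return list of variations: each has the masking-sample fields plus
#'   `reference_index`, `ldg` and `sizes`.
#' @export
enumerate_sco_variations <- function(references, max_ligand_size = 10L,
                                     seed = 1L) {
  rng <- make_rng(seed)
  out <- list()
  for (ri in seq_along(references)) {
    for (m in enumerate_maskings(references[[ri]])) {
      for (ldg in enumerate_ldg(m$cn_g)) {
        v <- m
        v$reference_index <- ri
        v$ldg <- ldg
        v$sizes <- vapply(ldg, function(d)
          rng("int", 1L, lo = d, hi = max(d, max_ligand_size)), integer(1))
        out[[length(out) + 1L]] <- v
      }
    }
  }
  out
}

#' Mock energy backend
#'
#' Deterministic stand-in for an external quantum-chemistry engine
#' (synthetic energies; no chemistry is computed). Energies derive from a
#' hash of the structure so repeated calls agree exactly; the high-spin
#' state is offset by a structure-dependent gap spanning roughly
#' -25..+25 kcal/mol so that downstream classification and gap filtering
#' exercise both branches. Optionally, energies can be supplied
#' explicitly as a lookup table keyed by `"<id>:<state>"`.
#'
#' @param energies optional named numeric vector / list: exact energies
#'   (kcal/mol) keyed by `"<id>:HS"` / `"<id>:LS"`.
#' @param fail_ids character vector of complex ids whose optimisation
#'   should report failure (for attrition testing).
#' @return an energy backend: list with `name`, `capabilities` and
#'   `optimize(elements, coords, id, state, charge, multiplicity)`.
#' @export
mock_backend <- function(energies = NULL, fail_ids = character(0)) {
  list(
    name = "mock",
    capabilities = c("optimize", "single-point"),
    units = "kcal/mol",
    optimize = function(elements, coords, id, state,
                        charge = 0L, multiplicity = 1L) {
      if (id %in% fail_ids)
        return(list(energy = NA_real_, coords = coords, converged = FALSE))
      key <- paste0(id, ":", state)
      if (!is.null(energies) && !is.null(energies[[key]]))
        return(list(energy = as.numeric(energies[[key]]), coords = coords,
                    converged = TRUE))
      ## deterministic pseudo-energy from structure + state
      h <- sum(round(coords, 3)^2) + sum(utf8ToInt(paste(elements,
                                                         collapse = "")))
      base <- -1000 - (h %% 97)
      gap <- ((h * 7919) %% 51) - 25   # spread of HS-LS gaps
      e <- if (state == "HS") base + gap else base
      list(energy = e, coords = coords, converged = TRUE)
    }
  )
}

#' Read a mock backend from a JSON energy fixture
#' @param path JSON file: object mapping `"<id>:<state>"` to kcal/mol.
#' @return an energy backend (see [mock_backend()]).
#' @export
mock_backend_from_json <- function(path) {
  mock_backend(energies = jsonlite::fromJSON(path))
}

#' Run the spin-crossover screening workflow
#'
#' Pipeline stages, in order: enumerate variations, generate ligands for
#' up to `n_max` variations, validate the assembled complexes, apply the
#' hydrogen/charge hooks (pass-through by default; real chemistry is
#' delegated to external tooling), optimise both spin states through the
#' backend, classify ground states and apply the spin-gap filter. Every
#' stage logs retained/dropped counts; backend failure on an item flags
#' the item and the pipeline continues.
#'
#' @param references list of `tmc` reference complexes.
#' @param backend an energy backend (see [mock_backend()]).
#' @param model a trained `tmcdiff_model`.
#' @param seed integer seed.
#' @param n_max cap on the number of variations generated.
#' @param max_ligand_size heavy-atom cap per generated ligand.
#' @param gap_threshold spin-gap retention threshold (kcal/mol).
#' @param multiplicities named integer vector `c(HS = ..., LS = ...)`
#'   (2S+1) forwarded to the backend.
#' @param hydrogen_hook,charge_hook functions applied to each valid
#'   generated structure before the energy stage; defaults pass through.
#' @param steps reverse-diffusion steps per generation (default: model
#'   schedule).
#' @param generator optional replacement for the diffusion sampler, a
#'   `function(ctx, ldg, sizes, seed)` returning a `tmc_generated` (used
#'   for pipeline audits, e.g. injecting known-invalid structures).
#' @return object of class `sco_report`: `items` data frame,
#'   `stage_counts`, `retained` (list of `spin_pair`), and the per-stage
#'   drop log.
#' @export
run_sco_workflow <- function(references, backend, model, seed = 1L,
                             n_max = 20L, max_ligand_size = 10L,
                             gap_threshold = 10,
                             multiplicities = c(HS = 5L, LS = 1L),
                             hydrogen_hook = identity,
                             charge_hook = identity,
                             steps = NULL, generator = NULL) {
  vars <- enumerate_sco_variations(references, max_ligand_size, seed = seed)
  n_gen <- min(length(vars), n_max)
  stage <- list(enumerated = length(vars), generated = 0L,
                valid = 0L, optimized = 0L, classified = 0L, retained = 0L)
  items <- list()
  pairs <- list()
  for (k in seq_len(n_gen)) {
    v <- vars[[k]]
    ref <- references[[v$reference_index]]
    id <- sprintf("var%03d_%s_m%s_ldg%s", k, ref$source_id,
                  paste(v$masked, collapse = ""), ldg_string(v$ldg))
    ctx <- tmc_context(ref, v$masked)
    g <- tryCatch({
      if (is.null(generator))
        sample_ligands(ctx, v$ldg, v$sizes, model,
                       seed = as.integer(substream_seed(seed, k)),
                       steps = steps)
      else generator(ctx, v$ldg, v$sizes,
                     seed = as.integer(substream_seed(seed, k)))
    }, error = function(e) NULL)
    rec <- list(id = id, generated = !is.null(g), valid = FALSE,
                optimized = FALSE, ground = NA_character_,
                gap = NA_real_, retained = FALSE)
    if (!is.null(g)) {
      stage$generated <- stage$generated + 1L
      g$cn_target <- ctx$cn_target
      cv <- complex_validity(list(g))
      rec$valid <- cv$num == 1L
      if (rec$valid) {
        stage$valid <- stage$valid + 1L
        st <- charge_hook(hydrogen_hook(g))
        o_hs <- backend$optimize(st$elements, st$coords, id, "HS",
                                 multiplicity = multiplicities[["HS"]])
        o_ls <- backend$optimize(st$elements, st$coords, id, "LS",
                                 multiplicity = multiplicities[["LS"]])
        sp <- spin_pair(id, o_hs$energy, o_ls$energy,
                        ok_hs = isTRUE(o_hs$converged),
                        ok_ls = isTRUE(o_ls$converged),
                        units = backend$units %||% "kcal/mol")
        rec$optimized <- !is.na(sp$gap)
        if (rec$optimized) {
          stage$optimized <- stage$optimized + 1L
          rec$ground <- classify_ground_state(sp)
          rec$gap <- sp$gap
          stage$classified <- stage$classified + 1L
          pairs[[length(pairs) + 1L]] <- sp
        }
      }
    }
    items[[k]] <- rec
  }
  retained <- spin_gap_filter(pairs, gap_threshold)
  stage$retained <- length(retained)
  kept_ids <- vapply(retained, `[[`, character(1), "id")
  items <- do.call(rbind, lapply(items, function(r) {
    r$retained <- r$id %in% kept_ids
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  structure(list(items = items, stage_counts = stage, retained = retained,
                 seed = seed, gap_threshold = gap_threshold),
            class = "sco_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sco_report <- function(x, ...) {
  s <- x$stage_counts
  cat("<sco_report>\n")
  cat(sprintf("  variations enumerated : %d\n", s$enumerated))
  cat(sprintf("  generated             : %d\n", s$generated))
  cat(sprintf("  valid complexes       : %d\n", s$valid))
  cat(sprintf("  optimised (HS & LS)   : %d\n", s$optimized))
  cat(sprintf("  retained (|gap| <= %g): %d\n", x$gap_threshold, s$retained))
  if (nrow(x$items) && any(!is.na(x$items$ground))) {
    tb <- table(x$items$ground[x$items$retained])
    cat(sprintf("  ground states among retained: HS %d, LS %d\n",
                sum(tb["HS"], na.rm = TRUE), sum(tb["LS"], na.rm = TRUE)))
  }
  invisible(x)
}

#' Write an SCO screening report as TSV + JSON
#' @param report an `sco_report`.
#' @param prefix output path prefix (writes `<prefix>.tsv`,
#'   `<prefix>.json`).
#' @return `prefix`, invisibly.
#' @export
write_sco_report <- function(report, prefix) {
  utils::write.table(report$items, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(stage_counts = report$stage_counts,
         gap_threshold = report$gap_threshold, seed = report$seed),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
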