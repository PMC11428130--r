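test_that("ground-state classification compares the two energies", {
  expect_equal(classify_ground_state(spin_pair("a", -10, -5)), "HS")
  expect_equal(classify_ground_state(spin_pair("b", -5, -10)), "LS")
  expect_warning(g <- classify_ground_state(spin_pair("c", -7, -7)), "tie")
  expect_equal(g, "LS")
  expect_error(classify_ground_state(spin_pair("d", NA, -5)),
               class = "tmcdiff_missing_energy")
  expect_error(classify_ground_state(spin_pair("e", -3, -5, ok_ls = FALSE)),
               class = "tmcdiff_missing_energy")
})

test_that("mock-energy batches classify exactly as labelled", {
  set.seed(21)
  labels <- sample(c("HS", "LS"), 40, replace = TRUE)
  pairs <- lapply(seq_along(labels), function(i) {
    e_ls <- -1000 + runif(1, -5, 5)
    gap <- runif(1, 0.5, 20) * if (labels[i] == "HS") -1 else 1
    spin_pair(sprintf("p%02d", i), e_ls + gap, e_ls)
  })
  got <- vapply(pairs, classify_ground_state, character(1))
  expect_identical(got, labels)
})

test_that("the spin-gap filter has an inclusive boundary and is monotone", {
  mk <- function(id, gap) spin_pair(id, -100 + gap, -100)
  pairs <- list(mk("keep5", 5), mk("drop12", 12), mk("edge10", 10),
                mk("neg8", -8), mk("negedge", -10), mk("drop-15", -15))
  kept <- spin_gap_filter(pairs, threshold = 10)
  ids <- vapply(kept, `[[`, character(1), "id")
  expect_setequal(ids, c("keep5", "edge10", "neg8", "negedge"))
  ## monotone in the threshold
  k5 <- vapply(spin_gap_filter(pairs, 5), `[[`, character(1), "id")
  k10 <- vapply(spin_gap_filter(pairs, 10), `[[`, character(1), "id")
  expect_true(all(k5 %in% k10))
  ## constructed batch with a known retention count
  set.seed(3)
  gaps <- c(runif(37, -10, 10), runif(63, 10.01, 40) * sample(c(-1, 1), 63,
                                                              replace = TRUE))
  batch <- lapply(seq_along(gaps), function(i) mk(paste0("b", i), gaps[i]))
  expect_length(spin_gap_filter(batch, 10), 37L)
})

test_that("hartree energies convert to kcal/mol at ingestion", {
  p <- spin_pair("h", -1000.00, -1000.01, units = "hartree")
  expect_equal(p$gap, 0.01 * 627.509474, tolerance = 1e-9)
})

test_that("variation enumeration reconciles with the combinatorics", {
  refs <- list(bis_tri(1), bis_tri(2))
  v <- enumerate_sco_variations(refs, max_ligand_size = 10L, seed = 1L)
  expect_length(v, 34L)
  expect_equal(sum(vapply(v, `[[`, integer(1), "reference_index") == 1L), 17L)
  ## sizes respect the cap and the assigned denticities
  for (vi in v) {
    expect_true(all(vi$sizes <= 10L))
    expect_true(all(vi$sizes >= vi$ldg))
    expect_equal(sum(vi$ldg), vi$cn_g)
  }
  ## a single totally-masked hexadentate reference: p(6) = 11 variations
  hexa <- make_toy_complex("Mn", "hexaoxa", geometry = "octahedral", seed = 3)
  expect_length(hexa$ligands, 1L)
  expect_length(enumerate_sco_variations(list(hexa), seed = 1L), 11L)
  expect_identical(count_variations(hexa), 11L)
})

test_that("the screening pipeline conserves counts at every stage", {
  refs <- list(bis_tri(5))
  model <- tiny_model(T = 10L)
  ## generator bypass: return pristine fixtures (always valid)
  gen_fix <- function(ctx, ldg, sizes, seed) {
    x <- hexa_mono(seed = (seed %% 50) + 1L)
    structure(list(elements = x$elements, coords = x$coords,
                   context_rows = 1L, gen_rows = lapply(x$ligands, `[[`,
                                                        "atoms"),
                   ldg = ldg, sizes = sizes, seed = seed, complex = x,
                   cn_target = 6L),
              class = "tmc_generated")
  }
  rep_ <- run_sco_workflow(refs, mock_backend(), model, seed = 2L,
                           n_max = 12L, generator = gen_fix)
  s <- rep_$stage_counts
  expect_equal(s$enumerated, 17L)
  expect_equal(s$generated, 12L)
  expect_lte(s$valid, s$generated)
  expect_lte(s$optimized, s$valid)
  expect_lte(s$retained, s$classified)
  ## per-item bookkeeping sums to the stage counts
  expect_equal(sum(rep_$items$generated), s$generated)
  expect_equal(sum(rep_$items$valid), s$valid)
  expect_equal(sum(rep_$items$retained), s$retained)
  ## rerun with the same seed is identical
  rep2 <- run_sco_workflow(refs, mock_backend(), model, seed = 2L,
                           n_max = 12L, generator = gen_fix)
  expect_identical(rep_$items, rep2$items)
})

test_that("injected invalid complexes are dropped exactly at the validity stage", {
  refs <- list(bis_tri(6))
  model <- tiny_model(T = 10L)
  k_bad <- 0L
  gen_mixed <- function(ctx, ldg, sizes, seed) {
    x <- hexa_mono(seed = (seed %% 50) + 1L)
    bad <- (seed %% 3L) == 0L
    if (bad) {
      k_bad <<- k_bad + 1L
      x$coords[3, ] <- x$coords[2, ] + c(0.05, 0, 0)  # clash
      x <- suppressWarnings(tmc(x$elements, x$coords))
    }
    structure(list(elements = x$elements, coords = x$coords,
                   context_rows = 1L,
                   gen_rows = lapply(x$ligands, `[[`, "atoms"),
                   ldg = ldg, sizes = sizes, seed = seed, complex = x,
                   cn_target = 6L),
              class = "tmc_generated")
  }
  rep_ <- run_sco_workflow(refs, mock_backend(), model, seed = 4L,
                           n_max = 10L, generator = gen_mixed)
  s <- rep_$stage_counts
  expect_equal(s$generated - s$valid, k_bad)
})

test_that("backend failures flag items but do not stop the pipeline", {
  refs <- list(bis_tri(7))
  model <- tiny_model(T = 10L)
  gen_fix <- function(ctx, ldg, sizes, seed) {
    x <- hexa_mono(seed = (seed %% 50) + 1L)
    structure(list(elements = x$elements, coords = x$coords,
                   context_rows = 1L,
                   gen_rows = lapply(x$ligands, `[[`, "atoms"),
                   ldg = ldg, sizes = sizes, seed = seed, complex = x,
                   cn_target = 6L),
              class = "tmc_generated")
  }
  ## fail every optimisation: pipeline finishes, nothing optimised
  be <- mock_backend(fail_ids = sprintf("var%03d_bis_tri_7_m%s_ldg%s",
                                        1:17, "x", "y"))
  be$optimize <- function(elements, coords, id, state, ...)
    list(energy = NA_real_, coords = coords, converged = FALSE)
  rep_ <- run_sco_workflow(refs, be, model, seed = 5L, n_max = 5L,
                           generator = gen_fix)
  expect_equal(rep_$stage_counts$optimized, 0L)
  expect_equal(rep_$stage_counts$retained, 0L)
  expect_true(all(!rep_$items$optimized))
})

test_that("a JSON energy fixture drives the backend deterministically", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(`c1:HS` = -1005, `c1:LS` = -1000,
                            `c2:HS` = -990, `c2:LS` = -1000),
                       f, auto_unbox = TRUE)
  be <- mock_backend_from_json(f)
  o <- be$optimize("Fe", matrix(0, 1, 3), "c1", "HS")
  expect_equal(o$energy, -1005)
  p1 <- spin_pair("c1", be$optimize("Fe", matrix(0, 1, 3), "c1", "HS")$energy,
                  be$optimize("Fe", matrix(0, 1, 3), "c1", "LS")$energy)
  expect_equal(classify_ground_state(p1), "HS")
})
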