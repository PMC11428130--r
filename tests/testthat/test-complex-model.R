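test_that("bond perception follows the covalent-radius rule", {
  two_c <- function(d) list(elements = c("C", "C"),
                            coords = rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(nrow(perceive_bonds(two_c(1.50), tolerance = 0.4)), 1L)
  expect_equal(nrow(perceive_bonds(two_c(5.00), tolerance = 0.4)), 0L)
  expect_error(covalent_radius("Xx"), class = "tmcdiff_unknown_element")
})

test_that("bond perception matches an exhaustive pairwise oracle", {
  set.seed(11)
  for (rep in 1:5) {
    el <- sample(c("C", "N", "O", "S", "P"), 10, replace = TRUE)
    xyz <- matrix(runif(30, 0, 6), 10, 3)
    got <- perceive_bonds(list(elements = el, coords = xyz), tolerance = 0.4)
    want <- NULL
    for (i in 1:9) for (j in (i + 1):10) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= covalent_radius(el[i]) + covalent_radius(el[j]) + 0.4)
        want <- rbind(want, c(i, j))
    }
    if (is.null(want)) want <- matrix(integer(0), 0, 2)
    expect_equal(unname(got), unname(want))
  }
})

test_that("ligand partitioning finds connected components off the metal", {
  ## metal + one diatomic ligand
  x <- tmc(c("Fe", "C", "O"),
           rbind(c(0, 0, 0), c(0, 0, 2), c(0, 0, 3.15)))
  expect_length(x$ligands, 1L)
  expect_equal(x$ligands[[1]]$atoms, c(2L, 3L))

  hx <- hexa_mono()
  expect_length(hx$ligands, 6L)
  expect_true(all(vapply(hx$ligands, `[[`, integer(1), "denticity") == 1L))

  bt <- bis_tri()
  expect_length(bt$ligands, 2L)
  expect_equal(vapply(bt$ligands, `[[`, integer(1), "denticity"), c(3L, 3L))
  expect_equal(coordination_number(bt), 6L)
})

test_that("partition is invariant under atom-index permutation", {
  x <- bis_tri()
  set.seed(3)
  ## permute non-metal atoms, keep a metal-first layout
  n <- length(x$elements)
  perm <- c(x$metal_index, sample(setdiff(seq_len(n), x$metal_index)))
  y <- tmc(x$elements[perm], x$coords[perm, ])
  sig <- function(z) sort(vapply(z$ligands, function(l)
    paste(sort(z$elements[l$atoms]), collapse = ""), character(1)))
  expect_equal(sig(y), sig(x))
  expect_equal(coordination_number(y), coordination_number(x))
})

test_that("denticity counts donor atoms inside the metal cutoff", {
  x <- tmc(c("Fe", "N"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(x$ligands[[1]]$denticity, 1L)

  ## bidentate chelate: both donors at 2.0, backbone out at 3.0
  bt <- make_toy_complex("Co", c("en", "aqua", "ammine", "chloro", "cyano"),
                         seed = 4)
  dent <- vapply(bt$ligands, `[[`, integer(1), "denticity")
  expect_equal(sort(dent, decreasing = TRUE), c(2L, 1L, 1L, 1L, 1L))

  ## context with one tridentate ligand: CN_c = 3, CN_g = 3
  ctx <- tmc_context(bis_tri(), masked_ligands = 2L)
  expect_equal(ctx$cn_c, 3L)
  expect_equal(ctx$cn_g, 3L)
})

test_that("dangling ligands are flagged, not dropped", {
  expect_warning(
    x <- tmc(c("Fe", "N", "O"),
             rbind(c(0, 0, 0), c(2, 0, 0), c(8, 0, 0))),
    "no atom within the metal cutoff")
  expect_length(x$ligands, 2L)
  expect_equal(x$ligands[[2]]$denticity, 0L)
})

test_that("complex construction enforces its invariants", {
  expect_error(tmc(c("C", "N"), rbind(c(0, 0, 0), c(1.4, 0, 0))),
               class = "tmcdiff_invalid_complex")
  expect_error(tmc(c("Fe", "Fe", "N"),
                   rbind(c(0, 0, 0), c(4, 0, 0), c(2, 0, 0))),
               class = "tmcdiff_invalid_complex")
  expect_error(tmc(c("Fe", "U"), rbind(c(0, 0, 0), c(2, 0, 0))),
               class = "tmcdiff_unknown_element")
  ## hydrogens are stripped on ingest
  x <- tmc(c("Fe", "N", "H"),
           rbind(c(0, 0, 0), c(2, 0, 0), c(2.5, 0.8, 0)))
  expect_false("H" %in% x$elements)
})

test_that("embeddings decode back to the source complex", {
  for (x in list(hexa_mono(), bis_tri(),
                 make_toy_complex("Zn", c("tetraaza", "en"), seed = 6))) {
    emb <- build_embedding(x, masked_ligands = 1L)
    dec <- decode_embedding(emb)
    expect_identical(dec$elements, x$elements)
    expect_identical(dec$ligand_assignment, x$ligand_assignment)
    ## one-hot rows all sum to 1
    expect_true(all(abs(rowSums(emb$h_a) - 1) < 1e-12))
    expect_true(all(abs(rowSums(emb$h_L) - 1) < 1e-12))
    expect_true(all(abs(rowSums(emb$h_c) - 1) < 1e-12))
    ## metal at origin, masked flags only on the chosen ligand
    expect_equal(as.numeric(emb$coords[emb$metal_row, ]), c(0, 0, 0))
    expect_equal(which(emb$masked),
                 which(x$ligand_assignment == 1L))
    expect_identical(unname(emb$scaling), c(0.1, 0.25, 1.0))
  }
})

test_that("generation-mode embeddings respect the denticity budget", {
  bt <- bis_tri()
  ## CN_c = 3 context, one tridentate to generate with 12 atoms
  emb <- build_embedding(bt, masked_ligands = 2L, ldg = 3L, sizes = 12L)
  expect_equal(sum(emb$masked), 12L)
  expect_equal(max(emb$ligand_code), 2L)
  expect_true(all(is.na(emb$coords[emb$masked, ])))
  ## h_c of placeholder atoms carries the assigned denticity
  expect_true(all(emb$h_c[emb$masked, 3] == 1))

  expect_error(build_embedding(bt, masked_ligands = 2L, ldg = c(2L, 2L),
                               sizes = c(5L, 5L)),
               class = "tmcdiff_denticity_budget")
  expect_error(build_embedding(bt, masked_ligands = integer(0)),
               class = "tmcdiff_nothing_to_generate")
  expect_warning(build_embedding(bt, masked_ligands = c(1L, 2L),
                                 ldg = c(2L, 2L, 2L), sizes = c(3L, 8L, 8L)),
                 "ligand size below denticity")
  expect_error(build_embedding(hexa_mono(), masked_ligands = 1L, l_max = 6L),
               class = "tmcdiff_context_overflow")
})

test_that("XYZ and SDF round-trips preserve structures", {
  x <- hexa_mono()
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(list(x, bis_tri()), f)
  back <- read_xyz(f)
  expect_length(back, 2L)
  expect_identical(back[[1]]$elements, x$elements)
  expect_lt(max_abs(back[[1]]$coords - x$coords), 1e-7)

  g <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(x$elements, x$coords, x$bonds, g)
  sx <- read_sdf(g)
  expect_identical(sx$elements, x$elements)
  expect_lt(max_abs(sx$coords - x$coords), 1e-3)
})
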