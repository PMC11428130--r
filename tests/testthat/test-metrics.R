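## handcrafted ligand blocks
sane_ligand <- function() list(elements = c("N", "C", "C"),
                               coords = rbind(c(0, 0, 0), c(1.4, 0, 0),
                                              c(2.1, 1.2, 0)))
pentavalent_carbon <- function() {
  ## central carbon bonded to five carbons
  list(elements = rep("C", 6),
       coords = rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0),
                      c(0, 1.5, 0), c(0, -1.5, 0), c(0, 0, 1.5)))
}
split_ligand <- function() list(elements = c("O", "O"),
                                coords = rbind(c(0, 0, 0), c(6, 0, 0)))

test_that("ligand validity screens implausible valences", {
  hx <- hexa_mono()
  expect_equal(ligand_validity(extract_ligands(hx))$value, 1.0)
  r <- ligand_validity(list(sane_ligand(), pentavalent_carbon()))
  expect_equal(r$value, 0.5)
  expect_equal(r$flags, c(TRUE, FALSE))
  expect_error(ligand_validity(list()), "empty")
  ## count additivity: concatenated ratio is the weighted mean
  a <- ligand_validity(list(sane_ligand(), sane_ligand()))
  b <- ligand_validity(list(sane_ligand(), pentavalent_carbon()))
  ab <- ligand_validity(list(sane_ligand(), sane_ligand(),
                             sane_ligand(), pentavalent_carbon()))
  expect_equal(ab$num, a$num + b$num)
  expect_equal(ab$den, a$den + b$den)
})

test_that("ligand connectivity requires a single component", {
  expect_equal(ligand_connectivity(list(sane_ligand()))$value, 1.0)
  expect_equal(ligand_connectivity(list(split_ligand()))$value, 0.0)
  r <- ligand_connectivity(list(sane_ligand(), sane_ligand(),
                                sane_ligand(), split_ligand()))
  expect_equal(r$value, 0.75)
})

test_that("complex validity applies its four rules", {
  hx <- hexa_mono()
  expect_equal(complex_validity(list(hx))$value, 1.0)
  ## superposed atoms fail the clash rule
  clash <- hx
  clash$coords[3, ] <- clash$coords[2, ] + c(0.1, 0, 0)
  clash <- tmc(clash$elements, clash$coords)
  expect_equal(complex_validity(list(clash))$value, 0.0)
  expect_equal(complex_validity(list(clash), checks = "clash")$value, 0.0)
  ## a plain complex trivially meets its own coordination target
  expect_equal(complex_validity(list(clash), checks = "denticity")$value, 1.0)
  ## batch ratio with one failure
  batch <- c(replicate(9, hexa_mono(seed = sample.int(100, 1)),
                       simplify = FALSE), list(clash))
  expect_equal(complex_validity(batch)$value, 0.9)
  ## monotonicity: adding a check can only lower the ratio
  some <- complex_validity(batch, checks = c("ligands"))
  all4 <- complex_validity(batch)
  expect_lte(all4$value, some$value)
})

test_that("novelty and uniqueness are exact set ratios", {
  expect_equal(novelty(c("A", "B"), c("A", "B", "C"))$value, 0.0)
  expect_equal(novelty(c("X", "Y"), c("A", "B"))$value, 1.0)
  expect_equal(novelty(c("X", "Y", "Z", "A"), c("A"))$value, 0.75)
  expect_equal(uniqueness(rep("A", 4))$value, 0.25)
  expect_equal(uniqueness(c("A", "B", "C"))$value, 1.0)
  expect_equal(uniqueness(c("A", "A", "B", "C"))$value, 0.75)
})

test_that("canonical SMILES are order-invariant identifiers", {
  l <- sane_ligand()
  perm <- c(3, 1, 2)
  l2 <- list(elements = l$elements[perm], coords = l$coords[perm, ])
  expect_identical(ligand_smiles(l), ligand_smiles(l2))
  ## distinct skeletons give distinct strings
  expect_false(ligand_smiles(l) == ligand_smiles(split_ligand()))
})

test_that("bond-length profiles average metal-donor distances", {
  x <- tmc(c("Fe", rep("N", 6)),
           rbind(c(0, 0, 0), c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0),
                 c(0, -2, 0), c(0, 0, 2), c(0, 0, -2)))
  expect_equal(bond_length_profile(x)$mean, 2.0)
  y <- tmc(c("Fe", "N", "N"),
           rbind(c(0, 0, 0), c(1.9, 0, 0), c(0, 2.1, 0)))
  expect_equal(bond_length_profile(y)$mean, 2.0)
  ## HS geometry uniformly +0.2 Angstrom: difference of means is 0.2
  hs <- tmc(x$elements, x$coords * 1.1)
  expect_equal(bond_length_profile(hs)$mean - bond_length_profile(x)$mean,
               0.2, tolerance = 1e-9)
  summ <- bond_length_summary(list(x, hs), spin_labels = c("LS", "HS"))
  expect_equal(diff(summ$mean_bond), 0.2, tolerance = 1e-9)
})

test_that("conformer RMSD is a proper superposition distance", {
  x <- hexa_mono()
  expect_equal(conformer_rmsd(x, x), 0.0, tolerance = 1e-10)
  y <- x
  y$coords <- x$coords %*% t(random_rotation(5L)) + 3.0
  expect_equal(conformer_rmsd(x, y), 0.0, tolerance = 1e-8)
  expect_equal(conformer_rmsd(y, x), conformer_rmsd(x, y), tolerance = 1e-8)
  z <- x; z$coords[2, ] <- z$coords[2, ] + 1
  expect_gt(conformer_rmsd(x, z), 0.01)
  expect_error(conformer_rmsd(x, bis_tri()), "mismatch")
})

test_that("optimal superposition matches an exhaustive rotation-grid oracle", {
  a <- list(elements = c("C", "N", "O", "C"),
            coords = rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0),
                           c(0.5, 0.5, 1.2)))
  set.seed(9)
  b <- list(elements = a$elements,
            coords = a$coords %*% t(random_rotation(3L)) +
              matrix(rnorm(12, sd = 0.1), 4, 3))
  got <- conformer_rmsd(a, b)
  ## oracle: centred coordinates, coarse Euler grid + local refinement
  ca <- scale(a$coords, scale = FALSE)
  cb <- scale(b$coords, scale = FALSE)
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3) %*%
      matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3) %*%
      matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  }
  obj <- function(ang) sqrt(mean(rowSums((cb %*% t(rot(ang)) - ca)^2)))
  grid <- expand.grid(a1 = seq(0, 2 * pi, length.out = 13),
                      a2 = seq(0, pi, length.out = 7),
                      a3 = seq(0, 2 * pi, length.out = 13))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  ref <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))$value
  expect_equal(got, ref, tolerance = 1e-3)
})

test_that("generation reports aggregate with exact arithmetic", {
  mk_report <- function(vals) {
    r <- list()
    for (nm in c("p_l_val", "p_l_con", "p_c_val", "p_l_nov", "p_l_uniq"))
      r[[nm]] <- list(value = vals[[nm]], num = 1L, den = 1L)
    structure(c(r, list(n_complexes = 1L)), class = "generation_report")
  }
  base <- c(p_l_val = 0.8, p_l_con = 1.0, p_c_val = 0.9, p_l_nov = 0.5,
            p_l_uniq = 0.7)
  ## 10 identical runs: sd exactly 0
  agg10 <- aggregate_reports(replicate(10, mk_report(as.list(base)),
                                       simplify = FALSE))
  expect_equal(agg10$mean, unname(base))
  expect_equal(agg10$sd, rep(0, 5))
  ## constructed 2-run case 0.8 / 1.0 -> mean 0.9
  v2 <- as.list(base); v2$p_l_val <- 1.0
  agg2 <- aggregate_reports(list(mk_report(as.list(base)), mk_report(v2)))
  expect_equal(agg2$mean[agg2$metric == "p_l_val"], 0.9)
  expect_equal(agg2$sd[agg2$metric == "p_l_val"], stats::sd(c(0.8, 1.0)))
})

test_that("a full report on pristine fixtures is all ones (novelty zero vs itself)", {
  fixtures <- list(hexa_mono(1), hexa_mono(2), bis_tri(3))
  smi <- unlist(lapply(fixtures, function(x)
    ligand_smiles(extract_ligands(x))))
  rep_ <- generation_report(fixtures, training_smiles = smi)
  expect_equal(rep_$p_l_val$value, 1.0)
  expect_equal(rep_$p_l_con$value, 1.0)
  expect_equal(rep_$p_c_val$value, 1.0)
  expect_equal(rep_$p_l_nov$value, 0.0)
  ## connectivity denominator equals the validity numerator
  expect_equal(rep_$p_l_con$den, rep_$p_l_val$num)
})
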