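test_that("ensemble size follows min(1 + 3 n_rot, 20)", {
  expect_identical(conformer_count(0), 1L)
  expect_identical(conformer_count(3), 10L)
  expect_identical(conformer_count(50), 20L)
  expect_error(conformer_count(-1), class = "chpka_domain_error")
})

test_that("rotatable bonds are non-ring single bonds between non-terminal heavy atoms", {
  expect_identical(nrow(rotatable_bonds("CCCC")), 1L)   # central C-C
  expect_identical(nrow(rotatable_bonds("CCO")), 0L)    # both bonds touch a terminal atom
  expect_identical(nrow(rotatable_bonds("CC(C)C")), 0L)
  expect_identical(nrow(rotatable_bonds("c1ccccc1")), 0L)
  expect_identical(nrow(rotatable_bonds("CCCCC")), 2L)
  expect_identical(nrow(rotatable_bonds("CCc1ccccc1")), 1L) # ring-to-CH2
})

test_that("ensemble generation is deterministic and correctly sized", {
  e1 <- generate_ensemble("CCCC", seed = 7)
  e2 <- generate_ensemble("CCCC", seed = 7)
  expect_identical(e1$conformers, e2$conformers)
  expect_length(e1$conformers, 4L)
  expect_length(generate_ensemble("C", seed = 3)$conformers, 1L)
  # geometry atom order matches the parsed species
  mol <- parse_mol("CCCC")
  expect_identical(nrow(e1$conformers[[1]]$xyz), mol$natoms)
})

test_that("embedded geometries have chemically sane bond lengths", {
  for (smi in c("CC", "c1ccccc1", "CC(C)=O", "CC#N")) {
    mol <- parse_mol(smi)
    xyz <- embed_molecule(mol)
    b <- mol$bonds
    d <- sqrt(rowSums((xyz[b$a1, , drop = FALSE] - xyz[b$a2, , drop = FALSE])^2))
    expect_true(all(d > 0.85 & d < 1.75), info = smi)
  }
})

test_that("energy-window pruning keeps the window-inclusive set and the minimum", {
  ens <- ensemble_with_energies("CCCCC", c(-10, -8, -6.5))
  kept <- prune_by_energy(ens, 3)
  expect_identical(sapply(kept$conformers, `[[`, "energy"), c(-10, -8))
  # inclusive boundary at exactly the window
  ens2 <- ensemble_with_energies("CCCCC", c(-10, -7))
  expect_length(prune_by_energy(ens2, 3)$conformers, 2L)
  ens3 <- ensemble_with_energies("C", -10)
  expect_length(prune_by_energy(ens3, 3)$conformers, 1L)
  # idempotent
  once <- prune_by_energy(ens, 3)
  expect_identical(prune_by_energy(once, 3), once)
  empty <- ens
  empty$conformers <- list()
  expect_error(prune_by_energy(empty, 3), class = "chpka_empty_ensemble")
})

test_that("best-fit RMSD agrees with an independent superposition", {
  skip_if_not_installed("bio3d")
  set.seed(42)
  a <- matrix(rnorm(30), 10, 3)
  # random rotation + translation leaves RMSD at zero
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  b <- a %*% q + matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  expect_lt(rmsd_kabsch(a, b), 1e-8)
  bb <- b + matrix(rnorm(30, sd = 0.3), 10, 3)
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(bb)), fit = TRUE)
  expect_equal(rmsd_kabsch(a, bb), ref, tolerance = 2e-3) # bio3d rounds to 3 dp
})

test_that("Butina clustering matches the naive oracle on random matrices", {
  expect_identical(butina_cluster(matrix(0, 1, 1), 0.5)$centroids, 1L)
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2)
  expect_identical(sort(butina_cluster(d2, 0.5)$centroids), c(1L, 2L))
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    d <- random_distance_matrix(n)
    thr <- stats::runif(1, 0.2, 0.8)
    got <- butina_cluster(d, thr)
    want <- butina_oracle(d, thr)
    expect_identical(got, want)
  }
})

test_that("every conformer is within threshold of a representative", {
  ens <- generate_ensemble("CCCCCC", seed = 5)
  D <- pairwise_rmsd(ens)
  res <- butina_cluster(D, 0.5)
  expect_lte(length(res$centroids), length(ens$conformers))
  for (i in seq_len(nrow(D))) {
    expect_true(i %in% res$centroids || D[i, res$cluster[i]] <= 0.5)
  }
})

test_that("lowest-energy selection breaks ties toward the smallest id", {
  ens <- ensemble_with_energies("CCCCC", c(-5, -7.2, -6.1))
  expect_identical(lowest_energy_conformer(ens)$energy, -7.2)
  tie <- ensemble_with_energies("CCCCC", c(-5, -5))
  expect_identical(lowest_energy_conformer(tie)$conformer_id, 0L)
  single <- ensemble_with_energies("C", -3)
  expect_identical(lowest_energy_conformer(single)$conformer_id, 0L)
})

test_that("prune + cluster + select never loses the global energy minimum", {
  # geometry-dependent mock: energy from the coordinates themselves
  geom_backend <- energy_backend("geom", function(species, xyz, elements) {
    -100 + sum(sin(xyz[, 1])) + 0.1 * sum(xyz[, 3]^2)
  })
  for (smi in c("CCCC", "CCCCC", "CCOC(C)=O")) {
    ens <- assign_energies(generate_ensemble(smi, seed = 11), geom_backend)
    global_min <- min(sapply(ens$conformers, `[[`, "energy"))
    out <- lowest_energy_conformer(cluster_butina(prune_by_energy(ens, 3), 0.5))
    expect_identical(out$energy, global_min, info = smi)
  }
})

test_that("XYZ files round-trip geometries", {
  mol <- parse_mol("CC(C)=O")
  xyz <- embed_molecule(mol)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(mol$atoms$element, xyz, path, comment = "acetone")
  back <- read_xyz(path)
  expect_identical(back$elements, mol$atoms$element)
  expect_equal(back$xyz, xyz, tolerance = 1e-7)
  expect_identical(back$comment, "acetone")
})
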