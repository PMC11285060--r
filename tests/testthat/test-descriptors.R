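provider <- surrogate_charge_provider()

test_that("surrogate charges conserve net charge and respect symmetry", {
  benz <- parse_mol("c1ccccc1")
  q <- compute_charges(benz, provider)
  carbons <- which(benz$atoms$element == "C")
  expect_equal(max(q[carbons]) - min(q[carbons]), 0, tolerance = 1e-12)
  expect_equal(sum(q), 0, tolerance = 1e-9)
  eth <- parse_mol("CC")
  qe <- compute_charges(eth, provider)
  cc <- which(eth$atoms$element == "C")
  expect_equal(qe[cc[1]], qe[cc[2]], tolerance = 1e-12)
  # anion: charges sum to -1
  an <- parse_mol("[CH2-]C(C)=O")
  expect_equal(sum(compute_charges(an, provider)), -1, tolerance = 1e-9)
})

test_that("a provider returning the wrong shape is a charge error", {
  bad <- charge_provider("bad", function(mol, seed) c(1, 2))
  expect_error(compute_charges("CCO", bad), class = "chpka_charge_error")
  nonconserving <- charge_provider("drift", function(mol, seed) {
    rep(0.1, mol$natoms)
  })
  expect_error(compute_charges("CCO", nonconserving),
               class = "chpka_charge_error")
})

test_that("shell vectors collect sorted charges by exact topological distance", {
  met <- parse_mol("C")
  q <- compute_charges(met, provider)
  d <- atom_descriptor(met, 0, q, radius = 6)
  expect_equal(d$shells[[1]], q[1])
  expect_equal(d$shells[[2]], sort(q[2:5], decreasing = TRUE))
  expect_identical(d$occupancy, c(1L, 4L, rep(0L, 5)))
  # descending order within a shell
  ace <- parse_mol("CC(C)=O")
  qa <- compute_charges(ace, provider)
  da <- atom_descriptor(ace, 0, qa, radius = 6)
  for (s in da$shells) expect_true(!is.unsorted(rev(s)))
  expect_error(atom_descriptor(met, 99, q), class = "chpka_index_error")
})

test_that("slot overflow is a loud error naming the shell", {
  met <- parse_mol("C")
  q <- compute_charges(met, provider)
  expect_error(atom_descriptor(met, 0, q, radius = 6,
                               slot_widths = c(1L, 2L, rep(1L, 5))),
               class = "chpka_overflow_error")
})

test_that("descriptors are invariant under input atom order", {
  for (pair in equivalent_smiles_pairs) {
    m1 <- parse_mol(pair[1])
    m2 <- parse_mol(pair[2])
    q1 <- compute_charges(m1, provider)
    q2 <- compute_charges(m2, provider)
    d1 <- atom_descriptor(m1, 0, q1, radius = 4)
    d2 <- atom_descriptor(m2, 0, q2, radius = 4)
    expect_equal(d1$vector, d2$vector, info = paste(pair, collapse = " vs "))
  }
})

test_that("symmetry-equivalent atoms share descriptors, distinct ones differ", {
  tol <- parse_mol("Cc1ccccc1")
  q <- compute_charges(tol, provider)
  sites <- enumerate_ch_sites(tol, "tol")
  cls <- tol$symmetry_class
  meta_pair <- which(cls == cls[4] & tol$atoms$element == "C") - 1L
  expect_length(meta_pair, 2L)
  dm1 <- atom_descriptor(tol, meta_pair[1], q, radius = 6)
  dm2 <- atom_descriptor(tol, meta_pair[2], q, radius = 6)
  expect_equal(dm1$vector, dm2$vector, tolerance = 1e-12)
  methyl <- atom_descriptor(tol, 0, q, radius = 6)
  para <- atom_descriptor(tol, sites$atom_index[4], q, radius = 6)
  expect_false(isTRUE(all.equal(methyl$vector, para$vector)))
})

test_that("radius-6 vectors truncate consistently to radius 5", {
  mols <- read_molecules(fixture_smiles(12))
  widths6 <- pmax(max_shell_occupancy(mols, 6), 1L)
  widths5 <- widths6[1:6]
  for (k in c(1, 3, 5, 9)) {
    mol <- mols$mol[[k]]
    q <- compute_charges(mol, provider)
    d6 <- atom_descriptor(mol, 0, q, radius = 6, slot_widths = widths6)
    d5 <- atom_descriptor(mol, 0, q, radius = 5, slot_widths = widths5)
    charge_part6 <- d6$vector[!grepl("^occ_", names(d6$vector))]
    charge_part5 <- d5$vector[!grepl("^occ_", names(d5$vector))]
    expect_equal(unname(charge_part6[seq_along(charge_part5)]),
                 unname(charge_part5))
    expect_equal(unname(d6$occupancy[1:6]), unname(d5$occupancy))
  }
})

test_that("the feature matrix is stable, schema-complete, and failure-aware", {
  mols <- read_molecules(c("CC(C)=O", "CC#N", "Cc1ccccc1"),
                         id = c("a", "b", "c"))
  sites <- ch_sites(mols)
  fm1 <- build_feature_matrix(sites, mols, provider, seed = 4)
  fm2 <- build_feature_matrix(sites, mols, provider, seed = 4)
  expect_identical(fm1$features, fm2$features)
  expect_identical(nrow(fm1$features), nrow(sites))
  expect_identical(fm1$schema$pad_value, 0)
  expect_identical(fm1$schema$provider, "surrogate")
  expect_length(fm1$schema$columns,
                sum(fm1$schema$slot_widths) + fm1$schema$radius + 1L)
  # a site pointing at an unknown molecule lands in failures, not silently dropped
  bad_sites <- dplyr::bind_rows(sites,
                                tibble::tibble(parent_id = "ghost", atom_index = 0L,
                                               n_equivalent_h = 1L,
                                               anion_smiles = "[CH3-]"))
  fm3 <- build_feature_matrix(bad_sites, mols, provider)
  expect_identical(nrow(fm3$features), nrow(sites))
  expect_identical(fm3$failures$parent_id, "ghost")
  # schema and matrix serialize together
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_feature_matrix(fm1, csv, js)
  schema <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(schema$radius, fm1$schema$radius)
})
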