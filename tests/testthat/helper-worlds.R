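# memoized fixtures shared across test files (building a world parses every
# molecule through Open Babel, so reuse pays)
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

exact_world <- function() {
  cached("world_sigma0", make_world(seed = 1, a_true = 0.35, b_true = -150,
                                    noise_sigma = 0))
}

noisy_world <- function() {
  cached("world_sigma1", make_world(seed = 2, a_true = 0.35, b_true = -150,
                                    noise_sigma = 1, n_molecules = 140))
}

# independent naive Butina: rescans the full distance matrix every round
butina_oracle <- function(d, threshold) {
  n <- nrow(d)
  active <- seq_len(n)
  centroids <- integer(0)
  cluster <- integer(n)
  while (length(active)) {
    best <- NA_integer_
    best_count <- -1L
    for (i in active) {
      cnt <- 0L
      for (j in active) {
        if (j != i && d[i, j] <= threshold) cnt <- cnt + 1L
      }
      if (cnt > best_count) {
        best_count <- cnt
        best <- i
      }
    }
    members <- best
    for (j in active) {
      if (j != best && d[best, j] <= threshold) members <- c(members, j)
    }
    cluster[members] <- best
    centroids <- c(centroids, best)
    active <- setdiff(active, members)
  }
  list(centroids = centroids, cluster = cluster)
}

random_distance_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0, 1)
  d + t(d)
}

# build an ensemble with prescribed energies on real geometries
ensemble_with_energies <- function(smiles, energies, seed = 1) {
  ens <- generate_ensemble(smiles, seed = seed,
                           max_conformers = length(energies))
  stopifnot(length(ens$conformers) >= length(energies))
  ens$conformers <- ens$conformers[seq_along(energies)]
  for (i in seq_along(energies)) ens$conformers[[i]]$energy <- energies[i]
  ens
}

# alternative SMILES spellings of the same molecules (atom-order permutations)
equivalent_smiles_pairs <- list(
  c("Cc1ccccc1", "c1ccc(C)cc1"),
  c("Cc1ccccc1", "c1ccccc1C"),
  c("CC(C)=O", "O=C(C)C"),
  c("CCOC(C)=O", "O=C(C)OCC"),
  c("CC(C)C", "C(C)(C)C"),
  c("N#CCc1ccccc1", "c1ccccc1CC#N")
)
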