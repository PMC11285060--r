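#' Number of conformers to generate for a species
#'
#' The ensemble size grows with conformational flexibility as
#' `min(1 + 3 * n_rot, 20)`: one conformer for a rigid molecule, three more
#' per rotatable bond, capped at 20.
#'
#' @param n_rot Non-negative rotatable-bond count.
#' @return Integer conformer count.
#' @export
conformer_count <- function(n_rot) {
  if (!is.numeric(n_rot) || any(n_rot < 0) || any(n_rot != floor(n_rot))) {
    abort("n_rot must be a non-negative integer", class = "chpka_domain_error")
  }
  pmin(1L + 3L * as.integer(n_rot), 20L)
}

#' Rotatable bonds of a molecule
#'
#' A bond is rotatable when it is a non-ring single bond between two
#' non-terminal heavy atoms (a heavy atom is terminal when it has exactly one
#' heavy neighbour). Ring membership is bridge-detection on the molecular
#' graph: a bond lies in a ring exactly when it is not a bridge.
#'
#' @param mol A `chpka_mol` or SMILES string.
#' @return Tibble of rotatable bonds with 0-based `a1`, `a2`.
#' @export
rotatable_bonds <- function(mol) {
  if (is.character(mol)) mol <- parse_mol(mol)
  b <- mol$bonds
  heavy <- mol$atoms$is_heavy
  n_heavy_nb <- vapply(seq_len(mol$natoms), function(i) {
    nb <- as.integer(igraph::neighbors(mol$graph, i))
    sum(heavy[nb])
  }, integer(1))
  bridge_eids <- as.integer(igraph::bridges(mol$graph))
  is_bridge <- seq_len(nrow(b)) %in% bridge_eids
  keep <- b$order == 1L & !b$aromatic & is_bridge &
    heavy[b$a1] & heavy[b$a2] &
    n_heavy_nb[b$a1] >= 2L & n_heavy_nb[b$a2] >= 2L
  tibble(a1 = b$a1[keep] - 1L, a2 = b$a2[keep] - 1L)
}

# covalent radii (angstrom) for the elements the package handles
.cov_radius <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                 Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)

bond_length_target <- function(e1, e2, order, aromatic) {
  r <- unname(.cov_radius[e1] + .cov_radius[e2])
  r[is.na(r)] <- 1.5
  f <- ifelse(aromatic, 0.92, c(1, 0.87, 0.78)[pmin(order, 3L)])
  r * f
}

# sp carbons are linear, sp2/aromatic trigonal, otherwise tetrahedral
atom_hybridization <- function(mol) {
  b <- mol$bonds
  vapply(seq_len(mol$natoms), function(i) {
    mine <- b[b$a1 == i | b$a2 == i, ]
    if (any(mine$order == 3L) || sum(mine$order == 2L) >= 2L) return(1L)
    if (any(mine$order == 2L) || any(mine$aromatic)) return(2L)
    3L
  }, integer(1))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place D at distance r from C, angle theta (D-C-B), dihedral phi (D-C-B-A)
nerf_place <- function(C, B, A, r, theta, phi) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(B - A, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) {
    tmp <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- cross3(tmp, bc)
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- cross3(n, bc)
  C + (-r * cos(theta)) * bc +
    (r * sin(theta) * cos(phi)) * m +
    (r * sin(theta) * sin(phi)) * n
}

#' Deterministic 3-D embedding of a molecule
#'
#' Builds coordinates by a breadth-first internal-coordinate walk (ideal bond
#' lengths from covalent radii, angles from hybridization, staggered default
#' torsions) and then relaxes them against a harmonic pseudo-potential over
#' bond distances (including ring-closing bonds absent from the spanning
#' tree), 1-3 distances, and a soft steric repulsion. The construction uses
#' no random numbers: the same molecule always embeds to the same geometry.
#' Geometries are coarse by design; energies always come from a backend.
#'
#' @param mol A `chpka_mol` or SMILES string.
#' @param refine Run the harmonic relaxation (default TRUE).
#' @return `natoms` x 3 coordinate matrix (angstrom).
#' @export
embed_molecule <- function(mol, refine = TRUE) {
  if (is.character(mol)) mol <- parse_mol(mol)
  n <- mol$natoms
  if (n == 1L) return(matrix(0, 1, 3))
  g <- mol$graph
  b <- mol$bonds
  el <- mol$atoms$element
  hyb <- atom_hybridization(mol)
  bridge_eids <- as.integer(igraph::bridges(g))
  ring_edge <- !(seq_len(nrow(b)) %in% bridge_eids)
  edge_of <- function(i, j) which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))[1]

  bf <- igraph::bfs(g, root = 1, father = TRUE, order = TRUE)
  ord <- as.integer(bf$order)
  father <- as.integer(bf$father)

  pos <- matrix(NA_real_, n, 3)
  anc1 <- matrix(NA_real_, n, 3)
  anc2 <- matrix(NA_real_, n, 3)
  nchild <- integer(n)
  root <- ord[1]
  pos[root, ] <- c(0, 0, 0)
  anc1[root, ] <- c(-1.5, 0, 0)
  anc2[root, ] <- c(-1.5, -1.5, 0)

  theta_of <- function(h) c(pi, 2 * pi / 3, acos(-1 / 3))[h]
  for (j in ord[-1]) {
    p <- father[j]
    e <- edge_of(p, j)
    r <- bond_length_target(el[p], el[j], b$order[e], b$aromatic[e])
    k <- nchild[p]
    nchild[p] <- k + 1L
    if (p == root && k == 0L) {
      theta <- pi
      phi <- 0
    } else {
      theta <- theta_of(hyb[p])
      # ring bonds open cis-first so rings pre-close; chains open anti-first
      in_ring_path <- ring_edge[e]
      offs <- if (in_ring_path) c(0, pi, 2 * pi / 3, 4 * pi / 3) else
        c(pi, pi / 3, 5 * pi / 3, 0)
      phi <- offs[(k %% 4L) + 1L]
    }
    pos[j, ] <- nerf_place(pos[p, ], anc1[p, ], anc2[p, ], r, theta, phi)
    anc1[j, ] <- pos[p, ]
    anc2[j, ] <- anc1[p, ]
    if (p == root && k == 0L) anc1[root, ] <- pos[j, ]
  }

  if (refine) pos <- refine_geometry(mol, pos, hyb)
  pos
}

# harmonic relaxation; analytic gradient keeps this fast enough for routine use
refine_geometry <- function(mol, pos, hyb, maxit = 200L) {
  n <- mol$natoms
  b <- mol$bonds
  el <- mol$atoms$element
  r0 <- bond_length_target(el[b$a1], el[b$a2], b$order, b$aromatic)
  pairs <- cbind(b$a1, b$a2)
  targ <- r0
  wt <- rep(1, nrow(b))

  # 1-3 distances from the angle at the shared atom
  adj <- lapply(seq_len(n), function(i) as.integer(igraph::neighbors(mol$graph, i)))
  theta_of <- c(pi, 2 * pi / 3, acos(-1 / 3))
  blen <- function(i, j) {
    e <- which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))[1]
    bond_length_target(el[i], el[j], b$order[e], b$aromatic[e])
  }
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    th <- theta_of[hyb[j]]
    cmb <- utils::combn(nb, 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; l <- cmb[2, k]
      d13 <- sqrt(blen(i, j)^2 + blen(j, l)^2 - 2 * blen(i, j) * blen(j, l) * cos(th))
      pairs <- rbind(pairs, c(i, l))
      targ <- c(targ, d13)
      wt <- c(wt, 0.3)
    }
  }

  gd <- igraph::distances(mol$graph)
  far <- which(upper.tri(gd) & gd >= 3, arr.ind = TRUE)

  obj <- function(x) {
    p <- matrix(x, n, 3)
    d <- sqrt(rowSums((p[pairs[, 1], , drop = FALSE] - p[pairs[, 2], , drop = FALSE])^2))
    v <- sum(wt * (d - targ)^2)
    if (nrow(far)) {
      dn <- sqrt(rowSums((p[far[, 1], , drop = FALSE] - p[far[, 2], , drop = FALSE])^2))
      v <- v + 0.05 * sum(pmax(0, 2 - dn)^2)
    }
    v
  }
  accumulate <- function(g, i1, i2, contrib) {
    idx <- c(i1, i2)
    s <- rowsum(rbind(contrib, -contrib), idx)
    rows <- as.integer(rownames(s))
    g[rows, ] <- g[rows, ] + s
    g
  }
  grad <- function(x) {
    p <- matrix(x, n, 3)
    g <- matrix(0, n, 3)
    dvec <- p[pairs[, 1], , drop = FALSE] - p[pairs[, 2], , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    coef <- 2 * wt * (d - targ) / pmax(d, 1e-9)
    g <- accumulate(g, pairs[, 1], pairs[, 2], coef * dvec)
    if (nrow(far)) {
      dvec <- p[far[, 1], , drop = FALSE] - p[far[, 2], , drop = FALSE]
      dn <- sqrt(rowSums(dvec^2))
      act <- dn < 2
      if (any(act)) {
        coef <- 0.05 * 2 * (dn[act] - 2) / pmax(dn[act], 1e-9)
        g <- accumulate(g, far[act, 1], far[act, 2],
                        coef * dvec[act, , drop = FALSE])
      }
    }
    as.vector(g)
  }
  res <- stats::optim(as.vector(pos), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-8))
  matrix(res$par, n, 3)
}

# rotate the subtree on the a2 side of rotatable bond (a1, a2) by delta
apply_torsion <- function(mol, pos, a1, a2, delta) {
  g2 <- igraph::delete_edges(mol$graph, igraph::get_edge_ids(mol$graph, c(a1, a2)))
  comp <- igraph::components(g2)$membership
  side <- which(comp == comp[a2])
  axis <- pos[a2, ] - pos[a1, ]
  axis <- axis / sqrt(sum(axis^2))
  ct <- cos(delta); st <- sin(delta)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + st * K + (1 - ct) * (K %*% K)
  moving <- setdiff(side, a2)
  if (length(moving)) {
    rel <- sweep(pos[moving, , drop = FALSE], 2, pos[a2, ])
    pos[moving, ] <- sweep(rel %*% t(R), 2, pos[a2, ], `+`)
  }
  pos
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a conformer ensemble for a species
#'
#' The base geometry comes from the deterministic embedding; additional
#' conformers are seeded random torsion rotations about every rotatable bond.
#' The ensemble holds `min(1 + 3 * n_rot, 20)` conformers (capped further by
#' `max_conformers`); energies are unset until a backend assigns them.
#'
#' @param species_smiles SMILES of the species (neutral or anion).
#' @param seed Integer seed; fixed seed implies identical geometries.
#' @param max_conformers Hard cap on the ensemble size (default 20).
#' @return A `chpka_ensemble`.
#' @export
generate_ensemble <- function(species_smiles, seed = 1L, max_conformers = 20L) {
  mol <- parse_mol(species_smiles)
  rb <- rotatable_bonds(mol)
  n_rot <- nrow(rb)
  count <- min(conformer_count(n_rot), max_conformers)
  base <- embed_molecule(mol)
  confs <- with_seed(seed, {
    lapply(seq_len(count) - 1L, function(cid) {
      xyz <- base
      if (cid > 0L && n_rot > 0L) {
        for (k in seq_len(n_rot)) {
          delta <- stats::runif(1, 0, 2 * pi)
          xyz <- apply_torsion(mol, xyz, rb$a1[k] + 1L, rb$a2[k] + 1L, delta)
        }
      }
      list(conformer_id = cid, xyz = xyz, energy = NA_real_)
    })
  })
  structure(
    list(species_smiles = mol$smiles, elements = mol$atoms$element,
         heavy = mol$atoms$is_heavy, n_rot = n_rot, conformers = confs,
         mol = mol),
    class = "chpka_ensemble"
  )
}

#' @export
print.chpka_ensemble <- function(x, ...) {
  cat("<chpka_ensemble> ", x$species_smiles, ": ", length(x$conformers),
      " conformer(s), n_rot = ", x$n_rot, "\n", sep = "")
  invisible(x)
}

ensemble_energies <- function(ensemble) {
  vapply(ensemble$conformers, function(cf) cf$energy, numeric(1))
}

check_nonempty <- function(ensemble) {
  if (!length(ensemble$conformers)) {
    abort(paste0("Empty ensemble for '", ensemble$species_smiles, "'"),
          class = "chpka_empty_ensemble")
  }
}

#' Assign backend energies to every conformer
#'
#' @param ensemble A `chpka_ensemble`.
#' @param backend An [energy_backend()].
#' @return The ensemble with `energy` set (kcal/mol).
#' @export
assign_energies <- function(ensemble, backend) {
  check_nonempty(ensemble)
  ensemble$conformers <- lapply(ensemble$conformers, function(cf) {
    cf$energy <- backend_energy(backend, ensemble$species_smiles, cf$xyz,
                                ensemble$elements)
    cf
  })
  ensemble
}

#' Drop conformers outside a relative-energy window
#'
#' Retains conformers whose energy lies within `window_kcal` of the ensemble
#' minimum (inclusive: a conformer exactly at the window edge survives, since
#' only those *above* the window are removed).
#'
#' @param ensemble A `chpka_ensemble` with energies assigned.
#' @param window_kcal Window in kcal/mol (default 3).
#' @return The pruned ensemble.
#' @export
prune_by_energy <- function(ensemble, window_kcal = 3.0) {
  check_nonempty(ensemble)
  e <- ensemble_energies(ensemble)
  if (anyNA(e)) abort("All conformers need energies before pruning")
  keep <- (e - min(e)) <= window_kcal
  ensemble$conformers <- ensemble$conformers[keep]
  ensemble
}

#' Best-fit RMSD between two conformations
#'
#' Root mean square deviation after optimal superposition (Kabsch algorithm)
#' with the identity atom mapping.
#'
#' @param a,b n x 3 coordinate matrices over the same atoms in the same order.
#' @return RMSD in the coordinate units.
#' @export
rmsd_kabsch <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(ac, bc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((ac %*% t(R) - bc)^2)))
}

#' Pairwise heavy-atom RMSD matrix of an ensemble
#'
#' @param ensemble A `chpka_ensemble`.
#' @return Symmetric matrix of best-fit heavy-atom RMSDs.
#' @export
pairwise_rmsd <- function(ensemble) {
  check_nonempty(ensemble)
  hv <- which(ensemble$heavy)
  xs <- lapply(ensemble$conformers, function(cf) cf$xyz[hv, , drop = FALSE])
  m <- length(xs)
  D <- matrix(0, m, m)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        D[i, j] <- D[j, i] <- rmsd_kabsch(xs[[i]], xs[[j]])
      }
    }
  }
  D
}

#' Butina clustering of a distance matrix
#'
#' Leader-style clustering: repeatedly pick the unassigned item with the most
#' unassigned neighbours within `threshold` (ties resolved to the smallest
#' index), make it a centroid, and assign it together with those neighbours.
#' Neighbour counts are recomputed over the remaining items each round.
#'
#' @param d Symmetric distance matrix.
#' @param threshold Neighbour distance cutoff.
#' @return List with `centroids` (indices, in selection order) and `cluster`
#'   (centroid index of each item).
#' @export
butina_cluster <- function(d, threshold) {
  n <- nrow(d)
  if (n == 0L) return(list(centroids = integer(), cluster = integer()))
  nb <- lapply(seq_len(n), function(i) setdiff(which(d[i, ] <= threshold), i))
  unassigned <- rep(TRUE, n)
  cluster <- integer(n)
  centroids <- integer(0)
  while (any(unassigned)) {
    cnt <- rep(-1L, n)
    idx <- which(unassigned)
    cnt[idx] <- vapply(idx, function(i) sum(unassigned[nb[[i]]]), integer(1))
    ci <- which.max(cnt) # ties -> smallest index
    members <- c(ci, nb[[ci]][unassigned[nb[[ci]]]])
    cluster[members] <- ci
    unassigned[members] <- FALSE
    centroids <- c(centroids, ci)
  }
  list(centroids = centroids, cluster = cluster)
}

#' Reduce an ensemble to one representative conformer per Butina cluster
#'
#' Clusters by best-fit heavy-atom RMSD and keeps one conformer per cluster.
#' With `representative = "centroid"` that is the Butina centroid itself;
#' with `"lowest_energy"` it is the cluster member of lowest energy, which
#' guarantees the downstream energy minimum is never discarded by
#' deduplication. The default, `"auto"`, picks the lowest-energy member when
#' energies have been assigned and the centroid otherwise.
#'
#' @param ensemble A `chpka_ensemble`.
#' @param rmsd_threshold_A Heavy-atom RMSD threshold in angstrom (default 0.5).
#' @param representative `"auto"`, `"centroid"`, or `"lowest_energy"`.
#' @return Ensemble containing one conformer per cluster.
#' @export
cluster_butina <- function(ensemble, rmsd_threshold_A = 0.5,
                           representative = c("auto", "centroid", "lowest_energy")) {
  representative <- match.arg(representative)
  check_nonempty(ensemble)
  e <- ensemble_energies(ensemble)
  if (representative == "auto") {
    representative <- if (anyNA(e)) "centroid" else "lowest_energy"
  }
  D <- pairwise_rmsd(ensemble)
  res <- butina_cluster(D, rmsd_threshold_A)
  keep <- if (representative == "centroid") {
    res$centroids
  } else {
    if (anyNA(e)) abort("lowest_energy representatives need energies")
    ids <- vapply(ensemble$conformers, function(cf) cf$conformer_id, integer(1))
    vapply(res$centroids, function(ci) {
      members <- which(res$cluster == ci)
      members[order(e[members], ids[members])[1]]
    }, integer(1))
  }
  ensemble$conformers <- ensemble$conformers[sort(keep)]
  ensemble
}

#' Lowest-energy conformer of an ensemble
#'
#' @param ensemble A `chpka_ensemble` with energies.
#' @return The conformer (list with `conformer_id`, `xyz`, `energy`); energy
#'   ties resolve to the smallest `conformer_id`.
#' @export
lowest_energy_conformer <- function(ensemble) {
  check_nonempty(ensemble)
  e <- ensemble_energies(ensemble)
  if (anyNA(e)) abort("All conformers need energies")
  ids <- vapply(ensemble$conformers, function(cf) cf$conformer_id, integer(1))
  best <- order(e, ids)[1]
  ensemble$conformers[[best]]
}

#' Write conformer coordinates in XYZ format
#'
#' @param elements Character vector of element symbols.
#' @param xyz n x 3 coordinate matrix.
#' @param path Output file.
#' @param comment Second-line comment.
#' @export
write_xyz <- function(elements, xyz, path, comment = "") {
  lines <- c(length(elements), comment,
             sprintf("%-3s %14.8f %14.8f %14.8f", elements,
                     xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file
#'
#' @param path XYZ file path.
#' @return List with `elements`, `xyz`, `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  list(
    elements = vapply(rows, `[`, character(1), 1),
    xyz = matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), n, 3, byrow = TRUE),
    comment = lines[2]
  )
}
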