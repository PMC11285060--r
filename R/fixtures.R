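core_fixture_smiles <- c(
  # ketones and 1,3-dicarbonyls
  "CC(C)=O", "CCC(C)=O", "CC(=O)c1ccccc1", "O=C1CCCCC1", "CC(=O)CC(C)=O",
  "CC(=O)CC(=O)OC",
  # esters
  "COC(C)=O", "CCOC(C)=O", "COC(=O)CC(=O)OC",
  # nitriles
  "CC#N", "CCC#N", "N#CCc1ccccc1", "N#CCC#N",
  # heteroaromatics
  "c1ccncc1", "c1cncnc1", "c1ccsc1", "c1ccoc1", "Cn1cccc1", "Cc1ccncc1",
  "Cc1cccnc1",
  # aromatics
  "c1ccccc1", "Cc1ccccc1", "Cc1ccccc1C", "CCc1ccccc1",
  # alkanes
  "C", "CC", "CCC", "CC(C)C", "CCCC",
  # sulfur, nitro, amide, ether
  "CS(C)=O", "CS(C)(=O)=O", "C[N+](=O)[O-]", "CN(C)C=O", "CC(=O)N(C)C",
  "C1CCOC1", "COC"
)

#' Embedded fixture molecules
#'
#' A literal set of small organic molecules spanning the chemistry classes
#' the workflow targets (ketones, esters, nitriles, heteroaromatics,
#' aromatics, alkanes, sulfoxides/sulfones, nitroalkanes, amides, ethers),
#' extended deterministically with homolog series (chain-lengthened ketones,
#' nitriles, esters, alkylarenes) when more molecules are requested. All
#' SMILES are canonical and unique.
#'
#' @param n Number of molecules (default: the whole core set).
#' @return Character vector of canonical SMILES.
#' @export
fixture_smiles <- function(n = length(core_fixture_smiles)) {
  out <- vapply(core_fixture_smiles, canonical_smiles, character(1),
                USE.NAMES = FALSE)
  if (n <= length(out)) return(out[seq_len(n)])
  templates <- list(
    function(k, m) paste0(strrep("C", k), "C(=O)", strrep("C", m)),
    function(k, m) paste0(strrep("C", k), "C#N"),
    function(k, m) paste0("CCOC(=O)", strrep("C", k)),
    function(k, m) paste0(strrep("C", k), "c1ccccc1"),
    function(k, m) paste0(strrep("C", k), "c1ccncc1"),
    function(k, m) paste0("COC(=O)", strrep("C", k), "C#N"),
    function(k, m) paste0("CC(C)", strrep("C", k), "C(C)=O"),
    function(k, m) paste0(strrep("C", k), "S(=O)(=O)", strrep("C", m)),
    function(k, m) paste0(strrep("C", k), "N(C)C=O"),
    function(k, m) paste0(strrep("C", k), "Oc1ccccc1"),
    function(k, m) paste0(strrep("C", k), "OC(=O)", strrep("C", m)),
    function(k, m) paste0(strrep("C", k), "c1ccc(", strrep("C", m), ")cc1"),
    function(k, m) paste0(strrep("C", k), "c1ccco1"),
    function(k, m) paste0(strrep("C", k), "c1cccs1"),
    function(k, m) paste0(strrep("C", k), "C(=O)CC#N"),
    function(k, m) paste0("N#C", strrep("C", k), "C#N"),
    function(k, m) paste0(strrep("C", k), "C(=O)N(C)", strrep("C", m)),
    function(k, m) paste0(strrep("C", k), "S(=O)", strrep("C", m)),
    function(k, m) paste0(strrep("C", k), "[N+](=O)[O-]"),
    function(k, m) paste0(strrep("C", k), "OC(=O)c1ccccc1")
  )
  seen <- new.env(parent = emptyenv())
  for (s in out) assign(s, TRUE, envir = seen)
  for (km in 1:8) {
    for (ti in seq_along(templates)) {
      for (m in 1:km) {
        if (length(out) >= n) return(out[seq_len(n)])
        smi <- tryCatch(canonical_smiles(templates[[ti]](km, m)),
                        error = function(e) NULL)
        if (!is.null(smi) && !isTRUE(seen[[smi]])) {
          assign(smi, TRUE, envir = seen)
          out <- c(out, smi)
        }
      }
    }
  }
  if (length(out) < n) {
    abort(paste0("Can only generate ", length(out), " distinct fixture molecules"))
  }
  out[seq_len(n)]
}

# Functional-group classification of a C-H site in its neutral parent.
# The base values track broad DMSO acidity trends (doubly activated <<
# singly activated carbonyl/nitrile < benzylic < heteroaromatic < aromatic
# < alkyl); they exist to give the synthetic world learnable structure, not
# chemical accuracy.
site_base_pka <- function(mol, atom_index) {
  i <- atom_index + 1L
  at <- mol$atoms
  b <- mol$bonds
  nb <- as.integer(igraph::neighbors(mol$graph, i))
  nb <- nb[at$is_heavy[nb]]
  bond_between <- function(x, y) b[(b$a1 == x & b$a2 == y) | (b$a1 == y & b$a2 == x), ]
  dbl_to <- function(j, el) {
    jnb <- as.integer(igraph::neighbors(mol$graph, j))
    any(vapply(jnb, function(k) {
      at$element[k] == el && bond_between(j, k)$order[1] == 2L
    }, logical(1)))
  }
  single_to <- function(j, el) {
    jnb <- as.integer(igraph::neighbors(mol$graph, j))
    any(vapply(jnb, function(k) {
      at$element[k] == el && bond_between(j, k)$order[1] == 1L
    }, logical(1)))
  }
  n_carbonyl <- n_ester <- n_amide <- n_nitrile <- n_nitro <- n_so <- 0L
  benzylic <- FALSE
  for (j in nb) {
    el <- at$element[j]
    if (el == "C" && at$aromatic[j] && !at$aromatic[i]) benzylic <- TRUE
    if (el == "C" && dbl_to(j, "O")) {
      if (single_to(j, "O")) n_ester <- n_ester + 1L
      else if (single_to(j, "N")) n_amide <- n_amide + 1L
      else n_carbonyl <- n_carbonyl + 1L
    }
    if (el == "C") {
      jnb <- as.integer(igraph::neighbors(mol$graph, j))
      if (any(vapply(jnb, function(k) at$element[k] == "N" &&
                       bond_between(j, k)$order[1] == 3L, logical(1)))) {
        n_nitrile <- n_nitrile + 1L
      }
    }
    if (el == "N" && at$formal_charge[j] == 1L) n_nitro <- n_nitro + 1L
    if (el == "S" && dbl_to(j, "O")) n_so <- n_so + 1L
  }
  ewg <- n_carbonyl + n_ester + n_amide + n_nitrile + n_nitro + n_so
  arom <- at$aromatic[i]
  het_adjacent <- arom && any(at$element[nb] %in% c("N", "O", "S") & at$aromatic[nb])
  if (ewg >= 2L) return(list(class = "doubly_activated", base = 12))
  if (n_nitro == 1L) return(list(class = "nitroalkane", base = 17))
  if (n_carbonyl == 1L) return(list(class = "alpha_carbonyl", base = 26))
  if (n_ester == 1L) return(list(class = "alpha_ester", base = 30))
  if (n_nitrile == 1L) return(list(class = "alpha_nitrile", base = 31))
  if (n_amide == 1L) return(list(class = "alpha_amide", base = 33))
  if (n_so == 1L) return(list(class = "alpha_sulfinyl", base = 32))
  if (benzylic) return(list(class = "benzylic", base = 43))
  if (het_adjacent) return(list(class = "heteroaromatic", base = 38))
  if (arom) return(list(class = "aromatic", base = 44))
  list(class = "alkyl", base = 51)
}

#' Build a synthetic world with known ground truth
#'
#' The world stands in for a QM dataset: fixture molecules, per-site "true"
#' pKa values assigned by a deterministic functional-group rule plus a
#' seeded per-site jitter, and a deprotonation-energy oracle constructed to
#' invert the calibration exactly:
#' `delta_g = (pka_true - b_true) / a_true + N(0, noise_sigma / |a_true|)`.
#' At `noise_sigma = 0` the full pipeline (energies, calibration, prediction)
#' must return every site's true pKa exactly; regenerating with the same
#' seed reproduces every value bit for bit.
#'
#' @param seed Integer seed.
#' @param a_true,b_true Calibration constants (slope in pKa per kcal/mol,
#'   nonzero; intercept in pKa units).
#' @param noise_sigma Gaussian noise on the oracle, in pKa units (>= 0).
#' @param n_molecules Number of fixture molecules (default: core set).
#' @return A `chpka_world`: `molecules`, `sites` (with `site_class`,
#'   `pka_true`, `delta_g`), `calibration` (per-molecule `delta_g_min`,
#'   `pka_exp`), and the energy table behind [surrogate_energy_backend()].
#' @export
make_world <- function(seed = 1L, a_true = 0.35, b_true = -150,
                       noise_sigma = 1.0, n_molecules = NULL) {
  if (a_true == 0) abort("a_true must be nonzero", class = "chpka_input_error")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0", class = "chpka_input_error")
  smi <- fixture_smiles(n_molecules %||% length(core_fixture_smiles))
  molecules <- read_molecules(smi, id = sprintf("fx%03d", seq_along(smi)))
  sites <- ch_sites(molecules)
  cls <- purrr::map2(sites$parent_id, sites$atom_index, function(pid, ai) {
    site_base_pka(molecules$mol[[match(pid, molecules$id)]], ai)
  })
  sites$site_class <- vapply(cls, `[[`, character(1), "class")
  base <- vapply(cls, `[[`, numeric(1), "base")
  ns <- nrow(sites)
  draws <- with_seed(seed, {
    list(jitter = stats::runif(ns, -2, 2),
         noise = stats::rnorm(ns, 0, noise_sigma / abs(a_true)))
  })
  sites$pka_true <- base + draws$jitter
  sites$delta_g <- (sites$pka_true - b_true) / a_true + draws$noise

  e_neutral <- setNames(-1000 - 17 * molecules$atom_count, molecules$smiles)
  parent_smiles <- molecules$smiles[match(sites$parent_id, molecules$id)]
  e_anion <- setNames(unname(e_neutral[parent_smiles]) + sites$delta_g,
                      sites$anion_smiles)
  calibration <- sites %>%
    group_by(.data$parent_id) %>%
    summarise(delta_g_min = min(.data$delta_g),
              pka_exp = min(.data$pka_true), .groups = "drop") %>%
    dplyr::rename(id = "parent_id")

  structure(
    list(seed = seed, a_true = a_true, b_true = b_true,
         noise_sigma = noise_sigma, molecules = molecules, sites = sites,
         calibration = calibration,
         energies = c(e_neutral, e_anion)),
    class = "chpka_world"
  )
}

#' @export
print.chpka_world <- function(x, ...) {
  cat("<chpka_world> ", nrow(x$molecules), " molecules, ", nrow(x$sites),
      " C-H sites; a = ", x$a_true, ", b = ", x$b_true,
      ", sigma = ", x$noise_sigma, " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Deterministic energy backend over a synthetic world
#'
#' Species energies are fixed per species (geometry-independent, so the
#' conformer stages cannot perturb them) and constructed so that
#' `E(anion) - E(neutral)` equals the world's deprotonation-energy oracle for
#' every site.
#'
#' @param world A [make_world()] object.
#' @return A `chpka_backend`; asking it about a species outside the world is
#'   an error.
#' @export
surrogate_energy_backend <- function(world) {
  stopifnot(inherits(world, "chpka_world"))
  tab <- world$energies
  energy_backend("surrogate", function(species, xyz, elements) {
    if (!species %in% names(tab)) {
      abort(paste0("Species '", species, "' is not part of this world"),
            class = "chpka_backend_error")
    }
    unname(tab[[species]])
  })
}

#' Deterministic surrogate charge provider
#'
#' Assigns each atom a charge as a fixed function of its element,
#' aromaticity, formal charge, and heteroatom-neighbour count, then shifts
#' all charges uniformly so they sum to the molecule's net formal charge.
#' Being a function of the local environment only, it respects molecular
#' symmetry exactly; it involves no conformers and ignores the seed.
#'
#' @return A [charge_provider()].
#' @export
surrogate_charge_provider <- function() {
  base <- c(H = 0.06, C = -0.05, N = -0.28, O = -0.38, F = -0.18, S = -0.12,
            Cl = -0.09, Br = -0.07, I = -0.05, P = -0.10, B = 0.10)
  charge_provider("surrogate", function(mol, seed) {
    at <- mol$atoms
    q0 <- unname(base[at$element])
    q0[is.na(q0)] <- 0
    n_het <- vapply(seq_len(mol$natoms), function(i) {
      nb <- as.integer(igraph::neighbors(mol$graph, i))
      sum(!at$element[nb] %in% c("C", "H"))
    }, integer(1))
    q0 <- q0 + 0.04 * at$aromatic + 0.07 * n_het + 0.30 * at$formal_charge
    net <- sum(at$formal_charge)
    q0 + (net - sum(q0)) / mol$natoms
  })
}

#' Write the fixture world to disk as pipeline inputs
#'
#' Emits the `.smi` molecule list, the per-molecule experimental-pKa CSV the
#' calibration step consumes, and the per-site deprotonation-energy CSV, so a
#' full run can be driven from files alone.
#'
#' @param seed World seed.
#' @param out_dir Output directory (created).
#' @param ... Passed to [make_world()].
#' @return Invisibly, the file paths.
#' @export
fixtures_generate <- function(seed = 1L, out_dir, ...) {
  world <- make_world(seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  smi_path <- file.path(out_dir, "molecules.smi")
  writeLines(paste(world$molecules$smiles, world$molecules$id), smi_path)
  pka_path <- file.path(out_dir, "pka_exp.csv")
  utils::write.csv(as.data.frame(world$calibration), pka_path, row.names = FALSE)
  dg_path <- file.path(out_dir, "delta_g.csv")
  utils::write.csv(
    as.data.frame(world$sites[, c("parent_id", "atom_index", "delta_g")]),
    dg_path, row.names = FALSE)
  invisible(list(smi = smi_path, pka = pka_path, delta_g = dg_path))
}
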