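#' Deprotonate a single carbon atom
#'
#' Removes one hydrogen from the carbon at `atom_index` and places a formal
#' charge of -1 on it, yielding the carbanion formed by heterolytic C-H bond
#' cleavage. All other atoms are untouched; the result is returned as a
#' canonical SMILES so that chemically equivalent sites collapse to the same
#' string.
#'
#' @param mol A `chpka_mol` (or SMILES string).
#' @param atom_index 0-based index into the canonical atom order.
#' @return Canonical SMILES of the carbanion.
#' @export
deprotonate <- function(mol, atom_index) {
  if (is.character(mol)) mol <- parse_mol(mol)
  i <- atom_index + 1L
  if (atom_index < 0 || i > mol$natoms) {
    abort(paste0("atom_index ", atom_index, " out of range"),
          class = "chpka_index_error")
  }
  at <- mol$atoms
  if (at$element[i] != "C" || at$n_h[i] < 1L) {
    abort(paste0("Atom ", atom_index, " (", at$element[i],
                 ") is not a carbon bearing at least one hydrogen"),
          class = "chpka_invalid_site")
  }

  # drop the highest-index hydrogen neighbour (hydrogens sit at the end of
  # the canonical order, so heavy-atom indices are unaffected)
  nb <- as.integer(igraph::neighbors(mol$graph, i))
  h <- max(nb[at$element[nb] == "H"])

  b <- mol$bonds
  keep <- b$a1 != h & b$a2 != h
  b2 <- b[keep, , drop = FALSE]
  shift <- function(j) ifelse(j > h, j - 1L, j)
  b2$a1 <- shift(b2$a1)
  b2$a2 <- shift(b2$a2)

  charge <- at$formal_charge
  charge[i] <- charge[i] - 1L
  charge <- charge[-h]
  element <- at$element[-h]

  n2 <- length(element)
  atom_block <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, element)
  bond_block <- sprintf("%3d%3d%3d  0  0  0  0", b2$a1, b2$a2, b2$order)
  chg_idx <- which(charge != 0L)
  chg_lines <- if (length(chg_idx)) {
    vapply(chg_idx, function(j) sprintf("M  CHG  1 %3d %3d", j, charge[j]),
           character(1))
  } else character()
  sdf <- paste(c(
    "", " chpka", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n2, nrow(b2)),
    atom_block, bond_block, chg_lines, "M  END", "$$$$", ""
  ), collapse = "\n")

  out <- ob_convert("SDF", "CAN", sdf)
  if (!nzchar(out)) {
    abort(paste0("Open Babel failed to canonicalize the anion of '",
                 mol$smiles, "' at atom ", atom_index),
          class = "chpka_parse_error")
  }
  out
}

#' Enumerate symmetry-distinct C-H deprotonation sites
#'
#' Each site is one equivalence class of H-bearing carbons; deprotonating any
#' member gives the same carbanion. The default method computes one anion per
#' graph-symmetry class; `method = "exhaustive"` deprotonates every H-bearing
#' carbon individually and deduplicates by canonical anion SMILES. The two
#' must agree, and the test suite checks that they do.
#'
#' Carbons that already carry a formal charge or a radical are skipped with a
#' warning: the workflow is defined for closed-shell neutral C-H acids.
#'
#' @param mol A `chpka_mol` or SMILES string.
#' @param parent_id Identifier recorded in the output.
#' @param method `"symmetry"` (default) or `"exhaustive"`.
#' @return A tibble with one row per site: `parent_id`, `atom_index` (0-based,
#'   smallest index in the equivalence class), `n_equivalent_h` (hydrogens
#'   pooled over the class), `anion_smiles`. Sorted by `atom_index`. Molecules
#'   without C-H bonds yield zero rows.
#' @export
enumerate_ch_sites <- function(mol, parent_id = NULL,
                               method = c("symmetry", "exhaustive")) {
  method <- match.arg(method)
  if (is.character(mol)) mol <- parse_mol(mol)
  parent_id <- parent_id %||% mol$smiles
  at <- mol$atoms
  cand <- which(at$element == "C" & at$n_h >= 1L)
  skip <- cand[at$formal_charge[cand] != 0L | at$radical[cand] != 0L]
  if (length(skip)) {
    warn(paste0("Skipping charged/radical carbon site(s) at atom index ",
                paste(at$atom_index[skip], collapse = ", "), " in '",
                mol$smiles, "'"))
    cand <- setdiff(cand, skip)
  }
  empty <- tibble(parent_id = character(), atom_index = integer(),
                  n_equivalent_h = integer(), anion_smiles = character())
  if (!length(cand)) return(empty)

  if (method == "symmetry") {
    cls <- mol$symmetry_class[cand]
    rows <- lapply(split(cand, cls), function(members) {
      rep_i <- min(members)
      tibble(
        atom_index = at$atom_index[rep_i],
        n_equivalent_h = sum(at$n_h[members]),
        anion_smiles = deprotonate(mol, at$atom_index[rep_i])
      )
    })
    out <- bind_rows(rows)
  } else {
    out <- bind_rows(lapply(cand, function(i) tibble(
      atom_index = at$atom_index[i],
      n_equivalent_h = at$n_h[i],
      anion_smiles = deprotonate(mol, at$atom_index[i])
    )))
  }
  out %>%
    group_by(.data$anion_smiles) %>%
    summarise(atom_index = min(.data$atom_index),
              n_equivalent_h = sum(.data$n_equivalent_h), .groups = "drop") %>%
    mutate(parent_id = parent_id) %>%
    select("parent_id", "atom_index", "n_equivalent_h", "anion_smiles") %>%
    arrange(.data$atom_index)
}

#' Enumerate C-H sites for a whole molecule table
#'
#' @param molecules A molecule table from [read_molecules()].
#' @param method Passed to [enumerate_ch_sites()].
#' @return A tibble of sites across all molecules.
#' @export
ch_sites <- function(molecules, method = c("symmetry", "exhaustive")) {
  method <- match.arg(method)
  bind_rows(purrr::map2(molecules$mol, molecules$id,
                        function(m, id) enumerate_ch_sites(m, id, method)))
}

#' Write a site table to CSV
#'
#' @param sites Site tibble from [ch_sites()].
#' @param path Output path.
#' @export
write_sites_csv <- function(sites, path) {
  utils::write.csv(as.data.frame(sites), path, row.names = FALSE)
  invisible(path)
}
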