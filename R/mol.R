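#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter arrange group_by summarise ungroup
#'   bind_rows left_join select distinct n
NULL

# package-level cache: parsing the same SMILES twice is common (anions reappear
# as species in the energy pipeline), and each parse costs three Open Babel
# conversions
.chpka_cache <- new.env(parent = emptyenv())

ob_convert <- function(from, to, source, add_hydrogens = FALSE) {
  out <- suppressWarnings(if (add_hydrogens) {
    ChemmineOB::convertFormat(from, to, source,
                              options = data.frame(names = "h", args = ""))
  } else {
    ChemmineOB::convertFormat(from, to, source)
  })
  trimws(out)
}

#' Canonicalize a SMILES string
#'
#' Returns the Open Babel canonical SMILES. Canonicalization is the basis of
#' all deduplication in the package: two sites are chemically equivalent
#' exactly when their deprotonated species canonicalize to the same string.
#'
#' @param smiles A single SMILES string.
#' @return A canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  out <- ob_convert("SMI", "CAN", smiles)
  if (!nzchar(out)) {
    abort(paste0("Unparseable SMILES: '", smiles, "'"), class = "chpka_parse_error")
  }
  out
}

parse_sdf_block <- function(sdf) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  cnt_i <- grep("V2000", lines)[1]
  if (is.na(cnt_i)) abort("Malformed SDF block", class = "chpka_parse_error")
  cnt <- lines[cnt_i]
  natoms <- as.integer(substr(cnt, 1, 3))
  nbonds <- as.integer(substr(cnt, 4, 6))
  atom_lines <- lines[(cnt_i + 1):(cnt_i + natoms)]
  bond_lines <- if (nbonds > 0) lines[(cnt_i + natoms + 1):(cnt_i + natoms + nbonds)] else character()
  element <- trimws(substr(atom_lines, 32, 34))
  a1 <- as.integer(substr(bond_lines, 1, 3))
  a2 <- as.integer(substr(bond_lines, 4, 6))
  order <- as.integer(substr(bond_lines, 7, 9))
  charge <- integer(natoms)
  radical <- integer(natoms)
  prop <- lines[grepl("^M  (CHG|RAD)", lines)]
  for (p in prop) {
    kind <- substr(p, 4, 6)
    k <- as.integer(substr(p, 7, 9))
    for (j in seq_len(k)) {
      off <- 10 + (j - 1) * 8
      idx <- as.integer(substr(p, off, off + 3))
      val <- as.integer(substr(p, off + 4, off + 7))
      if (kind == "CHG") charge[idx] <- val else radical[idx] <- val
    }
  }
  list(
    header = lines[1:(cnt_i - 1)], natoms = natoms, nbonds = nbonds,
    element = element, charge = charge, radical = radical,
    bonds = tibble(a1 = a1, a2 = a2, order = order)
  )
}

parse_mol2_flags <- function(mol2) {
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  sec <- grep("^@<TRIPOS>", lines)
  get_section <- function(name) {
    i <- which(lines == paste0("@<TRIPOS>", name))
    if (!length(i)) return(character())
    nxt <- sec[sec > i]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    lines[(i + 1L):end]
  }
  atom_type <- vapply(strsplit(trimws(get_section("ATOM")), "\\s+"),
                      function(x) x[6], character(1))
  bond_rows <- strsplit(trimws(get_section("BOND")), "\\s+")
  list(
    atom_aromatic = grepl("\\.ar$", atom_type),
    bond_aromatic = tibble(
      a1 = vapply(bond_rows, function(x) as.integer(x[2]), integer(1)),
      a2 = vapply(bond_rows, function(x) as.integer(x[3]), integer(1)),
      aromatic = vapply(bond_rows, function(x) x[4] == "ar", logical(1))
    )
  )
}

#' Parse a molecule into the package's internal representation
#'
#' The input is canonicalized first, so the atom order (and therefore every
#' `atom_index` reported by the package) is the canonical atom order: heavy
#' atoms in canonical-SMILES order followed by explicit hydrogens. Parsing the
#' same molecule from any atom permutation of its SMILES yields the identical
#' object.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `chpka_mol`: atom and bond tables (explicit
#'   hydrogens), aromaticity flags, the molecular graph, and per-atom symmetry
#'   classes (graph-automorphism orbits).
#' @export
parse_mol <- function(smiles) {
  can <- canonical_smiles(smiles)
  key <- paste0("mol:", can)
  if (!is.null(.chpka_cache[[key]])) return(.chpka_cache[[key]])

  sdf <- ob_convert("SMI", "SDF", can, add_hydrogens = TRUE)
  mol2 <- ob_convert("SMI", "MOL2", can, add_hydrogens = TRUE)
  sd <- parse_sdf_block(sdf)
  fl <- parse_mol2_flags(mol2)
  if (length(fl$atom_aromatic) != sd$natoms) {
    abort(paste0("Inconsistent atom count across formats for '", can, "'"),
          class = "chpka_parse_error")
  }

  bonds <- sd$bonds
  # mark aromatic bonds using the MOL2 bond list (SDF is kekulized)
  key_m <- paste(pmin(fl$bond_aromatic$a1, fl$bond_aromatic$a2),
                 pmax(fl$bond_aromatic$a1, fl$bond_aromatic$a2))
  arom <- fl$bond_aromatic$aromatic[match(
    paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2)), key_m)]
  bonds$aromatic <- !is.na(arom) & arom

  g <- igraph::make_graph(rbind(bonds$a1, bonds$a2), n = sd$natoms,
                          directed = FALSE)
  n_h <- vapply(seq_len(sd$natoms), function(i) {
    nb <- as.integer(igraph::neighbors(g, i))
    sum(sd$element[nb] == "H")
  }, integer(1))

  atoms <- tibble(
    atom_index = seq_len(sd$natoms) - 1L,
    element = sd$element,
    formal_charge = sd$charge,
    radical = sd$radical,
    aromatic = fl$atom_aromatic,
    n_h = n_h,
    is_heavy = sd$element != "H"
  )

  mol <- structure(
    list(smiles = can, atoms = atoms, bonds = bonds, graph = g,
         sdf = sdf, natoms = sd$natoms),
    class = "chpka_mol"
  )
  mol$symmetry_class <- symmetry_classes(mol)
  .chpka_cache[[key]] <- mol
  mol
}

#' @export
print.chpka_mol <- function(x, ...) {
  cat("<chpka_mol> ", x$smiles, "\n  atoms: ", x$natoms,
      " (", sum(x$atoms$is_heavy), " heavy), bonds: ", nrow(x$bonds), "\n",
      sep = "")
  invisible(x)
}

#' Per-atom symmetry classes from graph automorphism orbits
#'
#' Atoms receive the same class exactly when some automorphism of the
#' molecular graph (vertices colored by element and formal charge, edges by
#' bond class with aromatic bonds distinguished from their kekulized orders)
#' maps one onto the other. Edge colors are encoded by subdividing each bond
#' with a dummy vertex colored by the bond class, since igraph automorphisms
#' support vertex colors only.
#'
#' @param mol A `chpka_mol`.
#' @return Integer vector of length `natoms`; equal values mark topologically
#'   equivalent atoms. Classes are labeled by the smallest 0-based atom index
#'   they contain.
#' @export
symmetry_classes <- function(mol) {
  n <- mol$natoms
  b <- mol$bonds
  nb <- nrow(b)
  edges <- integer(0)
  for (i in seq_len(nb)) {
    bv <- n + i
    edges <- c(edges, b$a1[i], bv, bv, b$a2[i])
  }
  g <- igraph::make_graph(edges, n = n + nb, directed = FALSE)
  atom_color <- as.integer(factor(paste(mol$atoms$element,
                                        mol$atoms$formal_charge,
                                        mol$atoms$radical)))
  bond_class <- ifelse(b$aromatic, 9L, b$order)
  colors <- c(atom_color, max(atom_color) + bond_class)
  gens <- igraph::automorphism_group(g, colors = colors)
  orbit <- seq_len(n + nb)
  repeat {
    changed <- FALSE
    for (p in gens) {
      pm <- as.integer(p)
      m <- pmin(orbit, orbit[pm])
      if (!identical(m, orbit)) {
        orbit <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  orbit[seq_len(n)] - 1L
}

#' Read molecules from a file or object into a molecule table
#'
#' Accepts a character vector of SMILES, a data frame with a `smiles` column
#' (and optional `id`), a `.smi` file (one SMILES per line, optional
#' whitespace-separated id), or a `.csv` file with columns `smiles` and
#' optionally `id`.
#'
#' @param x Input (see Details).
#' @param id Optional ids when `x` is a character vector.
#' @return A tibble with columns `id`, `smiles` (canonical), `atom_count`,
#'   and a list-column `mol` of parsed [parse_mol()] objects.
#' @export
read_molecules <- function(x, id = NULL) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (grepl("\\.csv$", x, ignore.case = TRUE)) {
      df <- utils::read.csv(x, stringsAsFactors = FALSE)
      if (is.null(df$id)) df$id <- paste0("mol", seq_len(nrow(df)))
      return(molecule_table(df$smiles, df$id))
    }
    lines <- readLines(x, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    smi <- vapply(parts, `[`, character(1), 1)
    ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                  character(1))
    if (anyNA(ids)) ids <- ifelse(is.na(ids), paste0("mol", seq_along(smi)), ids)
    return(molecule_table(smi, ids))
  }
  if (is.data.frame(x)) {
    if (is.null(x$smiles)) abort("Data frame input needs a 'smiles' column")
    ids <- if (!is.null(x$id)) as.character(x$id) else paste0("mol", seq_len(nrow(x)))
    return(molecule_table(x$smiles, ids))
  }
  molecule_table(x, id %||% paste0("mol", seq_along(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

molecule_table <- function(smiles, id) {
  mols <- lapply(smiles, parse_mol)
  tibble(
    id = as.character(id),
    smiles = vapply(mols, function(m) m$smiles, character(1)),
    atom_count = vapply(mols, function(m) m$natoms, integer(1)),
    mol = mols
  )
}
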