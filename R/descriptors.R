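#' Construct a charge provider
#'
#' A charge provider returns one partial charge per atom in canonical atom
#' order, deterministically for a fixed seed. Providers mirroring the CM5
#' protocol (20 random conformers, force-field optimization, charges of the
#' lowest-energy conformer) plug in here; conformer-independent providers
#' such as the package surrogate may shortcut.
#'
#' @param name Provider name (recorded in feature schemas).
#' @param charges_fn `function(mol, seed)` returning a numeric vector of
#'   length `mol$natoms`.
#' @return A `chpka_charge_provider`.
#' @export
charge_provider <- function(name, charges_fn) {
  stopifnot(is.function(charges_fn))
  structure(list(name = name, charges_fn = charges_fn),
            class = "chpka_charge_provider")
}

#' Compute per-atom partial charges
#'
#' @param mol A `chpka_mol` or SMILES string.
#' @param provider A [charge_provider()].
#' @param seed Seed forwarded to the provider.
#' @return Numeric charges in canonical atom order; their sum must match the
#'   molecule's net formal charge within 1e-3.
#' @export
compute_charges <- function(mol, provider, seed = 1L) {
  if (is.character(mol)) mol <- parse_mol(mol)
  q <- tryCatch(provider$charges_fn(mol, seed), error = function(e) {
    abort(paste0("Charge provider '", provider$name, "' failed on '",
                 mol$smiles, "': ", conditionMessage(e)),
          class = "chpka_charge_error")
  })
  if (length(q) != mol$natoms) {
    abort(paste0("Charge provider returned ", length(q), " charges for ",
                 mol$natoms, " atoms ('", mol$smiles, "')"),
          class = "chpka_charge_error")
  }
  net <- sum(mol$atoms$formal_charge)
  if (abs(sum(q) - net) > 1e-3) {
    abort(paste0("Charges of '", mol$smiles, "' sum to ", signif(sum(q), 6),
                 ", expected net charge ", net),
          class = "chpka_charge_error")
  }
  q
}

#' Sorted-charge shell descriptor for one atom
#'
#' Shell `d` collects the charges of every atom (hydrogens included) at
#' topological bond-graph distance exactly `d` from the target, sorted in
#' descending order and right-padded with the pad value 0 to `slot_widths[d+1]`
#' slots. The descriptor vector concatenates shells d = 0..radius followed by
#' the true occupancy count of each shell, so a learner can distinguish
#' padding from genuine near-zero charges.
#'
#' @param mol A `chpka_mol` or SMILES string.
#' @param atom_index 0-based target atom index.
#' @param charges Per-atom charges (canonical order).
#' @param radius Maximum shell distance (default 6).
#' @param slot_widths Integer vector of length `radius + 1`; when NULL, each
#'   shell is exactly as wide as its occupancy (no padding).
#' @return List with `vector` (named numeric), `shells`, `occupancy`,
#'   `radius`, `slot_widths`.
#' @export
atom_descriptor <- function(mol, atom_index, charges, radius = 6L,
                            slot_widths = NULL) {
  if (is.character(mol)) mol <- parse_mol(mol)
  if (atom_index < 0 || atom_index >= mol$natoms) {
    abort(paste0("atom_index ", atom_index, " out of range"),
          class = "chpka_index_error")
  }
  stopifnot(length(charges) == mol$natoms, radius >= 0)
  dist <- as.integer(igraph::distances(mol$graph, v = atom_index + 1L))
  shells <- lapply(0:radius, function(d) {
    sort(charges[which(dist == d)], decreasing = TRUE)
  })
  occupancy <- lengths(shells)
  if (is.null(slot_widths)) slot_widths <- occupancy
  if (length(slot_widths) != radius + 1L) {
    abort("slot_widths must have radius + 1 entries", class = "chpka_schema_error")
  }
  if (any(occupancy > slot_widths)) {
    d_bad <- which(occupancy > slot_widths)[1] - 1L
    abort(paste0("Shell ", d_bad, " of atom ", atom_index, " in '", mol$smiles,
                 "' holds ", occupancy[d_bad + 1L], " atoms but slot_widths allows ",
                 slot_widths[d_bad + 1L],
                 "; recompute slot widths over the full dataset"),
          class = "chpka_overflow_error")
  }
  padded <- lapply(0:radius, function(d) {
    s <- shells[[d + 1L]]
    c(s, rep(0, slot_widths[d + 1L] - length(s)))
  })
  vec <- c(unlist(padded), as.numeric(occupancy))
  names(vec) <- c(
    unlist(lapply(0:radius, function(d) {
      if (slot_widths[d + 1L] == 0L) return(character())
      sprintf("d%d_s%02d", d, seq_len(slot_widths[d + 1L]))
    })),
    sprintf("occ_d%d", 0:radius)
  )
  list(vector = vec, shells = shells, occupancy = occupancy, radius = radius,
       slot_widths = slot_widths)
}

#' Maximum shell occupancies over a molecule set
#'
#' First pass used to freeze the slot widths of a dataset: for each distance
#' d = 0..radius, the widest shell any atom of any molecule exhibits.
#'
#' @param molecules Molecule table.
#' @param radius Shell radius.
#' @return Integer vector of length `radius + 1`.
#' @export
max_shell_occupancy <- function(molecules, radius = 6L) {
  occ <- rep(0L, radius + 1L)
  for (m in molecules$mol) {
    dist <- igraph::distances(m$graph)
    for (i in seq_len(m$natoms)) {
      tb <- tabulate(dist[i, ][dist[i, ] <= radius] + 1L, nbins = radius + 1L)
      occ <- pmax(occ, tb)
    }
  }
  occ
}

#' Build the site-by-feature matrix
#'
#' One row per C-H site, the descriptor of the site carbon in the neutral
#' parent. Slot widths are frozen from a first pass over the dataset (or
#' taken from `slot_widths`, e.g. a stored schema) and recorded, together
#' with pad value, provider, radius and seed, in the returned schema.
#'
#' @param sites Site table ([ch_sites()]).
#' @param molecules Molecule table covering every `parent_id`.
#' @param provider A [charge_provider()].
#' @param radius Shell radius (default 6).
#' @param seed Charge seed.
#' @param slot_widths Optional frozen widths from an existing schema.
#' @return List with `features` (tibble: `parent_id`, `atom_index`, then
#'   feature columns; ordered by parent then atom), `schema`, and `failures`
#'   (tibble of sites whose molecule failed, never silently dropped).
#' @export
build_feature_matrix <- function(sites, molecules, provider, radius = 6L,
                                 seed = 1L, slot_widths = NULL) {
  mol_of <- setNames(molecules$mol, molecules$id)
  if (is.null(slot_widths)) {
    slot_widths <- pmax(max_shell_occupancy(molecules, radius), 1L)
  }
  sites <- arrange(sites, .data$parent_id, .data$atom_index)
  charge_cache <- new.env(parent = emptyenv())
  rows <- list()
  failures <- list()
  for (k in seq_len(nrow(sites))) {
    pid <- sites$parent_id[k]
    ai <- sites$atom_index[k]
    res <- tryCatch({
      mol <- mol_of[[pid]]
      if (is.null(mol)) abort(paste0("Unknown parent_id '", pid, "'"))
      if (is.null(charge_cache[[pid]])) {
        charge_cache[[pid]] <- compute_charges(mol, provider, seed)
      }
      d <- atom_descriptor(mol, ai, charge_cache[[pid]], radius, slot_widths)
      as_tibble(c(list(parent_id = pid, atom_index = ai), as.list(d$vector)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble(parent_id = pid, atom_index = ai, reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  features <- bind_rows(rows)
  schema <- list(
    radius = radius, slot_widths = as.integer(slot_widths), pad_value = 0,
    provider = provider$name, seed = seed,
    columns = setdiff(names(features), c("parent_id", "atom_index")),
    hydrogens_in_shells = TRUE, sort = "descending"
  )
  fail_tb <- if (length(failures)) bind_rows(failures) else {
    tibble(parent_id = character(), atom_index = integer(), reason = character())
  }
  list(features = features, schema = schema, failures = fail_tb)
}

#' Write a feature matrix and its schema sidecar
#'
#' @param fm Result of [build_feature_matrix()].
#' @param csv_path,schema_path Output paths.
#' @export
write_feature_matrix <- function(fm, csv_path, schema_path) {
  utils::write.csv(as.data.frame(fm$features), csv_path, row.names = FALSE)
  jsonlite::write_json(fm$schema, schema_path, auto_unbox = TRUE, digits = NA)
  invisible(fm)
}
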