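#' @importFrom stats setNames
NULL

KCAL_PER_HARTREE <- 627.509474

#' Convert Hartree to kcal/mol (and back)
#'
#' @param x Energies.
#' @return Converted energies.
#' @export
hartree_to_kcal <- function(x) x * KCAL_PER_HARTREE

#' @rdname hartree_to_kcal
#' @export
kcal_to_hartree <- function(x) x / KCAL_PER_HARTREE

#' Construct an energy backend
#'
#' A backend is the contract through which all energies enter the package:
#' a deterministic function from a species and its geometry to a total (free)
#' energy in kcal/mol in implicit solvent. Real engines (tight-binding,
#' DFT) plug in behind this interface; the test suite and the synthetic world
#' use the deterministic surrogate.
#'
#' @param name Backend name.
#' @param energy_fn `function(species_smiles, xyz, elements)` returning a
#'   single finite energy in kcal/mol.
#' @param solvent_model Tag describing the implicit solvent (default DMSO,
#'   dielectric constant 47.2).
#' @param temperature_K Temperature for thermal energies (default 298.15).
#' @param frequencies_fn Optional `function(species_smiles, xyz, elements)`
#'   returning vibrational frequencies; negative values mark an imaginary
#'   mode and flag the record as unreliable downstream.
#' @return A `chpka_backend`.
#' @export
energy_backend <- function(name, energy_fn,
                           solvent_model = "implicit-DMSO(eps=47.2)",
                           temperature_K = 298.15,
                           frequencies_fn = NULL) {
  stopifnot(is.function(energy_fn))
  structure(
    list(name = name, energy_fn = energy_fn, solvent_model = solvent_model,
         temperature_K = temperature_K, frequencies_fn = frequencies_fn),
    class = "chpka_backend"
  )
}

#' @export
print.chpka_backend <- function(x, ...) {
  cat("<chpka_backend> ", x$name, " [", x$solvent_model, ", ",
      x$temperature_K, " K]\n", sep = "")
  invisible(x)
}

backend_energy <- function(backend, species_smiles, xyz, elements) {
  e <- backend$energy_fn(species_smiles, xyz, elements)
  if (!is.numeric(e) || length(e) != 1L || !is.finite(e)) {
    abort(paste0("Backend '", backend$name, "' returned a non-finite energy for '",
                 species_smiles, "'"), class = "chpka_backend_error")
  }
  as.numeric(e)
}

#' A backend that looks species energies up in a fixed table
#'
#' Handy for tests and worked examples: every conformer of a species receives
#' the tabulated energy.
#'
#' @param energies Named numeric vector, names are canonical SMILES, values
#'   kcal/mol.
#' @param name Backend name.
#' @return A `chpka_backend`.
#' @export
table_energy_backend <- function(energies, name = "table") {
  energy_backend(name, function(species, xyz, elements) {
    if (!species %in% names(energies)) {
      abort(paste0("No tabulated energy for '", species, "'"),
            class = "chpka_backend_error")
    }
    unname(energies[[species]])
  })
}

.backend_registry <- new.env(parent = emptyenv())

#' Register or fetch energy backends by name
#'
#' @param name Backend name.
#' @param backend A `chpka_backend`.
#' @return `get_energy_backend` returns the backend; registering returns it
#'   invisibly.
#' @export
register_energy_backend <- function(name, backend) {
  stopifnot(inherits(backend, "chpka_backend"))
  .backend_registry[[name]] <- backend
  invisible(backend)
}

#' @rdname register_energy_backend
#' @export
get_energy_backend <- function(name) {
  b <- .backend_registry[[name]]
  if (is.null(b)) {
    abort(paste0("No registered energy backend named '", name, "'. Registered: ",
                 paste(ls(.backend_registry), collapse = ", ")))
  }
  b
}

#' Parse a total energy from xTB-style output text
#'
#' Part of the adapter contract for external tight-binding engines: the
#' adapter writes an XYZ input ([write_xyz()]) and parses the engine's text
#' output; this function extracts the `TOTAL ENERGY` line (Hartree) and
#' converts to kcal/mol. No engine is bundled or required.
#'
#' @param text Character vector of output lines.
#' @return Energy in kcal/mol.
#' @export
parse_xtb_energy <- function(text) {
  ln <- grep("TOTAL ENERGY", text, value = TRUE)
  if (!length(ln)) abort("No 'TOTAL ENERGY' line found", class = "chpka_backend_error")
  eh <- as.numeric(regmatches(ln[1], regexpr("-?[0-9]+\\.[0-9]+", ln[1])))
  hartree_to_kcal(eh)
}

#' Heterolytic deprotonation energy
#'
#' The free-energy change of removing a proton from a solvated neutral to
#' give the solvated carbanion: the anion energy minus the neutral energy.
#'
#' @param e_anion,e_neutral Energies in kcal/mol.
#' @return `e_anion - e_neutral` in kcal/mol.
#' @export
compute_delta_g <- function(e_anion, e_neutral) {
  if (!all(is.finite(e_anion)) || !all(is.finite(e_neutral))) {
    abort("Energies must be finite", class = "chpka_numeric_error")
  }
  e_anion - e_neutral
}

#' Per-molecule minimum deprotonation energy
#'
#' @param records Tibble with columns `atom_index`, `delta_g`, and optionally
#'   `parent_id` (one group per parent).
#' @return Tibble with `parent_id` (if present), `delta_g_min`, and
#'   `argmin_atom_index`; ties resolve to the smallest atom index.
#' @export
min_delta_g <- function(records) {
  if (!nrow(records)) abort("No records", class = "chpka_empty_error")
  pick <- function(df) {
    i <- order(df$delta_g, df$atom_index)[1]
    tibble(delta_g_min = df$delta_g[i], argmin_atom_index = df$atom_index[i])
  }
  if ("parent_id" %in% names(records)) {
    records %>%
      group_by(.data$parent_id) %>%
      dplyr::group_modify(~ pick(.x)) %>%
      ungroup()
  } else {
    pick(records)
  }
}

species_pipeline_energy <- function(species, backend, seed, energy_window_kcal,
                                    rmsd_threshold_A, max_conformers) {
  ens <- generate_ensemble(species, seed = seed, max_conformers = max_conformers)
  ens <- assign_energies(ens, backend)
  ens <- prune_by_energy(ens, energy_window_kcal)
  ens <- cluster_butina(ens, rmsd_threshold_A)
  best <- lowest_energy_conformer(ens)
  imag <- FALSE
  if (!is.null(backend$frequencies_fn)) {
    fr <- backend$frequencies_fn(species, best$xyz, ens$elements)
    imag <- any(fr < 0)
  }
  list(energy = best$energy, imaginary = imag)
}

#' Run the conformer/energy pipeline for every C-H site
#'
#' For the neutral parent and each carbanion: generate an ensemble, assign
#' backend energies, prune to the energy window, keep Butina centroids, take
#' the lowest-energy conformer, and form the deprotonation energy. A backend
#' failure on one species marks that record `failed:<reason>` and the run
#' continues; an imaginary frequency (when the backend reports vibrational
#' data) marks the record `imaginary_freq` but keeps its value.
#'
#' @param molecules Molecule table from [read_molecules()].
#' @param sites Site table from [ch_sites()].
#' @param backend A `chpka_backend`.
#' @param seed Conformer seed.
#' @param energy_window_kcal,rmsd_threshold_A,max_conformers Ensemble settings.
#' @return Tibble: `parent_id`, `atom_index`, `anion_smiles`, `e_neutral`,
#'   `e_anion`, `delta_g`, `status`.
#' @export
run_site_energies <- function(molecules, sites, backend, seed = 1L,
                              energy_window_kcal = 3.0, rmsd_threshold_A = 0.5,
                              max_conformers = 20L) {
  cache <- new.env(parent = emptyenv())
  species_energy <- function(species) {
    key <- species
    if (is.null(cache[[key]])) {
      cache[[key]] <- tryCatch(
        species_pipeline_energy(species, backend, seed, energy_window_kcal,
                                rmsd_threshold_A, max_conformers),
        error = function(e) list(error = conditionMessage(e))
      )
    }
    cache[[key]]
  }
  neutral_of <- setNames(molecules$smiles, molecules$id)
  rows <- purrr::pmap(
    list(sites$parent_id, sites$atom_index, sites$anion_smiles),
    function(pid, ai, anion) {
      en <- species_energy(neutral_of[[pid]])
      ea <- species_energy(anion)
      if (!is.null(en$error) || !is.null(ea$error)) {
        return(tibble(parent_id = pid, atom_index = ai, anion_smiles = anion,
                      e_neutral = NA_real_, e_anion = NA_real_,
                      delta_g = NA_real_,
                      status = paste0("failed:", en$error %||% ea$error)))
      }
      status <- if (isTRUE(en$imaginary) || isTRUE(ea$imaginary)) {
        "imaginary_freq"
      } else "ok"
      tibble(parent_id = pid, atom_index = ai, anion_smiles = anion,
             e_neutral = en$energy, e_anion = ea$energy,
             delta_g = compute_delta_g(ea$energy, en$energy), status = status)
    })
  bind_rows(rows)
}
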