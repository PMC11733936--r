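#' Select backbone atoms to restrain, sparing the binding site
#'
#' High-temperature unbinding runs restrain the protein backbone to prevent
#' unfolding before the ligand leaves, but residues lining the binding site
#' are left free so the exit pathway is not blocked. A residue is a
#' binding-site residue when any of its heavy atoms lies within `cutoff`
#' (boundary inclusive) of any ligand heavy atom in the input pose; the
#' whole residue is then freed. The site is defined once, from the initial
#' pose, not per frame.
#'
#' @param structure a [structure_model()] with a nonempty ligand selection.
#' @param cutoff binding-site distance cutoff in Angstrom, default 6.
#' @return integer vector of atom indices (into `structure$atoms`) to
#'   restrain: backbone atoms of all non-site residues.
#' @export
select_restrained_atoms <- function(structure, cutoff = 6) {
  stopifnot(inherits(structure, "structure_model"))
  if (length(structure$ligand_heavy) == 0) {
    stop_invalid("ligand selection is empty")
  }
  if (!is.numeric(cutoff) || cutoff < 0) {
    stop_invalid("cutoff must be nonnegative")
  }
  atoms <- structure$atoms
  lig_xyz <- atom_coords(structure, structure$ligand_heavy)
  heavy_prot <- structure$protein[atoms$element[structure$protein] != "H"]
  if (length(heavy_prot) == 0) return(integer(0))
  prot_xyz <- atom_coords(structure, heavy_prot)
  # min distance from each protein heavy atom to any ligand heavy atom
  d2 <- outer(rowSums(prot_xyz^2), rowSums(lig_xyz^2), "+") -
    2 * prot_xyz %*% t(lig_xyz)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  site_key <- unique(paste(atoms$chain[heavy_prot],
                           atoms$resno[heavy_prot])[mind <= cutoff])
  bb <- structure$backbone
  bb[!(paste(atoms$chain[bb], atoms$resno[bb]) %in% site_key)]
}

#' Restraint specification
#'
#' Harmonic positional restraints on the selected atoms. `sigma` is read as
#' the standard deviation of the restrained coordinate at the reference
#' temperature, giving a Boltzmann-consistent force constant
#' `k = k_B T_ref / sigma^2` per coordinate (kcal/mol/A^2 with
#' `k_B T_ref = R T_ref` in molar units). The protocol default is
#' `sigma = 3.0` A with a 6 A binding-site exclusion.
#'
#' @param restrained_atoms integer atom indices, normally from
#'   [select_restrained_atoms()].
#' @param sigma positional standard deviation in Angstrom, default 3.
#' @param binding_site_cutoff site-exclusion cutoff used to build the
#'   selection, recorded for provenance; default 6.
#' @param T_ref reference temperature (K) for the force constant,
#'   default 300.
#' @return object of class `restraint_spec` with the derived
#'   `force_constant` (kcal mol^-1 A^-2).
#' @export
restraint_spec <- function(restrained_atoms, sigma = 3,
                           binding_site_cutoff = 6, T_ref = 300) {
  if (sigma <= 0) stop_invalid("sigma must be positive")
  structure(
    list(restrained_atoms = as.integer(restrained_atoms),
         sigma = sigma,
         binding_site_cutoff = binding_site_cutoff,
         force_constant = R_KCAL_PER_MOL_K * T_ref / sigma^2),
    class = "restraint_spec"
  )
}

sim_spec_defaults <- list(
  time_step_fs = 2,
  sigma_A = 3,
  site_cutoff_A = 6,
  n_replicas = 32L,
  base_seed = 1L,
  frame_interval_ps = 10,
  friction_per_ps = 1,
  T_ref = 300
)

#' Build a validated high-temperature unbinding simulation specification
#'
#' Fills a config (key-value list, e.g. parsed from YAML) with the standard
#' protocol defaults — NVT ensemble, 2 fs time step, Langevin thermostat,
#' backbone restraints (sigma 3 A) sparing residues within 6 A of the
#' ligand, up to 32 replicas — and validates every field, reporting all
#' offending keys at once. Typical production settings are 600-1000 K for
#' 1-5 ns per replica.
#'
#' @param config named list; must supply `temperature_K` and
#'   `total_time_ns`. Optional keys: `time_step_fs`, `sigma_A`,
#'   `site_cutoff_A`, `n_replicas`, `base_seed`, `frame_interval_ps`,
#'   `friction_per_ps`, `T_ref`.
#' @param structure a [structure_model()]; used to derive the restrained
#'   atom selection.
#' @return object of class `simulation_spec`.
#' @export
build_simulation_spec <- function(config, structure) {
  stopifnot(inherits(structure, "structure_model"))
  if (!is.list(config)) stop_invalid("config must be a named list")
  known <- c("temperature_K", "total_time_ns", names(sim_spec_defaults))
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop_invalid("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(sim_spec_defaults, config)

  bad <- character(0)
  need_pos <- c("temperature_K", "total_time_ns", "time_step_fs", "sigma_A",
                "frame_interval_ps", "friction_per_ps", "T_ref")
  for (key in need_pos) {
    v <- cfg[[key]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        v <= 0) {
      bad <- c(bad, key)
    }
  }
  if (!("site_cutoff_A" %in% bad) &&
      (!is.numeric(cfg$site_cutoff_A) || cfg$site_cutoff_A < 0)) {
    bad <- c(bad, "site_cutoff_A")
  }
  if (!is.numeric(cfg$n_replicas) || cfg$n_replicas < 1) {
    bad <- c(bad, "n_replicas")
  }
  if (length(bad)) {
    stop_invalid("invalid simulation config value(s) for: ",
                 paste(unique(bad), collapse = ", "))
  }
  n_frames <- cfg$total_time_ns * 1000 / cfg$frame_interval_ps
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop_invalid("total_time_ns must be a whole number of frame intervals")
  }

  restraints <- restraint_spec(
    select_restrained_atoms(structure, cfg$site_cutoff_A),
    sigma = cfg$sigma_A, binding_site_cutoff = cfg$site_cutoff_A,
    T_ref = cfg$T_ref
  )
  structure(
    list(temperature = cfg$temperature_K,
         total_time_ns = cfg$total_time_ns,
         time_step_fs = cfg$time_step_fs,
         thermostat = "langevin",
         friction_per_ps = cfg$friction_per_ps,
         ensemble = "NVT",
         restraints = restraints,
         n_replicas = as.integer(cfg$n_replicas),
         base_seed = as.integer(cfg$base_seed),
         frame_interval_ps = cfg$frame_interval_ps,
         n_frames = as.integer(round(n_frames)),
         T_ref = cfg$T_ref),
    class = "simulation_spec"
  )
}

#' Per-replica run plan
#'
#' Expands a [build_simulation_spec()] into one descriptor per replica.
#' Replica `i` gets seed `base_seed + i - 1` and otherwise identical
#' physics; downstream results must not depend on the order in which
#' descriptors are executed, so replicas can run in parallel.
#'
#' @param spec a `simulation_spec`.
#' @return list of length `n_replicas`; each element has `replica_id`,
#'   `seed`, and the shared physics fields.
#' @export
plan_replicas <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  lapply(seq_len(spec$n_replicas), function(i) {
    list(replica_id = i,
         seed = spec$base_seed + i - 1L,
         temperature = spec$temperature,
         total_time_ns = spec$total_time_ns,
         time_step_fs = spec$time_step_fs,
         frame_interval_ps = spec$frame_interval_ps,
         restraints = spec$restraints)
  })
}
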