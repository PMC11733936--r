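#' Read a protein-ligand structure from PDB
#'
#' Parses a PDB file and builds a [structure_model()], identifying the
#' ligand by HETATM residue name. Coordinates are in Angstrom; residue
#' numbering is taken 1-based as written in the file.
#'
#' @param path PDB file path.
#' @param ligand_resname HETATM residue name of the ligand.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, ligand_resname) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    stop_invalid("failed to parse PDB '", path, "': ",
                                 conditionMessage(e))
                  })
  a <- pdb$atom
  element <- a$elesy
  no_elem <- is.na(element) | element == ""
  element[no_elem] <- substr(gsub("[0-9]", "", a$elety[no_elem]), 1, 1)
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, element = element,
    resname = a$resid, resno = a$resno,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    type = a$type, x = a$x, y = a$y, z = a$z
  )
  structure_model(atoms, ligand_resname)
}

#' Write a structure model to PDB
#'
#' @param structure a [structure_model()].
#' @param path output PDB file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "structure_model"))
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = a$type, resno = a$resno, resid = a$resname,
                   eleno = a$serial, elety = a$name, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

# --- minimal CHARMM-format DCD writer -------------------------------------
# bio3d reads DCD but cannot write it; fixtures need a real binary
# trajectory to exercise the reader, so frames are written here in the
# CHARMM layout (Fortran unformatted records, single-precision x/y/z
# blocks, no unit cell) and round-tripped against bio3d::read.dcd in the
# tests.

write_record <- function(con, payload_writer, size) {
  writeBin(as.integer(size), con, size = 4)
  payload_writer(con)
  writeBin(as.integer(size), con, size = 4)
}

#' Write a trajectory to a DCD file
#'
#' @param traj a [trajectory()].
#' @param path output DCD path.
#' @return `path`, invisibly.
#' @export
write_trajectory_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  n_frames <- nrow(traj$xyz)
  n_atoms <- ncol(traj$xyz) / 3
  con <- file(path, "wb")
  on.exit(close(con))

  icntrl <- integer(20)
  icntrl[1] <- n_frames   # frames in file
  icntrl[2] <- 1L         # first step
  icntrl[3] <- 1L         # steps between frames
  icntrl[4] <- n_frames   # last step
  icntrl[20] <- 24L       # CHARMM version flag
  write_record(con, function(c2) {
    writeBin(charToRaw("CORD"), c2)
    writeBin(icntrl[1:9], c2, size = 4)
    writeBin(1, c2, size = 4)          # delta (float slot)
    writeBin(icntrl[11:20], c2, size = 4)
  }, 84)
  title <- formatC("generated trajectory", width = -80)
  write_record(con, function(c2) {
    writeBin(1L, c2, size = 4)
    writeBin(charToRaw(title), c2)
  }, 84)
  write_record(con, function(c2) writeBin(as.integer(n_atoms), c2, size = 4),
               4)
  for (f in seq_len(n_frames)) {
    coords <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    for (d in 1:3) {
      write_record(con, function(c2) writeBin(coords[, d], c2, size = 4),
                   4 * n_atoms)
    }
  }
  invisible(path)
}

#' Read a coordinate trajectory (DCD or multi-model PDB)
#'
#' Frame times are assigned from `frame_interval` (frame `i` at
#' `i * frame_interval`, the first frame one save interval into the run)
#' rather than trusting timestamps embedded in the file, which vary across
#' writers.
#'
#' @param path trajectory file; `.dcd` (binary) or `.pdb` (multi-MODEL).
#' @param topology a [structure_model()] with the matching atom count.
#' @param frame_interval time between frames in ps, default 10.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, topology, frame_interval = 10) {
  stopifnot(inherits(topology, "structure_model"))
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  xyz <- tryCatch(
    switch(ext,
           dcd = bio3d::read.dcd(path, verbose = FALSE),
           pdb = bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)$xyz,
           stop_invalid("unsupported trajectory format '.", ext,
                        "' (use .dcd or multi-model .pdb)")),
    error = function(e) {
      stop_invalid("failed to parse trajectory '", path, "': ",
                   conditionMessage(e))
    })
  xyz <- as.matrix(unclass(xyz))
  if (nrow(xyz) == 0) stop_invalid("trajectory '", path, "' has no frames")
  n_top <- nrow(topology$atoms)
  if (ncol(xyz) != 3 * n_top) {
    stop_invalid("atom count mismatch: trajectory has ", ncol(xyz) / 3,
                 " atoms, topology has ", n_top)
  }
  trajectory(xyz, seq_len(nrow(xyz)) * frame_interval, topology)
}

#' Read and validate a pipeline run configuration (YAML)
#'
#' @param path YAML config file. Required keys depend on `backend`
#'   (`"toy"` or `"trajectories"`); unknown keys are rejected.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- path
  validate_run_config(cfg)
}

toy_config_keys <- c("backend", "t_sim", "t_ref", "n_replicas", "base_seed",
                     "dt", "t_max", "friction", "ligands", "output_dir",
                     "config_path")
traj_config_keys <- c("backend", "structure", "ligand_resname",
                      "frame_interval_ps", "cutoff_A", "persistence_frames",
                      "temperature_K", "t_ref_K", "censoring_policy",
                      "accept_lower_bound", "ligands", "output_dir",
                      "config_path")

validate_run_config <- function(cfg) {
  if (is.null(cfg$backend) ||
      !cfg$backend %in% c("toy", "trajectories")) {
    stop_invalid("config must set backend: 'toy' or 'trajectories'")
  }
  known <- if (cfg$backend == "toy") toy_config_keys else traj_config_keys
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$ligands) || !length(cfg$ligands)) {
    stop_invalid("config must list at least one ligand")
  }
  ids <- vapply(cfg$ligands, function(l) as.character(l$id %||% NA),
                character(1))
  if (anyNA(ids) || anyDuplicated(ids)) {
    stop_invalid("every ligand needs a unique 'id'")
  }
  if (cfg$backend == "toy") {
    cfg$t_sim <- cfg$t_sim %||% 3
    cfg$t_ref <- cfg$t_ref %||% 1
    cfg$n_replicas <- cfg$n_replicas %||% 32L
    cfg$base_seed <- cfg$base_seed %||% 1L
    cfg$dt <- cfg$dt %||% 0.005
    cfg$friction <- cfg$friction %||% 1
    if (is.null(cfg$t_max) || cfg$t_max <= 0) {
      stop_invalid("toy config must set a positive t_max")
    }
    bh <- vapply(cfg$ligands,
                 function(l) as.numeric(l$barrier_height %||% NA),
                 numeric(1))
    if (anyNA(bh) || any(bh <= 0)) {
      stop_invalid("every toy ligand needs a positive 'barrier_height'")
    }
  } else {
    if (is.null(cfg$structure) || !file.exists(cfg$structure)) {
      stop_invalid("config 'structure' must point to an existing PDB file")
    }
    if (is.null(cfg$ligand_resname)) {
      stop_invalid("config must set 'ligand_resname'")
    }
    cfg$frame_interval_ps <- cfg$frame_interval_ps %||% 10
    cfg$cutoff_A <- cfg$cutoff_A %||% 5
    cfg$persistence_frames <- cfg$persistence_frames %||% 5L
    cfg$t_ref_K <- cfg$t_ref_K %||% 300
    cfg$censoring_policy <- cfg$censoring_policy %||% "tmax"
    cfg$accept_lower_bound <- isTRUE(cfg$accept_lower_bound)
    if (is.null(cfg$temperature_K) || cfg$temperature_K <= 0) {
      stop_invalid("config must set a positive 'temperature_K'")
    }
    for (l in cfg$ligands) {
      if (is.null(l$trajectories) || !length(l$trajectories)) {
        stop_invalid("ligand '", l$id, "' lists no trajectories")
      }
      missing_files <- l$trajectories[!file.exists(unlist(l$trajectories))]
      if (length(missing_files)) {
        stop_invalid("missing trajectory file(s) for ligand '", l$id, "': ",
                     paste(unlist(missing_files), collapse = ", "))
      }
    }
  }
  cfg$output_dir <- cfg$output_dir %||% "."
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
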