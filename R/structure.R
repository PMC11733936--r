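#' Protein-ligand structure model
#'
#' Lightweight container for one prepared complex: an atom table plus the
#' two selections the unbinding workflow needs (ligand atoms and protein
#' backbone atoms). Coordinates are in Angstrom.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `type` ("ATOM"/"HETATM"), `x`, `y`, `z`.
#' @param ligand_resname residue name identifying the ligand among HETATM
#'   records (e.g. `"LIG"`).
#' @return object of class `structure_model`: the atom table plus integer
#'   index vectors `ligand` (all ligand atoms), `ligand_heavy`,
#'   `protein` (all non-ligand atoms), `backbone` (N, CA, C, O of protein
#'   residues).
#' @export
structure_model <- function(atoms, ligand_resname) {
  req <- c("serial", "name", "element", "resname", "resno", "chain",
           "type", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stop_invalid("atom table is missing columns: ",
                 paste(missing_cols, collapse = ", "))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop_invalid("atom coordinates must be finite")

  ligand <- which(atoms$type == "HETATM" & atoms$resname == ligand_resname)
  if (length(ligand) == 0) {
    hets <- unique(atoms$resname[atoms$type == "HETATM"])
    stop_invalid("no HETATM residue named '", ligand_resname, "' found",
                 if (length(hets)) paste0("; available HET residues: ",
                                          paste(hets, collapse = ", "))
                 else "; file contains no HETATM records")
  }
  protein <- which(!(seq_len(nrow(atoms)) %in% ligand))
  if (length(intersect(ligand, protein))) {
    stop_invalid("ligand and protein selections overlap")
  }

  prot <- atoms[protein, ]
  key <- paste(prot$chain, prot$resno, prot$resname)
  per_res <- unique(data.frame(chain = prot$chain, resno = prot$resno,
                               resname = prot$resname))
  if (anyDuplicated(per_res[, c("chain", "resno")])) {
    stop_invalid("residue numbering is not unique per chain")
  }

  backbone <- protein[atoms$name[protein] %in% c("N", "CA", "C", "O")]
  heavy <- atoms$element != "H"
  structure(
    list(atoms = atoms,
         ligand = ligand,
         ligand_heavy = ligand[heavy[ligand]],
         protein = protein,
         backbone = backbone),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "structure_model: %d atoms (%d protein, %d ligand, %d backbone), %d residues\n",
    nrow(x$atoms), length(x$protein), length(x$ligand), length(x$backbone),
    nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

atom_coords <- function(structure, idx = seq_len(nrow(structure$atoms))) {
  as.matrix(structure$atoms[idx, c("x", "y", "z")])
}

#' Synthetic protein-ligand complex
#'
#' Builds a small, fully synthetic complex used as topology for scripted
#' trajectories and format round-trip tests: a helical chain of backbone-only
#' residues (N, CA, C, O per residue) with a rigid multi-atom ligand placed
#' near a chosen residue. Entirely artificial geometry; it exercises
#' selections, superposition and IO, not chemistry.
#'
#' @param n_residues number of protein residues, default 20.
#' @param ligand_resname residue name for the ligand, default "LIG".
#' @param n_ligand_atoms number of ligand heavy atoms (>= 3), default 6.
#' @param site_residue protein residue the ligand sits next to; default the
#'   middle residue.
#' @return a [structure_model()].
#' @export
synthetic_complex <- function(n_residues = 20, ligand_resname = "LIG",
                              n_ligand_atoms = 6,
                              site_residue = ceiling(n_residues / 2)) {
  if (n_ligand_atoms < 3) stop_invalid("need >= 3 ligand atoms")
  # Idealized helix-like backbone: residues along z, rotating about the axis.
  bb_names <- c("N", "CA", "C", "O")
  bb_offsets <- rbind(c(0, 0, 0), c(0.8, 0.6, 0.4), c(1.6, 0.2, 0.9),
                      c(2.2, -0.6, 0.7))
  rows <- vector("list", n_residues)
  for (r in seq_len(n_residues)) {
    ang <- 100 * pi / 180 * (r - 1)
    base <- c(4 * cos(ang), 4 * sin(ang), 1.5 * (r - 1))
    rows[[r]] <- data.frame(
      name = bb_names, element = c("N", "C", "C", "O"),
      resname = "ALA", resno = r, chain = "A", type = "ATOM",
      x = base[1] + bb_offsets[, 1],
      y = base[2] + bb_offsets[, 2],
      z = base[3] + bb_offsets[, 3]
    )
  }
  prot <- do.call(rbind, rows)
  site <- prot[prot$resno == site_residue & prot$name == "CA",
               c("x", "y", "z")]
  # Rigid ring-like ligand ~3.5 A from the site CA.
  th <- 2 * pi * (seq_len(n_ligand_atoms) - 1) / n_ligand_atoms
  lig <- data.frame(
    name = paste0("C", seq_len(n_ligand_atoms)), element = "C",
    resname = ligand_resname, resno = 900L, chain = "L", type = "HETATM",
    x = site$x + 3.5 + 1.2 * cos(th),
    y = site$y + 1.2 * sin(th),
    z = site$z + 0.5
  )
  atoms <- rbind(prot, lig)
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms[, c("serial", "name", "element", "resname", "resno",
                            "chain", "type", "x", "y", "z")],
                  ligand_resname)
}
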