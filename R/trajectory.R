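#' Coordinate trajectory
#'
#' Frames are stored row-wise in the flat `x1,y1,z1,x2,...` layout used by
#' the DCD reader, with one uniformly spaced time stamp (ps) per frame.
#'
#' @param xyz numeric matrix, `n_frames` x `3 * n_atoms`.
#' @param times frame times in ps, strictly increasing and uniform.
#' @param topology a [structure_model()] with matching atom count.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(xyz, times, topology) {
  stopifnot(inherits(topology, "structure_model"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0) stop_invalid("trajectory has no frames")
  if (ncol(xyz) != 3 * nrow(topology$atoms)) {
    stop_invalid("trajectory has ", ncol(xyz) / 3, " atoms but topology has ",
                 nrow(topology$atoms))
  }
  if (length(times) != nrow(xyz)) {
    stop_invalid("times length must equal the number of frames")
  }
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || any(abs(dt - dt[1]) > 1e-9 * dt[1]))) {
    stop_invalid("frame times must be strictly increasing and uniform")
  }
  structure(list(xyz = xyz, times = as.numeric(times), topology = topology),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, %.6g-%.6g ps\n",
              nrow(x$xyz), ncol(x$xyz) / 3, x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

frame_coords <- function(traj, frame, idx = NULL) {
  m <- matrix(traj$xyz[frame, ], ncol = 3, byrow = TRUE)
  if (is.null(idx)) m else m[idx, , drop = FALSE]
}

xyz_indices <- function(atom_idx) {
  as.vector(t(outer(3 * (atom_idx - 1), 1:3, "+")))
}

rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Scripted-trajectory specification
#'
#' Ground-truth script for a synthetic unbinding trajectory: which frame the
#' ligand departs at (if any), which single frames show transient
#' recrossing excursions, a rigid-body motion applied to the whole complex
#' per frame, and per-atom Gaussian noise. Because the truth is scripted,
#' the analysis chain can be tested for exact recovery.
#'
#' @param n_frames number of frames (frame 1 is the reference).
#' @param frame_interval time between frames in ps, default 10.
#' @param departure_frame frame index at which the ligand leaves and stays
#'   out, or `NULL` for a trajectory that remains bound.
#' @param recrossing_frames integer frame indices of single-frame unbound
#'   excursions; must precede `departure_frame`.
#' @param rotation_deg_per_frame rigid rotation of the whole complex about
#'   the z axis through the protein centroid, degrees per frame.
#' @param translation_per_frame length-3 rigid translation per frame (A).
#' @param noise_sigma per-coordinate Gaussian noise (A) added to frames
#'   after the first; 0 gives noise-free ground truth.
#' @param displacement ligand displacement when unbound (A), default 8
#'   (safely beyond the 5 A cutoff).
#' @param seed RNG seed for the noise.
#' @return object of class `scripted_trajectory_spec`.
#' @export
scripted_trajectory_spec <- function(n_frames, frame_interval = 10,
                                     departure_frame = NULL,
                                     recrossing_frames = integer(0),
                                     rotation_deg_per_frame = 0,
                                     translation_per_frame = c(0, 0, 0),
                                     noise_sigma = 0, displacement = 8,
                                     seed = 1L) {
  if (n_frames < 2) stop_invalid("need at least 2 frames")
  if (!is.null(departure_frame)) {
    if (departure_frame <= 1 || departure_frame > n_frames) {
      stop_invalid("departure_frame must lie in 2..n_frames")
    }
    if (length(recrossing_frames) &&
        any(recrossing_frames >= departure_frame)) {
      stop_invalid("recrossing frames must precede the departure frame")
    }
  }
  if (length(recrossing_frames) &&
      (any(recrossing_frames <= 1) || any(recrossing_frames > n_frames))) {
    stop_invalid("recrossing frames must lie in 2..n_frames")
  }
  if (length(translation_per_frame) != 3) {
    stop_invalid("translation_per_frame must have length 3")
  }
  structure(
    list(n_frames = as.integer(n_frames), frame_interval = frame_interval,
         departure_frame = departure_frame,
         recrossing_frames = as.integer(recrossing_frames),
         rotation_deg_per_frame = rotation_deg_per_frame,
         translation_per_frame = translation_per_frame,
         noise_sigma = noise_sigma, displacement = displacement,
         seed = as.integer(seed)),
    class = "scripted_trajectory_spec"
  )
}

#' Generate a scripted coordinate trajectory
#'
#' Builds the trajectory described by a [scripted_trajectory_spec()] on top
#' of a topology: the ligand is rigidly displaced by `displacement` A (along
#' +x in the reference frame) on recrossing frames and from the departure
#' frame onward, then the whole complex undergoes the scripted rigid
#' motion, then noise is added (frames after the first). After protein
#' superposition the ligand RMSD is exactly 0 on bound frames and exactly
#' `displacement` on unbound frames when `noise_sigma = 0`.
#'
#' @param spec a [scripted_trajectory_spec()].
#' @param topology a [structure_model()].
#' @return a [trajectory()] with times `frame_interval, 2*frame_interval,
#'   ...` ps (frame `f` at `f * frame_interval`).
#' @export
make_scripted_trajectory <- function(spec, topology) {
  stopifnot(inherits(spec, "scripted_trajectory_spec"),
            inherits(topology, "structure_model"))
  ref <- atom_coords(topology)
  n_atoms <- nrow(ref)
  center <- colMeans(ref[topology$protein, , drop = FALSE])
  lig <- topology$ligand
  set.seed(spec$seed)

  unbound <- rep(FALSE, spec$n_frames)
  unbound[spec$recrossing_frames] <- TRUE
  if (!is.null(spec$departure_frame)) {
    unbound[spec$departure_frame:spec$n_frames] <- TRUE
  }

  xyz <- matrix(0, spec$n_frames, 3 * n_atoms)
  for (f in seq_len(spec$n_frames)) {
    coords <- ref
    if (unbound[f]) {
      coords[lig, 1] <- coords[lig, 1] + spec$displacement
    }
    theta <- (f - 1) * spec$rotation_deg_per_frame * pi / 180
    coords <- sweep(coords, 2, center) %*% t(rot_z(theta))
    coords <- sweep(coords, 2, center + (f - 1) * spec$translation_per_frame,
                    "+")
    if (f > 1 && spec$noise_sigma > 0) {
      coords <- coords + matrix(rnorm(3 * n_atoms, sd = spec$noise_sigma),
                                n_atoms, 3)
    }
    xyz[f, ] <- as.vector(t(coords))
  }
  # Frames are numbered from 1 at t = frame_interval, matching MD engines
  # that write the first frame one save interval into the run.
  trajectory(xyz, seq_len(spec$n_frames) * spec$frame_interval, topology)
}
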