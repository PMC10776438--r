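#' Build a trajectory object
#'
#' A trajectory couples a static [topology()] with per-frame coordinates,
#' frame times and (optionally) periodic-box lengths. Coordinates are
#' Cartesian and unwrapped on construction; periodic-image handling is left
#' to the consuming analysis (minimum-image convention where relevant).
#'
#' Units: Angstrom for coordinates and box lengths, picoseconds for frame
#' times. Binding times are converted to nanoseconds only at the reporting
#' boundary.
#'
#' @param topology a [topology()].
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param box `NULL`, a length-3 vector (constant box) or an
#'   `n_frames x 3` matrix of box lengths (Angstrom).
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(topology, coords, times, box = NULL) {
  if (!inherits(topology, "topology")) stop_ib("topology must be a topology object")
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    stop_ib("coords must be an n_atoms x 3 x n_frames array")
  n_fr <- dim(coords)[3L]
  if (dim(coords)[1L] != nrow(topology$atoms))
    stop_ib("coords atom count (", dim(coords)[1L],
            ") does not match topology (", nrow(topology$atoms), ")")
  if (length(times) != n_fr) stop_ib("times length must equal frame count")
  if (n_fr > 1L && any(diff(times) <= 0))
    stop_ib("frame times must be strictly increasing")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = n_fr, ncol = 3L, byrow = TRUE)
    box <- as.matrix(box)
    if (nrow(box) != n_fr || ncol(box) != 3L)
      stop_ib("box must be a length-3 vector or an n_frames x 3 matrix")
    if (any(box <= 0)) stop_ib("box lengths must be positive")
  }
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times), box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", dim(x$coords)[1L], " atoms x ", n_frames(x),
      " frames, t = ", x$times[1L], "..", x$times[n_frames(x)], " ps",
      if (!is.null(x$box)) " (periodic)", "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Uniform frame spacing of a trajectory (ps)
#'
#' @param traj a [trajectory()].
#' @param tol relative tolerance on spacing uniformity.
#' @return The frame spacing dt in ps.
#' @export
frame_dt <- function(traj, tol = 1e-6) {
  dts <- diff(traj$times)
  if (!length(dts)) stop_ib("trajectory has a single frame; dt undefined")
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > tol * dt))
    stop_ib("frame times are not uniformly spaced; resample upstream")
  dt
}

# Native tabular trajectory format (plain-text CSV so fixtures diff):
# columns frame, time_ps, atom_id, x, y, z. One row per atom per frame;
# each frame additionally carries one box row with atom_id = 0 and the box
# lengths in (x, y, z). Frames without a box row are non-periodic.

#' Read a trajectory from the native CSV format
#'
#' @param path CSV path (columns `frame`, `time_ps`, `atom_id`, `x`, `y`,
#'   `z`; box rows have `atom_id = 0`).
#' @param topology the [topology()] the coordinates refer to; atom counts are
#'   validated for every frame.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, topology) {
  if (!file.exists(path)) stop_ib("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "time_ps", "atom_id", "x", "y", "z")
  if (!all(req %in% names(d)))
    stop_ib("trajectory CSV must have columns: ", paste(req, collapse = ", "))
  frames <- sort(unique(d$frame))
  n_at <- nrow(topology$atoms)
  n_fr <- length(frames)
  coords <- array(NA_real_, dim = c(n_at, 3L, n_fr))
  times <- numeric(n_fr)
  box_rows <- d[d$atom_id == 0L, , drop = FALSE]
  has_box <- nrow(box_rows) > 0L
  if (has_box && nrow(box_rows) != n_fr)
    stop_ib("box rows present for ", nrow(box_rows), " of ", n_fr, " frames")
  box <- if (has_box) matrix(NA_real_, n_fr, 3L) else NULL
  for (i in seq_len(n_fr)) {
    fr <- d[d$frame == frames[i] & d$atom_id != 0L, , drop = FALSE]
    if (nrow(fr) != n_at || !setequal(fr$atom_id, topology$atoms$atom_id))
      stop_ib("frame ", frames[i], " has ", nrow(fr),
              " atoms; expected ", n_at)
    ord <- order(fr$atom_id)
    coords[, , i] <- as.matrix(fr[ord, c("x", "y", "z")])
    times[i] <- fr$time_ps[1L]
    if (has_box) {
      b <- box_rows[box_rows$frame == frames[i], , drop = FALSE]
      if (nrow(b) != 1L) stop_ib("frame ", frames[i], " lacks a unique box row")
      box[i, ] <- as.numeric(b[1L, c("x", "y", "z")])
    }
  }
  if (n_fr > 1L && any(diff(times) <= 0))
    stop_ib("frame times are not strictly increasing")
  trajectory(topology, coords, times, box)
}

#' Write a trajectory in the native CSV format
#'
#' @param traj a [trajectory()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  n_at <- dim(traj$coords)[1L]
  n_fr <- n_frames(traj)
  blocks <- vector("list", n_fr)
  for (i in seq_len(n_fr)) {
    at <- data.frame(frame = i, time_ps = traj$times[i],
                     atom_id = seq_len(n_at),
                     x = traj$coords[, 1L, i],
                     y = traj$coords[, 2L, i],
                     z = traj$coords[, 3L, i])
    if (!is.null(traj$box)) {
      at <- rbind(data.frame(frame = i, time_ps = traj$times[i], atom_id = 0L,
                             x = traj$box[i, 1L], y = traj$box[i, 2L],
                             z = traj$box[i, 3L]), at)
    }
    blocks[[i]] <- at
  }
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}

# Coordinates of a set of atoms across all frames: 3 x n_frames slices
# per atom are the workhorse layout for the vectorised distance loops.
atom_xyz <- function(traj, atom_id) traj$coords[atom_id, , , drop = FALSE]
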