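# Programmatic fixtures shared across the suite.

# Fixed-width PDB ATOM record writer.
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element = "") {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain, resno, x, y, z, 1.0, 0.0, element)
}

# A 3-atom toy PDB (one GLY with N, CA and a hydrogen).
write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    pdb_atom_line(1, "N",  "GLY", "A", 1, 0.0, 0.0, 0.0, "N"),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.5, 0.0, 0.0, "C"),
    pdb_atom_line(3, "HA", "GLY", "A", 1, 1.5, 1.0, 0.0, "H"),
    "END"
  ), path)
  path
}

# Minimal topology: a set of named atoms in single-atom residues.
make_topology <- function(elements, res_names = NULL, names = NULL) {
  n <- length(elements)
  res_names <- res_names %||% rep("ALA", n)
  topology(
    atoms = data.frame(atom_id = seq_len(n),
                       name = names %||% paste0(elements, seq_len(n)),
                       element = elements,
                       is_heavy = toupper(elements) != "H",
                       residue_index = seq_len(n),
                       stringsAsFactors = FALSE),
    residues = data.frame(residue_index = seq_len(n),
                          residue_name = res_names,
                          chain = "A", stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trajectory in which one "ion" atom follows a prescribed distance from a
# fixed protein atom at the origin (both on the z axis).
make_distance_trajectory <- function(d, dt_ps = 200, box = NULL) {
  top <- make_topology(c("C", "O"), res_names = c("ARG", "ION"))
  n <- length(d)
  coords <- array(0, dim = c(2, 3, n))
  coords[2, 3, ] <- d
  trajectory(top, coords, times = (seq_len(n) - 1) * dt_ps, box = box)
}

# Distance series straight from numbers (for event-detection tests).
make_distance_series <- function(d, dt_ns = 0.2, residue = "ARG") {
  out <- data.frame(time_ns = (seq_along(d) - 1) * dt_ns, d_min = d,
                    nearest_residue = 1L, nearest_residue_name = residue,
                    stringsAsFactors = FALSE)
  class(out) <- c("distance_series", "data.frame")
  attr(out, "dt") <- dt_ns
  out
}

# Brute-force oracle for event detection: scan runs of below-cutoff frames.
brute_force_events <- function(d, cutoff, dt, min_frames = 2L) {
  below <- d < cutoff
  out <- NULL
  i <- 1L
  n <- length(below)
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_frames)
        out <- rbind(out, data.frame(i_start = i, i_end = j,
                                     t_b = (j - i + 1L) * dt))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Brute-force minimum-image distance by explicit search over periodic images
# (wide enough for points up to two cells outside the primary box).
brute_force_min_image_dist <- function(a, b, box) {
  imgs <- as.matrix(expand.grid(i = -2:2, j = -2:2, k = -2:2))
  min(apply(imgs, 1L, function(s) sqrt(sum((a - (b + s * box))^2))))
}

# Standard Markov-binding fixture used by several modules.
markov_fixture <- function(n_ions = 2, duration = 200, dt = 0.2, k_on = 1,
                           k_off = 1, seed = 42, two_sites = FALSE) {
  sites <- if (two_sites)
    data.frame(site_id = 1:2, x = c(15, 45), y = 30, z = 30,
               jitter_sigma = 0.5, k_on = k_on / 2, k_off = k_off)
  else
    data.frame(site_id = 1, x = 30, y = 30, z = 30, jitter_sigma = 0.5,
               k_on = k_on, k_off = k_off)
  spec <- binding_kinetics_spec(sites, box = c(60, 60, 60), n_ions = n_ions,
                                duration = duration, dt = dt, seed = seed)
  simulate_markov_binding(spec)
}

row_norms_test <- function(m) sqrt(rowSums(m * m))
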