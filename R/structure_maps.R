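#' Kabsch superposition
#'
#' Least-squares optimal rigid-body superposition of a mobile structure onto
#' a reference: proper rotation (determinant +1) plus translation, via SVD
#' of the cross-covariance matrix, with the RMSD after superposition.
#'
#' @param mobile n x 3 coordinate matrix (Angstrom).
#' @param reference n x 3 coordinate matrix.
#' @param selection optional integer row indices used to compute the fit
#'   (and the reported RMSD); the transform is applied to all rows.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation` applied to centred
#'   coordinates -- use `$transformed`), `rmsd` (Angstrom) and
#'   `transformed` (n x 3).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop_ib("mobile and reference must be equal-sized n x 3 matrices")
  sel <- selection %||% seq_len(nrow(mobile))
  if (length(sel) < 3L) stop_ib("need at least 3 selected atoms")
  ms <- mobile[sel, , drop = FALSE]
  rs <- reference[sel, , drop = FALSE]
  mc <- colMeans(ms)
  rc <- colMeans(rs)
  msc <- sweep(ms, 2L, mc)
  rsc <- sweep(rs, 2L, rc)
  A <- t(msc) %*% rsc
  sv <- svd(A)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
    stop_ib("degenerate (collinear) selection; superposition is ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transformed <- sweep(sweep(mobile, 2L, mc) %*% t(R), 2L, rc, "+")
  dev <- transformed[sel, , drop = FALSE] - rs
  rmsd <- sqrt(mean(rowSums(dev * dev)))
  list(rotation = R, translation = as.numeric(rc - R %*% mc), rmsd = rmsd,
       transformed = transformed)
}

# Backbone heavy-atom indices (N, CA, C, O) of protein residues; falls back
# to all protein heavy atoms for reduced models without full backbones.
backbone_selection <- function(topology) {
  a <- topology$atoms
  prot <- a$residue_index %in% topology$residues$residue_index[
    is_protein_residue(topology$residues$residue_name)]
  bb <- which(prot & a$is_heavy & a$name %in% c("N", "CA", "C", "O"))
  if (length(bb) >= 3L) bb else which(prot & a$is_heavy)
}

#' Per-frame RMSD series
#'
#' Superposes every frame onto a reference over a selection (default:
#' protein backbone) and reports the per-frame RMSD, with mean and standard
#' deviation as attributes.
#'
#' @param traj a [trajectory()].
#' @param reference n x 3 reference coordinates (default: first frame).
#' @param selection integer atom indices (default: backbone heavy atoms).
#' @return numeric vector of per-frame RMSD (Angstrom) with attributes
#'   `mean` and `sd`.
#' @export
rmsd_series <- function(traj, reference = NULL, selection = NULL) {
  if (is.null(reference)) reference <- traj$coords[, , 1L]
  if (is.null(selection)) selection <- backbone_selection(traj$topology)
  out <- vapply(seq_len(n_frames(traj)), function(i)
    kabsch_superpose(traj$coords[, , i], reference, selection)$rmsd,
    numeric(1L))
  attr(out, "mean") <- mean(out)
  attr(out, "sd") <- stats::sd(out)
  out
}

#' Per-residue RMSF
#'
#' Root-mean-square fluctuation of atomic positions about their
#' time-average, averaged per residue. The trajectory is assumed already
#' aligned to a common reference.
#'
#' @param traj a [trajectory()] (>= 2 frames).
#' @param selection integer atom indices (default: all heavy atoms).
#' @return data.frame with `residue_index`, `residue_name`, `rmsf`
#'   (Angstrom).
#' @export
rmsf_per_residue <- function(traj, selection = NULL) {
  if (n_frames(traj) < 2L) stop_ib("RMSF needs at least 2 frames")
  a <- traj$topology$atoms
  if (is.null(selection)) selection <- a$atom_id[a$is_heavy]
  mean_pos <- apply(traj$coords[selection, , , drop = FALSE], c(1L, 2L), mean)
  dev2 <- sweep(traj$coords[selection, , , drop = FALSE], c(1L, 2L), mean_pos)
  # per-atom mean over frames of the squared 3-D displacement
  per_atom <- sqrt(rowMeans(apply(dev2^2, c(1L, 3L), sum)))
  res_idx <- a$residue_index[match(selection, a$atom_id)]
  agg <- tapply(per_atom, res_idx, mean)
  data.frame(
    residue_index = as.integer(names(agg)),
    residue_name = traj$topology$residues$residue_name[
      match(as.integer(names(agg)), traj$topology$residues$residue_index)],
    rmsf = as.numeric(agg),
    stringsAsFactors = FALSE, row.names = NULL)
}

# Ion reference point per frame: single-atom position, or the bond midpoint
# for diatomic ions (per-atom weighting available via weight_atoms).
ion_reference_points <- function(traj, ion, weight_atoms = FALSE) {
  if (length(ion$atom_ids) == 1L || weight_atoms) {
    pts <- lapply(ion$atom_ids, function(a) t(matrix(traj$coords[a, , ], nrow = 3L)))
    do.call(rbind, pts)
  } else {
    t((matrix(traj$coords[ion$atom_ids[1L], , ], nrow = 3L) +
         matrix(traj$coords[ion$atom_ids[2L], , ], nrow = 3L)) / 2)
  }
}

#' Voxelised ion-occupancy grid
#'
#' Three-dimensional histogram of ion positions over an aligned trajectory
#' at a given voxel size (default 1 Angstrom). In `"probability"` mode a
#' voxel's value is the fraction of frames in which at least one selected
#' ion's reference point lies inside it (the probability the voxel contains
#' an ion at any given frame); `"mean_count"` mode stores the mean per-frame
#' ion count instead. The reference point of a diatomic ion is its bond
#' midpoint. Grid bounds auto-fit the data plus a margin.
#'
#' @param traj an aligned [trajectory()].
#' @param ions list of [ion_selection()] (or a single one).
#' @param voxel_size voxel edge (Angstrom).
#' @param mode `"probability"` or `"mean_count"`.
#' @param margin bounds padding (Angstrom).
#' @return An object of class `"occupancy_grid"`: list with `origin`,
#'   `voxel_size`, `shape`, `values` (3-D array), `n_frames`, `mode` and
#'   `frame_counts` (ions inside the grid per frame).
#' @export
occupancy_grid <- function(traj, ions, voxel_size = 1.0,
                           mode = c("probability", "mean_count"),
                           margin = 2) {
  mode <- match.arg(mode)
  check_number(voxel_size, "voxel_size", lower = 0, strict = TRUE)
  if (inherits(ions, "ion_selection")) ions <- list(ions)
  n_fr <- n_frames(traj)
  if (!n_fr) stop_ib("empty trajectory")
  pts <- do.call(rbind, lapply(ions, function(io)
    ion_reference_points(traj, io)))
  frame_of <- rep(seq_len(n_fr), times = length(ions))
  origin <- apply(pts, 2L, min) - margin
  shape <- pmax(ceiling((apply(pts, 2L, max) + margin - origin) / voxel_size),
                1L)
  idx3 <- pmin(floor(sweep(pts, 2L, origin) / voxel_size),
               matrix(shape - 1L, nrow(pts), 3L, byrow = TRUE)) + 1L
  lin <- (idx3[, 3L] - 1L) * shape[1L] * shape[2L] +
    (idx3[, 2L] - 1L) * shape[1L] + idx3[, 1L]
  nvox <- prod(shape)
  if (mode == "probability") {
    dup <- duplicated(cbind(frame_of, lin))
    tab <- tabulate(lin[!dup], nbins = nvox)
  } else {
    tab <- tabulate(lin, nbins = nvox)
  }
  values <- array(tab / n_fr, dim = shape)
  structure(list(origin = origin, voxel_size = voxel_size, shape = shape,
                 values = values, n_frames = n_fr, mode = mode,
                 frame_counts = tabulate(frame_of, nbins = n_fr)),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat("<occupancy_grid> ", paste(x$shape, collapse = " x "),
      " voxels of ", x$voxel_size, " A (", x$mode, "), max = ",
      signif(max(x$values), 3), "\n", sep = "")
  invisible(x)
}

# Centres of all voxels as an n x 3 matrix (same linear order as values).
voxel_centres <- function(grid) {
  g <- expand.grid(i = seq_len(grid$shape[1L]), j = seq_len(grid$shape[2L]),
                   k = seq_len(grid$shape[3L]))
  sweep((as.matrix(g) - 0.5) * grid$voxel_size, 2L, grid$origin, "+")
}

#' Extract occupancy hotspots
#'
#' 26-connected components of voxels at or above an iso-level, sorted by
#' peak value. Each hotspot carries its occupancy-weighted centroid, peak
#' value, member voxels, and (when a topology plus coordinates are given)
#' the residues with any atom within `annotate_radius` of the centroid.
#'
#' @param grid an [occupancy_grid()].
#' @param iso_level occupancy threshold (> 0).
#' @param topology optional [topology()] for residue annotation.
#' @param coords optional n x 3 reference coordinates matching `topology`.
#' @param annotate_radius annotation radius (Angstrom).
#' @return list of hotspots; each is a list with `voxels` (m x 3 index
#'   matrix), `centroid`, `peak`, `n_voxels`, `residues` (or `NULL`).
#' @export
extract_hotspots <- function(grid, iso_level, topology = NULL, coords = NULL,
                             annotate_radius = 4) {
  check_number(iso_level, "iso_level", lower = 0, strict = TRUE)
  mask <- grid$values >= iso_level
  if (!any(mask)) return(list())
  shape <- grid$shape
  labels <- array(0L, dim = shape)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  active <- which(mask, arr.ind = TRUE)
  comp <- 0L
  for (s in seq_len(nrow(active))) {
    v <- active[s, ]
    if (labels[v[1L], v[2L], v[3L]] != 0L) next
    comp <- comp + 1L
    queue <- matrix(v, ncol = 3L)
    labels[v[1L], v[2L], v[3L]] <- comp
    while (nrow(queue)) {
      cur <- queue[1L, ]
      queue <- queue[-1L, , drop = FALSE]
      nb <- sweep(offs, 2L, cur, "+")
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= shape[1L] &
        nb[, 2L] >= 1L & nb[, 2L] <= shape[2L] &
        nb[, 3L] >= 1L & nb[, 3L] <= shape[3L]
      nb <- nb[ok, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        w <- nb[q, ]
        if (mask[w[1L], w[2L], w[3L]] && labels[w[1L], w[2L], w[3L]] == 0L) {
          labels[w[1L], w[2L], w[3L]] <- comp
          queue <- rbind(queue, w)
        }
      }
    }
  }
  hotspots <- lapply(seq_len(comp), function(cc) {
    vox <- which(labels == cc, arr.ind = TRUE)
    vals <- grid$values[vox]
    ctr <- sweep((vox - 0.5) * grid$voxel_size, 2L, grid$origin, "+")
    centroid <- colSums(ctr * vals) / sum(vals)
    residues <- NULL
    if (!is.null(topology) && !is.null(coords)) {
      d <- row_norms(sweep(as.matrix(coords), 2L, centroid))
      near <- unique(topology$atoms$residue_index[d <= annotate_radius])
      residues <- topology$residues[
        topology$residues$residue_index %in% near, , drop = FALSE]
    }
    list(voxels = unname(vox), centroid = unname(centroid),
         peak = max(vals), n_voxels = nrow(vox), residues = residues)
  })
  hotspots[order(vapply(hotspots, `[[`, numeric(1L), "peak"),
                 decreasing = TRUE)]
}

#' Write an occupancy grid as an OpenDX scalar field
#'
#' Standard OpenDX format as read by VMD and gridDataFormats consumers
#' (z index fastest).
#'
#' @param grid an [occupancy_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  n <- prod(grid$shape)
  con <- file(path, "w")
  on.exit(close(con))
  h <- grid$voxel_size
  # voxel-centre positions
  o <- grid$origin + h / 2
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            grid$shape[1L], grid$shape[2L], grid$shape[3L]),
    sprintf("origin %.6f %.6f %.6f", o[1L], o[2L], o[3L]),
    sprintf("delta %.6f 0 0", h),
    sprintf("delta 0 %.6f 0", h),
    sprintf("delta 0 0 %.6f", h),
    sprintf("object 2 class gridconnections counts %d %d %d",
            grid$shape[1L], grid$shape[2L], grid$shape[3L]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  ), con)
  vals <- as.vector(aperm(grid$values, c(3L, 2L, 1L)))
  pad <- (-length(vals)) %% 3L
  if (pad) vals <- c(vals, rep(NA_real_, pad))
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"density\" class field"), con)
  invisible(path)
}
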