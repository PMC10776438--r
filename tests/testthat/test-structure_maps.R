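rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(8)
  ref <- matrix(rnorm(30 * 3, sd = 5), ncol = 3)
  # identical structures: zero RMSD, identity rotation
  fit0 <- kabsch_superpose(ref, ref)
  expect_lt(fit0$rmsd, 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)

  # known 30-degree rotation + translation: exact recovery
  R <- rotation_z(30)
  mob <- ref %*% t(R) + matrix(c(3, -2, 7), nrow(ref), 3, byrow = TRUE)
  fit <- kabsch_superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$transformed, ref, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  # degenerate (collinear) selections are rejected
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD is invariant under global rigid motion of both inputs", {
  set.seed(9)
  ref <- matrix(rnorm(25 * 3, sd = 4), ncol = 3)
  mob <- ref + matrix(rnorm(25 * 3, sd = 0.3), ncol = 3)
  base <- kabsch_superpose(mob, ref)$rmsd
  R <- rotation_z(117)
  shift <- matrix(c(-4, 9, 2), 25, 3, byrow = TRUE)
  moved <- kabsch_superpose(mob %*% t(R) + shift, ref %*% t(R) + shift)$rmsd
  expect_equal(moved, base, tolerance = 1e-10)
})

test_that("Kabsch RMSD of a noisy copy matches the sigma*sqrt(3) expectation", {
  # Monte-Carlo oracle: per-coordinate Gaussian noise sigma -> RMSD ~ sigma*sqrt(3)
  set.seed(10)
  sigma <- 0.5
  rmsds <- vapply(1:8, function(i) {
    ref <- matrix(rnorm(200 * 3, sd = 6), ncol = 3)
    mob <- ref + matrix(rnorm(200 * 3, sd = sigma), ncol = 3)
    kabsch_superpose(mob, ref)$rmsd
  }, numeric(1))
  expect_equal(mean(rmsds), sigma * sqrt(3), tolerance = 0.2)
})

test_that("kabsch agrees with the bio3d reference implementation", {
  set.seed(11)
  ref <- matrix(rnorm(20 * 3, sd = 5), ncol = 3)
  mob <- ref %*% t(rotation_z(40)) + 2 +
    matrix(rnorm(20 * 3, sd = 0.2), ncol = 3)
  ours <- kabsch_superpose(mob, ref)
  theirs <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(ref)),
                                            mobile = as.vector(t(mob))))
  theirs_rmsd <- bio3d::rmsd(as.vector(t(ref)), theirs)
  expect_equal(ours$rmsd, theirs_rmsd, tolerance = 1e-3)
})

test_that("RMSD series is zero for static or rigidly shifted trajectories", {
  d <- generate_decoy_protein(30, seed = 3)
  nf <- 4
  coords <- array(rep(d$coords, nf), dim = c(30, 3, nf))
  coords[, , 3] <- coords[, , 3] + 5           # pure translation
  coords[, , 4] <- coords[, , 4] %*% t(rotation_z(25))  # pure rotation
  traj <- trajectory(d$topology, coords, times = (0:(nf - 1)) * 200)
  r <- rmsd_series(traj)
  expect_true(all(r < 1e-10))
  expect_lt(attr(r, "mean"), 1e-10)

  # one atom displaced by 3 A among N = 30: RMSD bounded by 3/sqrt(30)
  coords2 <- array(rep(d$coords, 2), dim = c(30, 3, 2))
  coords2[1, 1, 2] <- coords2[1, 1, 2] + 3
  traj2 <- trajectory(d$topology, coords2, times = c(0, 200))
  r2 <- rmsd_series(traj2)
  expect_lte(r2[2], 3 / sqrt(30) + 1e-9)
  expect_gt(r2[2], 0.3)  # fitting can reduce, not remove, the deviation
})

test_that("RMSF recovers isotropic jitter and localises moving residues", {
  d <- generate_decoy_protein(20, seed = 4)
  nf <- 3000
  sigma <- 0.4
  set.seed(12)
  coords <- array(rep(d$coords, nf), dim = c(20, 3, nf)) +
    array(rnorm(20 * 3 * nf, sd = sigma), dim = c(20, 3, nf))
  traj <- trajectory(d$topology, coords, times = (0:(nf - 1)) * 200)
  rf <- rmsf_per_residue(traj)
  expect_equal(mean(rf$rmsf), sigma * sqrt(3), tolerance = 0.05)

  # one oscillating residue, others fixed
  coords2 <- array(rep(d$coords, 4), dim = c(20, 3, 4))
  coords2[5, 1, ] <- coords2[5, 1, ] + c(-1, 1, -1, 1)
  traj2 <- trajectory(d$topology, coords2, times = (0:3) * 200)
  rf2 <- rmsf_per_residue(traj2)
  expect_equal(rf2$rmsf[rf2$residue_index == 5], 1)
  expect_true(all(rf2$rmsf[rf2$residue_index != 5] == 0))

  expect_error(rmsf_per_residue(
    trajectory(d$topology, array(d$coords, dim = c(20, 3, 1)), times = 0)),
    "at least 2 frames")
})

test_that("occupancy grids are normalised per frame and conserve ions", {
  # single ion fixed in one voxel: that voxel 1.0, all others 0
  top <- make_topology(c("C", "O"), res_names = c("ARG", "ION"))
  nf <- 10
  coords <- array(0, dim = c(2, 3, nf))
  coords[2, , ] <- 5.5
  traj <- trajectory(top, coords, times = (0:(nf - 1)) * 200)
  ion <- ion_selection("ion", 2L, -1, top)
  g <- occupancy_grid(traj, ion, voxel_size = 1)
  expect_equal(max(g$values), 1)
  expect_equal(sum(g$values > 0), 1L)

  # alternating between two voxels over an even frame count: 0.5 / 0.5
  coords2 <- coords
  coords2[2, 1, seq(2, nf, by = 2)] <- 9.5
  traj2 <- trajectory(top, coords2, times = (0:(nf - 1)) * 200)
  g2 <- occupancy_grid(traj2, ion, voxel_size = 1)
  expect_equal(sort(g2$values[g2$values > 0]), c(0.5, 0.5))

  # conservation on synthetic data: mean-count mode sums to n_ions
  sim <- markov_fixture(n_ions = 3, duration = 60, seed = 13)
  gm <- occupancy_grid(sim$trajectory, sim$ions, mode = "mean_count")
  expect_equal(sum(gm$values), 3, tolerance = 1e-12)
  expect_true(all(gm$frame_counts == 3))
})

test_that("hotspot extraction separates blobs by iso-level (flood-fill oracle)", {
  # constructed grid: two high blobs bridged by mid-level voxels
  vals <- array(0, dim = c(9, 5, 5))
  vals[2, 3, 3] <- 0.5
  vals[3, 3, 3] <- 0.4
  vals[8, 3, 3] <- 0.45
  vals[4:7, 3, 3] <- 0.1   # bridge
  grid <- structure(list(origin = c(0, 0, 0), voxel_size = 1,
                         shape = c(9L, 5L, 5L), values = vals,
                         n_frames = 1L, mode = "probability",
                         frame_counts = 1L),
                    class = "occupancy_grid")
  high <- extract_hotspots(grid, iso_level = 0.2)
  expect_length(high, 2L)
  expect_equal(high[[1]]$peak, 0.5)
  low <- extract_hotspots(grid, iso_level = 0.05)
  expect_length(low, 1L)
  expect_length(extract_hotspots(grid, iso_level = 0.9), 0L)

  # diagonal adjacency is one component under 26-connectivity
  vals2 <- array(0, dim = c(4, 4, 4))
  vals2[1, 1, 1] <- 0.3
  vals2[2, 2, 2] <- 0.3
  grid2 <- grid
  grid2$shape <- c(4L, 4L, 4L)
  grid2$values <- vals2
  expect_length(extract_hotspots(grid2, 0.2), 1L)
})

test_that("hotspots recover generator site centres within one voxel", {
  sim <- markov_fixture(n_ions = 3, duration = 400, seed = 14,
                        two_sites = TRUE)
  g <- occupancy_grid(sim$trajectory, sim$ions, voxel_size = 1)
  hs <- extract_hotspots(g, iso_level = 0.02)
  expect_length(hs, 2L)
  centres <- rbind(c(15, 30, 30), c(45, 30, 30))
  got <- do.call(rbind, lapply(hs, `[[`, "centroid"))
  got <- got[order(got[, 1]), ]
  expect_true(all(abs(got - centres) <= 1))
})

test_that("OpenDX export writes a well-formed scalar field", {
  vals <- array(seq(0, 1, length.out = 24), dim = c(2, 3, 4))
  grid <- structure(list(origin = c(1, 2, 3), voxel_size = 0.5,
                         shape = c(2L, 3L, 4L), values = vals,
                         n_frames = 1L, mode = "probability",
                         frame_counts = 1L),
                    class = "occupancy_grid")
  p <- tempfile(fileext = ".dx")
  write_dx(grid, p)
  lines <- readLines(p)
  expect_match(lines[1], "counts 2 3 4")
  expect_match(lines[7], "items 24")
  nums <- as.numeric(unlist(strsplit(paste(lines[8:15], collapse = " "),
                                     " +")))
  nums <- nums[!is.na(nums)]
  expect_length(nums, 24L)
  # z varies fastest: first 4 values are vals[1, 1, ]
  expect_equal(nums[1:4], vals[1, 1, ], tolerance = 1e-6)
})
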