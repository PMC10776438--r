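## Synthetic-data generators with known ground truth. These emulate the
## statistical structure the analyses assume -- Markovian site binding with
## exponential residence times, isotropic rotational Brownian motion, and
## shell-structured pseudo-water -- so every downstream stage can be tested
## without production MD data.

#' Specify a Markovian binding-kinetics simulation
#'
#' Each ion is an independent continuous-time Markov chain (free vs bound at
#' one of several labelled sites) discretised at the frame interval `dt`.
#' Residence times are exponential with mean `1/k_off`; while bound the ion
#' sits at the site centre plus isotropic Gaussian jitter, while free it is
#' placed uniformly in the box outside 6-Angstrom exclusion spheres around
#' the sites.
#'
#' Defaults mirror the sampling character of long production MD: dt of
#' 0.2 ns (the coarse trajectory sampling interval) and a positional jitter
#' of 0.5 Angstrom, which lets the 4 / 3 Angstrom geometric contact criteria
#' cleanly recover the latent bound state.
#'
#' @param sites data.frame with columns `site_id`, `x`, `y`, `z` (centre,
#'   Angstrom), `jitter_sigma` (Angstrom), `k_on`, `k_off` (1/ns).
#' @param box length-3 box vector (Angstrom).
#' @param n_ions number of ions.
#' @param duration total simulated time (ns).
#' @param dt frame interval (ns).
#' @param seed integer seed; per-ion substreams are derived from it.
#' @return An object of class `"binding_kinetics_spec"`.
#' @export
binding_kinetics_spec <- function(sites, box, n_ions = 1L, duration = 100,
                                  dt = 0.2, seed = 1L) {
  req <- c("site_id", "x", "y", "z", "jitter_sigma", "k_on", "k_off")
  sites <- as.data.frame(sites)
  if (!all(req %in% names(sites)))
    stop_ib("sites must have columns: ", paste(req, collapse = ", "))
  if (any(sites$k_on < 0) || any(sites$k_off < 0))
    stop_ib("rates must be >= 0")
  if (any(sites$jitter_sigma < 0)) stop_ib("jitter_sigma must be >= 0")
  check_number(dt, "dt", lower = 0, strict = TRUE)
  if (duration < dt) stop_ib("duration must be >= dt")
  stopifnot(length(box) == 3L, all(box > 0), n_ions >= 1L)
  structure(list(sites = sites, box = as.numeric(box),
                 n_ions = as.integer(n_ions), duration = duration, dt = dt,
                 seed = as.integer(seed)),
            class = "binding_kinetics_spec")
}

# Draw the next run length (frames) in a discretised two-state chain.
# rgeom() counts failures before the first success, so +1 gives the number
# of frames spent in the current state (>= 1).
run_length <- function(p) if (p <= 0) Inf else stats::rgeom(1L, p) + 1

#' Simulate Markovian site binding
#'
#' Generates a [trajectory()] (site anchor atoms plus ions) together with
#' the latent per-frame state of every ion, which downstream event detection
#' can be validated against. The per-step transition probabilities are
#' `1 - exp(-k dt)`; a coarse discretisation where the linear one-step
#' probability `k dt` would exceed 1 is rejected.
#'
#' The returned topology has one fixed heavy "anchor" atom per site (an ARG
#' pseudo-residue at the site centre) and one atom per ion (non-protein
#' residue `ION`), so ion-protein minimum distances equal ion-site-centre
#' distances.
#'
#' @param spec a [binding_kinetics_spec()].
#' @return list with components `trajectory`, `states` (integer matrix
#'   `n_frames x n_ions`; 0 = free, otherwise the site_id), `ions` (list of
#'   [ion_selection()]), `sites` (list of [site_definition()]) and `spec`.
#' @export
simulate_markov_binding <- function(spec) {
  stopifnot(inherits(spec, "binding_kinetics_spec"))
  s <- spec$sites
  n_sites <- nrow(s)
  k_on_tot <- sum(s$k_on)
  if (k_on_tot * spec$dt > 1 || any(s$k_off * spec$dt > 1))
    stop_ib("per-step transition probability exceeds 1 at dt = ", spec$dt,
            " ns; decrease dt")
  n_fr <- floor(spec$duration / spec$dt) + 1L
  p_bind <- 1 - exp(-k_on_tot * spec$dt)
  p_off <- 1 - exp(-s$k_off * spec$dt)
  centres <- as.matrix(s[, c("x", "y", "z")])

  states <- matrix(0L, nrow = n_fr, ncol = spec$n_ions)
  ion_xyz <- array(NA_real_, dim = c(spec$n_ions, 3L, n_fr))

  for (ion in seq_len(spec$n_ions)) {
    set.seed(stream_seed(spec$seed, ion))
    st <- integer(n_fr)
    pos <- 1L
    cur <- 0L
    while (pos <= n_fr) {
      if (cur == 0L) {
        len <- run_length(p_bind)
        nxt <- if (k_on_tot > 0)
          sample.int(n_sites, 1L, prob = s$k_on) else 0L
      } else {
        len <- run_length(p_off[cur])
        nxt <- 0L
      }
      end <- min(pos + len - 1, n_fr)
      st[pos:end] <- cur
      pos <- as.integer(end + 1L)
      cur <- as.integer(nxt)
    }
    # st holds the site row index; expose the user-facing site_id
    states[, ion] <- ifelse(st == 0L, 0L, s$site_id[pmax(st, 1L)])

    # bound frames: site centre + isotropic Gaussian jitter
    xyz <- matrix(NA_real_, n_fr, 3L)
    for (j in seq_len(n_sites)) {
      idx <- which(st == j)
      if (length(idx))
        xyz[idx, ] <- centres[rep(j, length(idx)), , drop = FALSE] +
          matrix(stats::rnorm(3L * length(idx), sd = s$jitter_sigma[j]),
                 ncol = 3L)
    }
    # free frames: uniform in box, rejection-sampled outside 6 A site spheres
    free_idx <- which(st == 0L)
    if (length(free_idx)) {
      pts <- matrix(stats::runif(3L * length(free_idx)), ncol = 3L)
      pts <- sweep(pts, 2L, spec$box, "*")
      repeat {
        bad <- rep(FALSE, nrow(pts))
        for (j in seq_len(n_sites)) {
          d <- row_norms(min_image(sweep(pts, 2L, centres[j, ]), spec$box))
          bad <- bad | d < 6
        }
        if (!any(bad)) break
        pts[bad, ] <- sweep(matrix(stats::runif(3L * sum(bad)), ncol = 3L),
                            2L, spec$box, "*")
      }
      xyz[free_idx, ] <- pts
    }
    ion_xyz[ion, , ] <- t(xyz)
  }

  # topology: one ARG anchor atom per site, one O atom per ion
  atoms <- data.frame(
    atom_id = seq_len(n_sites + spec$n_ions),
    name = c(rep("CZ", n_sites), rep("O1", spec$n_ions)),
    element = c(rep("C", n_sites), rep("O", spec$n_ions)),
    is_heavy = TRUE,
    residue_index = seq_len(n_sites + spec$n_ions),
    stringsAsFactors = FALSE
  )
  residues <- data.frame(
    residue_index = seq_len(n_sites + spec$n_ions),
    residue_name = c(rep("ARG", n_sites), rep("ION", spec$n_ions)),
    chain = "A",
    stringsAsFactors = FALSE
  )
  top <- topology(atoms, residues)
  coords <- array(NA_real_, dim = c(n_sites + spec$n_ions, 3L, n_fr))
  for (j in seq_len(n_sites)) coords[j, , ] <- centres[j, ]
  coords[n_sites + seq_len(spec$n_ions), , ] <- ion_xyz
  times_ps <- (seq_len(n_fr) - 1L) * spec$dt * 1000
  traj <- trajectory(top, coords, times_ps, box = spec$box)

  ions <- lapply(seq_len(spec$n_ions), function(i)
    ion_selection(paste0("ion", i), n_sites + i, charge = -1, topology = top))
  site_defs <- lapply(seq_len(n_sites), function(j)
    site_definition(paste0("site", s$site_id[j]), j, topology = top))
  list(trajectory = traj, states = states, ions = ions, sites = site_defs,
       spec = spec)
}

#' Residence times from a latent state series
#'
#' Extracts the durations of contiguous runs in each ion's latent state
#' series. Runs truncated by the ends of the simulation are dropped by
#' default since their lengths are censored.
#'
#' @param states integer matrix as returned by [simulate_markov_binding()].
#' @param dt frame interval (ns).
#' @param state which state to extract runs of; `"bound"` pools all sites.
#' @param drop_censored drop first/last runs of each series.
#' @return Numeric vector of residence times (ns, frame-count convention:
#'   a run of k frames lasts k dt).
#' @export
state_residence_times <- function(states, dt, state = "bound",
                                  drop_censored = TRUE) {
  states <- as.matrix(states)
  out <- lapply(seq_len(ncol(states)), function(i) {
    r <- rle(states[, i])
    keep <- if (identical(state, "bound")) r$values != 0L else r$values == state
    if (drop_censored) {
      keep[1L] <- FALSE
      keep[length(keep)] <- FALSE
    }
    r$lengths[keep] * dt
  })
  unlist(out)
}

#' Specify a rotational-diffusion simulation
#'
#' Isotropic rotational Brownian motion of a unit bond vector with rotational
#' diffusion coefficient `D_r`; the ground-truth second-rank correlation time
#' is `tau2 = 1 / (6 D_r)`.
#'
#' @param D_r rotational diffusion coefficient (rad^2/ps), >= 0.
#' @param dt time step (ps); must satisfy `D_r * dt < 0.01` rad^2.
#' @param n_steps number of steps.
#' @param seed integer seed.
#' @return An object of class `"rotational_diffusion_spec"`.
#' @export
rotational_diffusion_spec <- function(D_r, dt = 1, n_steps = 1000L,
                                      seed = 1L) {
  check_number(D_r, "D_r", lower = 0)
  check_number(dt, "dt", lower = 0, strict = TRUE)
  if (D_r * dt >= 0.01)
    stop_ib("D_r * dt = ", signif(D_r * dt, 3),
            " rad^2 is too coarse; use dt < ", signif(0.01 / D_r, 3), " ps")
  structure(list(D_r = D_r, dt = dt, n_steps = as.integer(n_steps),
                 seed = as.integer(seed)),
            class = "rotational_diffusion_spec")
}

#' Simulate rotational Brownian motion of a unit vector
#'
#' Each step rotates the vector about a random axis perpendicular to it by a
#' Gaussian angle of variance `4 D_r dt` -- the two perpendicular diffusive
#' degrees of freedom contribute `2 D_r dt` each, which makes the
#' second-rank correlation decay as `exp(-6 D_r t)` and gives the
#' ground-truth `tau2 = 1/(6 D_r)`. The vector norm is maintained at 1 to
#' machine precision.
#'
#' @param spec a [rotational_diffusion_spec()].
#' @return `(n_steps + 1) x 3` matrix of unit vectors with attributes
#'   `dt` (ps) and `tau2_true` (ps; `Inf` when `D_r = 0`).
#' @export
simulate_rotational_diffusion <- function(spec) {
  stopifnot(inherits(spec, "rotational_diffusion_spec"))
  set.seed(spec$seed)
  u0 <- c(0, 0, 1)
  if (spec$D_r == 0) {
    u <- matrix(u0, nrow = spec$n_steps + 1L, ncol = 3L, byrow = TRUE)
  } else {
    angles <- stats::rnorm(spec$n_steps, sd = sqrt(4 * spec$D_r * spec$dt))
    axes <- matrix(stats::rnorm(3L * spec$n_steps), ncol = 3L)
    u <- cpp_rotational_walk(u0, angles, axes)
  }
  attr(u, "dt") <- spec$dt
  attr(u, "tau2_true") <- if (spec$D_r > 0) 1 / (6 * spec$D_r) else Inf
  u
}

#' Specify a shell-structured solvation point generator
#'
#' @param bulk_density homogeneous background density (waters/Angstrom^3).
#' @param shells data.frame with columns `r0` (shell radius, Angstrom),
#'   `width` (Gaussian radial width, Angstrom), `n_waters` (points per
#'   shell); rows sorted by `r0`.
#' @param r_max outer radius of the generated region (Angstrom).
#' @param seed integer seed.
#' @return An object of class `"solvation_shell_spec"`.
#' @export
solvation_shell_spec <- function(bulk_density = 0, shells = NULL, r_max = 10,
                                 seed = 1L) {
  check_number(bulk_density, "bulk_density", lower = 0)
  check_number(r_max, "r_max", lower = 0, strict = TRUE)
  if (!is.null(shells) && nrow(shells)) {
    shells <- as.data.frame(shells)
    req <- c("r0", "width", "n_waters")
    if (!all(req %in% names(shells)))
      stop_ib("shells must have columns: ", paste(req, collapse = ", "))
    if (is.unsorted(shells$r0)) stop_ib("shells must be sorted by r0")
    if (any(shells$n_waters < 0) || any(shells$width < 0))
      stop_ib("shell widths and counts must be >= 0")
    if (r_max <= max(shells$r0)) stop_ib("r_max must exceed the outermost shell")
  } else {
    shells <- data.frame(r0 = numeric(), width = numeric(),
                         n_waters = numeric())
  }
  structure(list(bulk_density = bulk_density, shells = shells, r_max = r_max,
                 seed = as.integer(seed)),
            class = "solvation_shell_spec")
}

#' Generate pseudo-water positions around an ion at the origin
#'
#' Bulk points come from a homogeneous Poisson process of intensity
#' `bulk_density` within `1.5 < r <= r_max` (the excluded core mimics the
#' ion's hard sphere); each shell contributes exactly `n_waters` points at
#' radius `r0 + N(0, width^2)` with uniform directions.
#'
#' @param spec a [solvation_shell_spec()].
#' @return `n x 3` matrix of positions (possibly 0-row).
#' @export
generate_solvation_points <- function(spec) {
  stopifnot(inherits(spec, "solvation_shell_spec"))
  set.seed(spec$seed)
  r_min <- 1.5
  pts <- list()
  if (spec$bulk_density > 0) {
    vol <- 4 / 3 * pi * (spec$r_max^3 - r_min^3)
    n <- stats::rpois(1L, spec$bulk_density * vol)
    if (n > 0) {
      r <- (stats::runif(n) * (spec$r_max^3 - r_min^3) + r_min^3)^(1 / 3)
      pts[[length(pts) + 1L]] <- random_unit_vectors(n) * r
    }
  }
  for (j in seq_len(nrow(spec$shells))) {
    n <- spec$shells$n_waters[j]
    if (n > 0) {
      r <- abs(stats::rnorm(n, spec$shells$r0[j], spec$shells$width[j]))
      pts[[length(pts) + 1L]] <- random_unit_vectors(n) * r
    }
  }
  if (!length(pts)) return(matrix(numeric(), ncol = 3L,
                                  dimnames = list(NULL, c("x", "y", "z"))))
  out <- do.call(rbind, pts)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Generate a decoy protein on a sphere
#'
#' Places one alpha-carbon pseudo-atom per residue on a sphere surface
#' (Fibonacci lattice, deterministic given the seed-jittered radius),
#' labelling designated residues ARG and returning matching
#' [site_definition()] anchors. Useful as a minimal protein for testing
#' residue-level statistics and site assignment.
#'
#' @param n_residues number of residues (>= 1).
#' @param charged_site_residues integer indices of residues to label ARG and
#'   tag as binding-site anchors.
#' @param seed integer seed (controls small radial jitter).
#' @param radius sphere radius (Angstrom).
#' @return list with `topology`, `coords` (n x 3) and `sites` (list of
#'   [site_definition()]).
#' @export
generate_decoy_protein <- function(n_residues, charged_site_residues = integer(),
                                   seed = 1L, radius = 15) {
  if (n_residues < 1L) stop_ib("n_residues must be >= 1")
  charged_site_residues <- as.integer(charged_site_residues)
  if (length(charged_site_residues) &&
      (min(charged_site_residues) < 1L ||
       max(charged_site_residues) > n_residues))
    stop_ib("charged_site_residues out of range 1..", n_residues)
  set.seed(as.integer(seed))
  i <- seq_len(n_residues) - 0.5
  phi <- acos(1 - 2 * i / n_residues)
  theta <- pi * (1 + sqrt(5)) * i
  r <- radius + stats::rnorm(n_residues, sd = 0.2)
  coords <- cbind(x = r * sin(phi) * cos(theta),
                  y = r * sin(phi) * sin(theta),
                  z = r * cos(phi))
  # neutral filler residues cycle through a few common codes
  filler <- rep(c("ALA", "LEU", "SER", "GLY"), length.out = n_residues)
  res_names <- filler
  res_names[charged_site_residues] <- "ARG"
  atoms <- data.frame(atom_id = seq_len(n_residues), name = "CA",
                      element = "C", is_heavy = TRUE,
                      residue_index = seq_len(n_residues),
                      stringsAsFactors = FALSE)
  residues <- data.frame(residue_index = seq_len(n_residues),
                         residue_name = res_names, chain = "A",
                         stringsAsFactors = FALSE)
  top <- topology(atoms, residues)
  sites <- lapply(seq_along(charged_site_residues), function(k)
    site_definition(paste0("site", k), charged_site_residues[k],
                    topology = top))
  list(topology = top, coords = coords, sites = sites)
}
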