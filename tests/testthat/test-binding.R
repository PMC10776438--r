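test_that("minimum-distance series follows the closest-atom convention", {
  # ion at (0,0,3) from sole heavy atom at origin
  traj <- make_distance_trajectory(c(3, 3))
  ion <- ion_selection("ion", 2L, -1, traj$topology)
  ser <- min_distance_series(traj, ion)
  expect_equal(ser$d_min, c(3, 3))
  expect_equal(ser$nearest_residue_name, c("ARG", "ARG"))

  # 2-atom ion at z = 3 and z = 5: closest atom wins
  top <- make_topology(c("C", "O", "O"), res_names = c("ARG", "ION", "ION"))
  coords <- array(0, dim = c(3, 3, 1))
  coords[2, 3, 1] <- 3
  coords[3, 3, 1] <- 5
  traj2 <- trajectory(top, coords, times = 0)
  ion2 <- ion_selection("superoxide", 2:3, -1, top)
  expect_equal(min_distance_series(traj2, ion2)$d_min, 3)

  # hydrogens never count on the protein side
  toph <- make_topology(c("C", "H", "O"), res_names = c("ALA", "ALA", "ION"))
  ch <- array(0, dim = c(3, 3, 1))
  ch[2, 3, 1] <- 1    # hydrogen closer than the carbon
  ch[3, 3, 1] <- 4
  trajh <- trajectory(toph, ch, times = 0)
  expect_equal(min_distance_series(trajh, ion_selection("ion", 3L))$d_min, 4)

  expect_error(min_distance_series(traj2, ion2, protein_atoms = integer()),
               "no protein heavy atoms")
})

test_that("minimum-image distances agree with a 27-image brute force", {
  set.seed(77)
  box <- c(20, 25, 30)
  for (rep in 1:25) {
    a <- runif(3) * box
    b <- runif(3) * box * 3 - box  # may sit outside the primary cell
    top <- make_topology(c("C", "O"), res_names = c("ARG", "ION"))
    coords <- array(rbind(a, b), dim = c(2, 3, 1))
    traj <- trajectory(top, coords, times = 0, box = box)
    got <- min_distance_series(traj, ion_selection("ion", 2L))$d_min
    expect_equal(got, brute_force_min_image_dist(a, b, box),
                 tolerance = 1e-10)
  }
})

test_that("distance density integrates to one and reports contact probability", {
  ser <- make_distance_series(rep(2, 10))
  dd <- distance_density(ser, bin_width = 0.1, cutoff = 2.75)
  expect_equal(sum(dd$density * diff(dd$breaks)), 1, tolerance = 1e-12)
  expect_equal(dd$contact_probability, 1)

  ser2 <- make_distance_series(c(rep(2, 5), rep(5, 5)))
  expect_equal(distance_density(ser2, cutoff = 2.75)$contact_probability, 0.5)
  expect_error(distance_density(ser2, bin_width = 0), "> 0")
})

test_that("binding-event detection implements the two-frame rule and durations", {
  # (5, 3.9, 3.8, 5): one 2-frame event, t_b = 0.4 ns, kept
  ev <- detect_binding_events(make_distance_series(c(5, 3.9, 3.8, 5)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$t_b, 0.4)
  expect_equal(ev$n_frames, 2L)
  expect_equal(ev$t_end - ev$t_start, ev$t_b)

  # all above cutoff: empty
  expect_equal(nrow(detect_binding_events(make_distance_series(c(5, 6, 7)))),
               0L)

  # (3,3,5,3,3): two events of 0.4 ns
  ev2 <- detect_binding_events(make_distance_series(c(3, 3, 5, 3, 3)))
  expect_equal(ev2$t_b, c(0.4, 0.4))

  # single-frame contact dropped by the two-frame rule
  expect_equal(nrow(detect_binding_events(make_distance_series(c(5, 3, 5, 5)))),
               0L)

  # gap tolerance merges runs when requested
  ev3 <- detect_binding_events(make_distance_series(c(3, 3, 5, 3, 3)), gap = 1)
  expect_equal(ev3$t_b, 1.0)

  # non-uniform spacing is rejected
  ser <- make_distance_series(c(3, 3, 3))
  attr(ser, "dt") <- NULL
  ser$time_ns <- c(0, 0.2, 0.5)
  expect_error(detect_binding_events(ser), "non-uniform")
})

test_that("event detection equals a brute-force run scan on random series", {
  set.seed(123)
  for (rep in 1:60) {
    n <- sample(5:100, 1)
    d <- runif(n, 2, 6)
    ser <- make_distance_series(d)
    got <- detect_binding_events(ser, cutoff = 4)
    want <- brute_force_events(d, cutoff = 4, dt = 0.2)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$i_start, want$i_start)
      expect_equal(got$i_end, want$i_end)
      expect_equal(got$t_b, want$t_b, tolerance = 1e-12)
    }
  }
})

test_that("site assignment uses the majority-frame tally", {
  # two sites; ion sits within 3 A of site A for 10 frames, site B for 3
  top <- make_topology(c("C", "C", "O"),
                       res_names = c("ARG", "ARG", "ION"))
  nf <- 13
  coords <- array(0, dim = c(3, 3, nf))
  coords[2, 1, ] <- 20  # site B anchor at x = 20
  coords[3, 1, 1:10] <- 2     # near site A
  coords[3, 1, 11:13] <- 18   # near site B
  traj <- trajectory(top, coords, times = (0:(nf - 1)) * 200)
  ion <- ion_selection("ion", 3L, -1, top)
  sites <- list(site_definition("A", 1L, topology = top),
                site_definition("B", 2L, topology = top))
  ser <- min_distance_series(traj, ion)
  ev <- detect_binding_events(ser, cutoff = 25)  # one event spanning all frames
  ev <- assign_site(ev, traj, ion, sites)
  expect_equal(ev$site, "A")

  # ion far from every site: NA
  coords2 <- coords
  coords2[3, 1, ] <- 10
  traj2 <- trajectory(top, coords2, times = (0:(nf - 1)) * 200)
  ev2 <- detect_binding_events(min_distance_series(traj2, ion), cutoff = 25)
  ev2 <- assign_site(ev2, traj2, ion, sites)
  expect_true(is.na(ev2$site))
})

test_that("per-residue statistics pick each event's modal partner", {
  ev <- data.frame(residue = c("ARG", "ARG", "LYS", "LYS"))
  st <- residue_binding_stats(ev)
  expect_equal(st$fraction, c(0.5, 0.5))
  expect_equal(sum(st$fraction), 1)

  # generator ground truth: ARG anchors receive (essentially) all events
  sim <- markov_fixture(n_ions = 2, duration = 300, seed = 31)
  ser <- min_distance_series(sim$trajectory, sim$ions[[1]])
  events <- detect_binding_events(ser)
  st2 <- residue_binding_stats(events)
  expect_gte(st2$fraction[st2$residue_name == "ARG"], 0.9)
})

test_that("binding-time summaries reproduce printed-count percentages", {
  counts <- clcry4_binding_counts()
  condI <- counts[counts$condition == "I", c("site", "total", "ge_1ns",
                                             "ge_10ns", "ge_100ns")]
  summ <- binding_count_summary(condI)
  expect_equal(summ$pct_ge_1ns[summ$site == "all"], 32.3)
  expect_equal(summ$pct_ge_1ns[1:5], c(36.2, 42.3, 30.9, 25.2, 22.0))
  expect_equal(summ$total[summ$site == "all"], 10203)

  # summary from events matches direct counting
  ev <- data.frame(site = c("s1", "s1", "s2"), t_b = c(0.5, 2, 12))
  s <- binding_time_summary(ev)
  expect_equal(s$total, c(2L, 1L, 3L))
  expect_equal(s$pct_ge_1ns, c(50, 100, 66.7))
  expect_equal(s$pct_ge_10ns[s$site == "all"], 33.3)

  # empty input gives a zero aggregate, no division error
  s0 <- binding_time_summary(data.frame(site = character(), t_b = numeric()))
  expect_equal(s0$total, 0L)
  expect_equal(s0$pct_ge_1ns, 0)
})

test_that("mean binding time is the exponential-rate MLE", {
  expect_equal(mean_binding_time(c(1, 2, 3)), 2)
  expect_equal(mean_binding_time(7.5), 7.5)
  set.seed(99)
  tb <- rexp(5000, rate = 1 / 1.1)
  expect_equal(mean_binding_time(tb), 1.1, tolerance = 0.03)
  expect_error(mean_binding_time(numeric()), "no binding events")
})

test_that("survival curves step at the event durations", {
  curve <- bound_fraction_curve(c(1, 2, 3))
  expect_equal(curve$f[curve$t == 0], 1)
  expect_equal(curve$f[curve$t == 2], 2 / 3)
  expect_equal(curve$t, c(0, 1, 2, 3))
  expect_true(all(diff(curve$f) <= 0))
  expect_true(all(curve$f >= 0 & curve$f <= 1))
})

test_that("bi-exponential fits recover parameters and respect constraints", {
  a <- 0.9; tf <- 1; ts <- 50
  t <- c(0, exp(seq(log(0.05), log(250), length.out = 199)))
  f <- a * exp(-t / tf) + (1 - a) * exp(-t / ts)
  fit <- fit_biexponential(structure(data.frame(t = t, f = f),
                                     class = c("survival_curve",
                                               "data.frame")))
  expect_equal(fit$a_fast, 0.9, tolerance = 0.05)
  expect_equal(fit$tau_fast, 1, tolerance = 0.05)
  expect_equal(fit$tau_slow, 50, tolerance = 0.05)
  expect_equal(fit$a_fast + fit$a_slow, 1, tolerance = 1e-12)
  expect_gte(fit$tau_slow, fit$tau_fast)
  expect_equal(fit$fitted(0), 1, tolerance = 1e-12)

  # mono-exponential input: degenerate but well-behaved fit
  fm <- 1 * exp(-t / 2)
  fitm <- fit_biexponential(structure(data.frame(t = t, f = fm),
                                      class = c("survival_curve",
                                                "data.frame")))
  expect_lt(fitm$residual_norm, 1e-6)
  expect_equal(fitm$fitted(2), exp(-1), tolerance = 1e-4)

  expect_error(fit_biexponential(data.frame(t = 0:3, f = exp(-(0:3)))),
               "6 distinct")
})

test_that("hit rate divides events by simulated time", {
  expect_equal(round(hit_rate(498, 3074.8), 2), 0.16)
  expect_equal(hit_rate(0, 100), 0)
  expect_equal(hit_rate(10, 100), 0.1)
  expect_error(hit_rate(10, 0), "> 0")
})

test_that("escape termination triggers at the documented cutoffs", {
  top <- make_topology(c("C", "O"), res_names = c("ARG", "ION"))
  nf <- 12
  coords <- array(0, dim = c(2, 3, nf))
  coords[2, 3, ] <- 2
  traj <- trajectory(top, coords, times = (0:(nf - 1)) * 200)
  ion <- ion_selection("ion", 2L, -1, top)
  sites <- list(site_definition("A", 1L, topology = top))

  # never escapes: end of trajectory, untriggered
  idx <- escape_termination(traj, ion, sites, mode = "site_local")
  expect_equal(as.integer(idx), nf)
  expect_false(attr(idx, "triggered"))

  # steps from 2 to 5 A at frame 7 (site_local, 3 A rule)
  coords2 <- coords
  coords2[2, 3, 7:nf] <- 5
  traj2 <- trajectory(top, coords2, times = (0:(nf - 1)) * 200)
  idx2 <- escape_termination(traj2, ion, sites, mode = "site_local")
  expect_equal(as.integer(idx2), 7L)
  expect_true(attr(idx2, "triggered"))

  # far-field rule waits for the 10 A crossing
  coords3 <- coords
  coords3[2, 3, ] <- seq(2, 13, length.out = nf)
  traj3 <- trajectory(top, coords3, times = (0:(nf - 1)) * 200)
  idx3 <- escape_termination(traj3, ion, sites, mode = "far_field")
  expect_equal(as.integer(idx3),
               which(seq(2, 13, length.out = nf) > 10)[1])
})

test_that("hydrogen-bond detection applies distance and angle criteria", {
  # N-H...O collinear at 2.9 A: contact
  top <- make_topology(c("N", "H", "O"),
                       res_names = c("ARG", "ARG", "ION"),
                       names = c("NE", "HE", "O1"))
  top$atoms$residue_index <- c(1L, 1L, 2L)
  top$residues <- top$residues[c(1, 3), ]
  top$residues$residue_index <- c(1L, 2L)
  coords <- array(0, dim = c(3, 3, 1))
  coords[2, 3, 1] <- 1.0   # H along +z
  coords[3, 3, 1] <- 2.9   # acceptor along +z
  traj <- trajectory(top, coords, times = 0)
  ion <- ion_selection("ion", 3L, -1, top)
  hb <- detect_hydrogen_bonds(traj, ion, donor_atoms = 1L)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$angle, 180, tolerance = 1e-6)

  # H pointing away: no contact
  coords2 <- coords
  coords2[2, 3, 1] <- -1.0
  traj2 <- trajectory(top, coords2, times = 0)
  expect_equal(nrow(detect_hydrogen_bonds(traj2, ion, 1L)), 0L)

  # contacts are monotone non-increasing as the distance cutoff shrinks
  set.seed(17)
  nf <- 40
  coords3 <- array(0, dim = c(3, 3, nf))
  coords3[2, 3, ] <- 1.0
  coords3[3, 1, ] <- runif(nf, -1, 1)
  coords3[3, 3, ] <- runif(nf, 1.5, 5)
  traj3 <- trajectory(top, coords3, times = (0:(nf - 1)) * 200)
  cuts <- c(4.5, 4, 3.5, 3, 2.5)
  n_hits <- vapply(cuts, function(cc)
    nrow(detect_hydrogen_bonds(traj3, ion, 1L, d_cut = cc)), integer(1))
  expect_true(all(diff(n_hits) <= 0))

  # donor without hydrogen errors, naming the atom
  expect_error(detect_hydrogen_bonds(traj, ion, donor_atoms = 3L),
               "no attached hydrogen")
})

test_that("pearson correlation matches hand-computed values", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_correlation(1:5, -(1:5)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_correlation(1:3, c(2, 2, 2)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})
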