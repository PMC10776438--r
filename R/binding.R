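#' Minimum ion-protein distance series
#'
#' Per frame, the minimum Euclidean distance (minimum-image when the
#' trajectory has a box and `minimum_image = TRUE`) between any atom of the
#' ion and any protein heavy atom, together with the identity of the nearest
#' protein residue. For a diatomic ion such as superoxide the distance is
#' taken from whichever of its atoms is closest. Hydrogens are excluded on
#' the protein side.
#'
#' @param traj a [trajectory()].
#' @param ion an [ion_selection()].
#' @param protein_atoms optional integer atom ids for the protein side;
#'   defaults to all heavy atoms of standard amino-acid residues, excluding
#'   the ion's own atoms.
#' @param minimum_image use the minimum-image convention (default: on when
#'   the trajectory carries a box).
#' @return A `distance_series` data.frame with columns `time_ns`, `d_min`
#'   (Angstrom), `nearest_residue` (residue_index) and
#'   `nearest_residue_name`; frame spacing (ns) is stored in attribute `dt`.
#' @export
min_distance_series <- function(traj, ion, protein_atoms = NULL,
                                minimum_image = !is.null(traj$box)) {
  top <- traj$topology
  if (is.null(protein_atoms)) {
    prot_res <- top$residues$residue_index[
      is_protein_residue(top$residues$residue_name)]
    protein_atoms <- top$atoms$atom_id[
      top$atoms$is_heavy & top$atoms$residue_index %in% prot_res &
        !(top$atoms$atom_id %in% ion$atom_ids)]
  } else {
    heavy <- top$atoms$atom_id[top$atoms$is_heavy]
    protein_atoms <- intersect(protein_atoms, heavy)
  }
  if (!length(protein_atoms))
    stop_ib("no protein heavy atoms available for the distance series")
  n_fr <- n_frames(traj)
  box_t <- if (minimum_image && !is.null(traj$box)) t(traj$box) else NULL
  best <- rep(Inf, n_fr)
  best_atom <- rep(NA_integer_, n_fr)
  for (pa in protein_atoms) {
    pc <- matrix(traj$coords[pa, , ], nrow = 3L)
    for (ia in ion$atom_ids) {
      d3 <- matrix(traj$coords[ia, , ], nrow = 3L) - pc
      if (!is.null(box_t)) d3 <- d3 - box_t * round(d3 / box_t)
      d <- sqrt(colSums(d3 * d3))
      upd <- d < best
      best[upd] <- d[upd]
      best_atom[upd] <- pa
    }
  }
  res_idx <- top$atoms$residue_index[best_atom]
  out <- data.frame(
    time_ns = traj$times / 1000,
    d_min = best,
    nearest_residue = res_idx,
    nearest_residue_name = top$residues$residue_name[
      match(res_idx, top$residues$residue_index)],
    stringsAsFactors = FALSE
  )
  class(out) <- c("distance_series", "data.frame")
  if (n_fr > 1L) attr(out, "dt") <- frame_dt(traj) / 1000
  out
}

#' Distance density and contact probability
#'
#' Normalised histogram of the minimum-distance series (it integrates to 1)
#' plus the probability of the ion being found within a contact cutoff.
#'
#' @param series a `distance_series` from [min_distance_series()].
#' @param bin_width histogram bin width (Angstrom).
#' @param cutoff contact cutoff (Angstrom) for the reported probability.
#' @return list with `breaks`, `mids`, `density` (1/Angstrom),
#'   `contact_probability` and `cutoff`.
#' @export
distance_density <- function(series, bin_width = 0.05, cutoff = 2.75) {
  if (!nrow(series)) stop_ib("empty distance series")
  check_number(bin_width, "bin_width", lower = 0, strict = TRUE)
  d <- series$d_min
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, mids = h$mids, density = h$density,
       contact_probability = mean(d <= cutoff), cutoff = cutoff)
}

# Brute-force oracle-style run scan shared by detect_binding_events: returns
# start/end frame indices of maximal runs of TRUE, merging gaps of up to
# `gap` FALSE frames.
contact_runs <- function(contact, gap = 0L) {
  r <- rle(contact)
  if (gap > 0L) {
    # absorb short FALSE runs flanked by TRUE runs
    v <- r$values
    l <- r$lengths
    absorb <- which(!v & l <= gap)
    absorb <- absorb[absorb > 1L & absorb < length(v)]
    v[absorb] <- TRUE
    r <- rle(inverse.rle(list(values = v, lengths = l)))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(i_start = starts[keep], i_end = ends[keep])
}

#' Detect binding events in a distance series
#'
#' A binding event is a maximal run of consecutive frames with minimum
#' ion-protein distance below `cutoff` (default 4 Angstrom). Runs shorter
#' than `min_duration` are dropped; the default is the two-frame rule,
#' `2 dt`. Durations follow the frame-count convention: a run of k frames
#' spans `k dt` (so the shortest admissible event at 0.2 ns sampling lasts
#' 0.4 ns).
#'
#' @param series a `distance_series` (uniform frame spacing required).
#' @param cutoff contact cutoff (Angstrom).
#' @param min_duration minimum event duration (ns); default `2 dt`.
#' @param gap number of above-cutoff frames tolerated inside an event
#'   (default 0: a single excursion ends the event).
#' @return A `binding_events` data.frame with columns `event`, `i_start`,
#'   `i_end` (frame indices), `t_start`, `t_end`, `t_b` (ns), `n_frames`,
#'   `residue` (modal nearest residue name) and list-column
#'   `residues_contacted`; frame spacing in attribute `dt`.
#' @export
detect_binding_events <- function(series, cutoff = 4.0, min_duration = NULL,
                                  gap = 0L) {
  stopifnot(inherits(series, "distance_series"))
  dt <- attr(series, "dt")
  if (is.null(dt)) {
    dts <- diff(series$time_ns)
    dt <- stats::median(dts)
    if (any(abs(dts - dt) > 1e-6 * dt))
      stop_ib("non-uniform frame spacing; resample upstream")
  }
  if (is.null(min_duration)) min_duration <- 2 * dt
  runs <- contact_runs(series$d_min < cutoff, gap = as.integer(gap))
  if (nrow(runs)) {
    runs$n_frames <- runs$i_end - runs$i_start + 1L
    runs$t_b <- runs$n_frames * dt
    runs <- runs[runs$t_b >= min_duration - 1e-12, , drop = FALSE]
  }
  if (!nrow(runs)) {
    out <- data.frame(event = integer(), i_start = integer(),
                      i_end = integer(), t_start = numeric(),
                      t_end = numeric(), t_b = numeric(),
                      n_frames = integer(), residue = character(),
                      stringsAsFactors = FALSE)
    out$residues_contacted <- list()
  } else {
    modal <- character(nrow(runs))
    contacted <- vector("list", nrow(runs))
    for (i in seq_len(nrow(runs))) {
      idx <- runs$i_start[i]:runs$i_end[i]
      in_contact <- idx[series$d_min[idx] < cutoff]
      nm <- series$nearest_residue_name[in_contact]
      modal[i] <- names(which.max(table(nm)))
      contacted[[i]] <- sort(unique(series$nearest_residue[in_contact]))
    }
    out <- data.frame(event = seq_len(nrow(runs)),
                      i_start = runs$i_start, i_end = runs$i_end,
                      t_start = series$time_ns[runs$i_start],
                      t_end = series$time_ns[runs$i_start] + runs$t_b,
                      t_b = runs$t_b, n_frames = runs$n_frames,
                      residue = modal, stringsAsFactors = FALSE)
    out$residues_contacted <- contacted
  }
  class(out) <- c("binding_events", "data.frame")
  attr(out, "dt") <- dt
  attr(out, "cutoff") <- cutoff
  out
}

#' Assign binding events to sites
#'
#' Each event is assigned to the site whose defining residues' heavy atoms
#' come within the site's `bound_cutoff` (default 3 Angstrom) of the ion for
#' the largest number of event frames; ties are broken by the smaller mean
#' ion-site distance, and events never within cutoff of any site get `NA`.
#'
#' @param events a `binding_events` data.frame (with frame indices).
#' @param traj the [trajectory()] the events were detected in.
#' @param ion the [ion_selection()].
#' @param sites list of [site_definition()].
#' @return `events` with a `site` column added.
#' @export
assign_site <- function(events, traj, ion, sites) {
  if (!length(sites)) stop_ib("no sites defined")
  n_fr <- n_frames(traj)
  # per-site per-frame min distance ion -> site residues' heavy atoms
  dsite <- matrix(Inf, nrow = n_fr, ncol = length(sites))
  box_t <- if (!is.null(traj$box)) t(traj$box) else NULL
  for (k in seq_along(sites)) {
    atoms <- site_heavy_atoms(traj$topology, sites[[k]]$residues)
    atoms <- setdiff(atoms, ion$atom_ids)
    for (pa in atoms) {
      pc <- matrix(traj$coords[pa, , ], nrow = 3L)
      for (ia in ion$atom_ids) {
        d3 <- matrix(traj$coords[ia, , ], nrow = 3L) - pc
        if (!is.null(box_t)) d3 <- d3 - box_t * round(d3 / box_t)
        dsite[, k] <- pmin(dsite[, k], sqrt(colSums(d3 * d3)))
      }
    }
  }
  site_names <- vapply(sites, `[[`, character(1L), "name")
  cutoffs <- vapply(sites, `[[`, numeric(1L), "bound_cutoff")
  events$site <- NA_character_
  for (i in seq_len(nrow(events))) {
    idx <- events$i_start[i]:events$i_end[i]
    within <- sweep(dsite[idx, , drop = FALSE], 2L, cutoffs, "<=")
    tallies <- colSums(within)
    if (all(tallies == 0L)) next
    best <- which(tallies == max(tallies))
    if (length(best) > 1L) {
      mean_d <- colMeans(dsite[idx, best, drop = FALSE])
      best <- best[which.min(mean_d)]
    }
    events$site[i] <- site_names[best[1L]]
  }
  events
}

#' Per-residue-type binding statistics
#'
#' Each event's binding partner is its modal nearest residue; fractions are
#' over events and sum to 1.
#'
#' @param events a `binding_events` data.frame.
#' @return data.frame with `residue_name`, `n_events`, `fraction`, sorted by
#'   decreasing fraction.
#' @export
residue_binding_stats <- function(events) {
  if (!nrow(events))
    return(data.frame(residue_name = character(), n_events = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  tab <- sort(table(events$residue), decreasing = TRUE)
  data.frame(residue_name = names(tab), n_events = as.integer(tab),
             fraction = as.numeric(tab) / nrow(events),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarise binding times by site and duration threshold
#'
#' Per site: total number of binding events and counts/percentages of events
#' with `t_b` at or above each threshold; plus an aggregate row with
#' percentages of the grand total. Percentages are rounded to one decimal
#' for report parity with published tables.
#'
#' @param events a `binding_events` data.frame with `site` and `t_b`.
#' @param thresholds duration thresholds (ns).
#' @return data.frame, one row per site plus an `"all"` aggregate row.
#' @export
binding_time_summary <- function(events, thresholds = c(1, 10, 100)) {
  sites <- sort(unique(stats::na.omit(events$site)))
  counts <- data.frame(site = as.character(sites),
                       total = integer(length(sites)),
                       stringsAsFactors = FALSE)
  for (th in thresholds)
    counts[[paste0("ge_", th, "ns")]] <- integer(length(sites))
  for (i in seq_along(sites)) {
    tb <- events$t_b[!is.na(events$site) & events$site == sites[i]]
    counts$total[i] <- length(tb)
    for (th in thresholds)
      counts[[paste0("ge_", th, "ns")]][i] <- sum(tb >= th)
  }
  binding_count_summary(counts, thresholds = thresholds)
}

#' Percentage summary from binding-event counts
#'
#' Turns a per-site table of binding-event counts into the standard summary
#' with per-site percentages and an aggregate row (percentages of the grand
#' total), rounded to one decimal. This is the arithmetic core behind
#' [binding_time_summary()] and works directly on published count tables.
#'
#' @param counts data.frame with columns `site`, `total` and one `ge_<t>ns`
#'   count column per threshold.
#' @param thresholds thresholds (ns) matching the count columns.
#' @return data.frame with `pct_ge_<t>ns` columns added and an `"all"` row.
#' @export
binding_count_summary <- function(counts, thresholds = c(1, 10, 100)) {
  counts <- as.data.frame(counts)
  cols <- paste0("ge_", thresholds, "ns")
  if (!all(c("site", "total", cols) %in% names(counts)))
    stop_ib("counts must have columns site, total, ",
            paste(cols, collapse = ", "))
  agg <- data.frame(site = "all", total = sum(counts$total),
                    stringsAsFactors = FALSE)
  for (cl in cols) agg[[cl]] <- sum(counts[[cl]])
  out <- rbind(counts[, c("site", "total", cols)], agg)
  for (cl in cols) {
    pct <- ifelse(out$total > 0, 100 * out[[cl]] / out$total, 0)
    out[[sub("^ge_", "pct_ge_", cl)]] <- round(pct, 1L)
  }
  out
}

#' Mean binding time
#'
#' The arithmetic mean of the event durations, which is the maximum
#' likelihood estimator of the inverse decay rate under an exponential
#' residence-time model.
#'
#' @param events a `binding_events` data.frame, or a numeric vector of
#'   durations (ns).
#' @return Mean binding time (ns).
#' @export
mean_binding_time <- function(events) {
  tb <- if (is.numeric(events)) events else events$t_b
  if (!length(tb)) stop_ib("no binding events")
  mean(tb)
}

#' Bound-fraction survival curve
#'
#' The fraction of initially bound configurations still bound after a lag
#' `t`: `f(t) = #\{t_b >= t\} / N`, evaluated at `t = 0` and on the sorted
#' distinct event durations.
#'
#' @param events a `binding_events` data.frame or numeric durations (ns).
#' @return A `survival_curve` data.frame with columns `t` (ns) and `f`.
#' @export
bound_fraction_curve <- function(events) {
  tb <- if (is.numeric(events)) events else events$t_b
  if (!length(tb)) stop_ib("no binding events")
  grid <- c(0, sort(unique(tb)))
  f <- vapply(grid, function(t) mean(tb >= t), numeric(1L))
  out <- data.frame(t = grid, f = f)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Fit a bi-exponential to a survival curve
#'
#' Nonlinear least squares of
#' `f(t) = a exp(-t/tau_fast) + (1 - a) exp(-t/tau_slow)` with `0 <= a <= 1`
#' and positive time constants, so `f(0) = 1` by construction. Deterministic
#' multi-start initialisation over a decade-spaced grid of time-constant
#' pairs; the best residual wins and near-ties go to the smaller
#' `tau_slow`. Amplitudes are ordered so `tau_slow >= tau_fast`.
#'
#' @param curve a `survival_curve` (>= 6 distinct time points).
#' @return An object of class `"biexp_fit"`: list with `a_fast`, `tau_fast`,
#'   `a_slow`, `tau_slow` (ns), `residual_norm` and `fitted` (function of t).
#' @export
fit_biexponential <- function(curve) {
  t <- curve$t
  f <- curve$f
  if (length(unique(t)) < 6L) stop_ib("need at least 6 distinct time points")
  pos <- t[t > 0]
  lo <- floor(log10(min(pos)))
  hi <- ceiling(log10(max(pos)))
  taus <- 10^seq(lo, hi)
  starts <- list()
  for (tf in taus) for (ts in taus) if (ts >= tf)
    starts[[length(starts) + 1L]] <- c(a = 0.8, tf = tf, ts = ts)
  best <- NULL
  best_rss <- Inf
  best_ts <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ a * exp(-t / tf) + (1 - a) * exp(-t / ts),
        data = data.frame(t = t, f = f), start = as.list(st),
        lower = c(a = 0, tf = 1e-9, ts = 1e-9),
        upper = c(a = 1, tf = Inf, ts = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    cf <- stats::coef(fit)
    ts_eff <- max(cf[["tf"]], cf[["ts"]])
    better <- rss < best_rss * (1 - 1e-9) ||
      (rss <= best_rss * (1 + 1e-9) && ts_eff < best_ts)
    if (better) {
      best <- cf
      best_rss <- rss
      best_ts <- ts_eff
    }
  }
  if (is.null(best))
    stop_ib("bi-exponential fit failed to converge from every start")
  a <- best[["a"]]
  tf <- best[["tf"]]
  ts <- best[["ts"]]
  if (tf > ts) {  # enforce tau_slow >= tau_fast
    tmp <- tf; tf <- ts; ts <- tmp
    a <- 1 - a
  }
  structure(list(a_fast = a, tau_fast = tf, a_slow = 1 - a, tau_slow = ts,
                 residual_norm = sqrt(best_rss),
                 fitted = function(t) a * exp(-t / tf) +
                   (1 - a) * exp(-t / ts)),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "<biexp_fit> a_fast = %.3f, tau_fast = %.3g ns; a_slow = %.3f, tau_slow = %.3g ns (|r| = %.2e)\n",
    x$a_fast, x$tau_fast, x$a_slow, x$tau_slow, x$residual_norm))
  invisible(x)
}

#' Binding hit rate
#'
#' @param n_events number of binding events.
#' @param total_time total simulated time (ns), > 0.
#' @return Events per ns.
#' @export
hit_rate <- function(n_events, total_time) {
  check_number(n_events, "n_events", lower = 0)
  check_number(total_time, "total_time", lower = 0, strict = TRUE)
  n_events / total_time
}

#' Escape-termination frame of a trajectory
#'
#' Finds the first frame at which an ion has escaped, under one of two
#' rules: `site_local` -- the ion separates by more than `cutoff` (default
#' 3 Angstrom) from the residues defining one designated site; `far_field`
#' -- the ion strays by more than `cutoff` (default 10 Angstrom) from the
#' residues of every site.
#'
#' @param traj a [trajectory()].
#' @param ion an [ion_selection()].
#' @param sites list of [site_definition()].
#' @param mode `"site_local"` or `"far_field"`.
#' @param site site name for `site_local` mode (default: first site).
#' @param cutoff escape distance (Angstrom); defaults 3 (site_local) or
#'   10 (far_field).
#' @return Integer frame index of the first escape frame, with attribute
#'   `triggered`; equals the last frame index when escape never occurs.
#' @export
escape_termination <- function(traj, ion, sites,
                               mode = c("site_local", "far_field"),
                               site = NULL, cutoff = NULL) {
  mode <- match.arg(mode)
  if (!length(sites)) stop_ib("no sites defined")
  if (is.null(cutoff)) cutoff <- if (mode == "site_local") 3 else 10
  n_fr <- n_frames(traj)
  box_t <- if (!is.null(traj$box)) t(traj$box) else NULL
  site_min_dist <- function(sdef) {
    atoms <- setdiff(site_heavy_atoms(traj$topology, sdef$residues),
                     ion$atom_ids)
    best <- rep(Inf, n_fr)
    for (pa in atoms) {
      pc <- matrix(traj$coords[pa, , ], nrow = 3L)
      for (ia in ion$atom_ids) {
        d3 <- matrix(traj$coords[ia, , ], nrow = 3L) - pc
        if (!is.null(box_t)) d3 <- d3 - box_t * round(d3 / box_t)
        best <- pmin(best, sqrt(colSums(d3 * d3)))
      }
    }
    best
  }
  if (mode == "site_local") {
    nm <- vapply(sites, `[[`, character(1L), "name")
    k <- if (is.null(site)) 1L else match(site, nm)
    if (is.na(k)) stop_ib("unknown site: ", site)
    escaped <- site_min_dist(sites[[k]]) > cutoff
  } else {
    dmin <- do.call(pmin, lapply(sites, site_min_dist))
    escaped <- dmin > cutoff
  }
  idx <- which(escaped)
  out <- if (length(idx)) idx[1L] else n_fr
  attr(out, "triggered") <- length(idx) > 0L
  out
}

#' Detect hydrogen bonds between donors and an ion
#'
#' Geometric criterion: donor-acceptor distance at or below `d_cut`
#' (default 3.5 Angstrom) and donor-H...acceptor angle (at the hydrogen) at
#' or above `angle_min` (default 120 degrees). Hydrogens are attached to a
#' donor when they belong to the same residue and lie within 1.25 Angstrom
#' of it in the first frame.
#'
#' @param traj a [trajectory()].
#' @param ion an [ion_selection()] (its atoms are the acceptors).
#' @param donor_atoms integer atom ids of the donor heavy atoms.
#' @param d_cut donor-acceptor distance cutoff (Angstrom).
#' @param angle_min minimum donor-H-acceptor angle (degrees).
#' @return data.frame with columns `frame`, `donor`, `hydrogen`, `acceptor`,
#'   `distance` (Angstrom), `angle` (degrees).
#' @export
detect_hydrogen_bonds <- function(traj, ion, donor_atoms, d_cut = 3.5,
                                  angle_min = 120) {
  top <- traj$topology
  hyd <- top$atoms$atom_id[!top$atoms$is_heavy]
  pairs <- list()
  for (d in donor_atoms) {
    res <- top$atoms$residue_index[top$atoms$atom_id == d]
    cand <- hyd[top$atoms$residue_index[match(hyd, top$atoms$atom_id)] == res]
    if (length(cand)) {
      dd <- row_norms(matrix(traj$coords[cand, , 1L], ncol = 3L) -
                        matrix(traj$coords[d, , 1L], ncol = 3L,
                               nrow = length(cand), byrow = TRUE))
      cand <- cand[dd <= 1.25]
    }
    if (!length(cand))
      stop_ib("donor atom ", d, " has no attached hydrogen")
    for (h in cand) pairs[[length(pairs) + 1L]] <- c(d, h)
  }
  out <- list()
  for (fr in seq_len(n_frames(traj))) {
    for (p in pairs) {
      dpos <- traj$coords[p[1L], , fr]
      hpos <- traj$coords[p[2L], , fr]
      for (a in ion$atom_ids) {
        apos <- traj$coords[a, , fr]
        dist_da <- sqrt(sum((apos - dpos)^2))
        if (dist_da > d_cut) next
        v1 <- dpos - hpos
        v2 <- apos - hpos
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang >= angle_min)
          out[[length(out) + 1L]] <- data.frame(
            frame = fr, donor = p[1L], hydrogen = p[2L], acceptor = a,
            distance = dist_da, angle = ang)
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), donor = integer(),
                      hydrogen = integer(), acceptor = integer(),
                      distance = numeric(), angle = numeric()))
  do.call(rbind, out)
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation, with explicit validation (equal
#' lengths of at least 3, non-zero variance). Used to test for association
#' between binding times and rotational correlation times.
#'
#' @param x,y numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_ib("x and y must have equal length")
  if (length(x) < 3L) stop_ib("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_ib("zero variance in x or y")
  stats::cor(x, y)
}
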