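#' Classify ion frames as bound, bulk or intermediate
#'
#' Frames with minimum ion-protein distance at or below `bound_cutoff`
#' (default 3 Angstrom) are `"bound"`; frames at or beyond `bulk_cutoff`
#' (default 10 Angstrom) are `"bulk"`; everything in between is
#' `"intermediate"` and excluded from state-resolved solvation averages.
#'
#' @param d_min numeric vector of minimum distances (Angstrom), or a
#'   `distance_series`.
#' @param bound_cutoff,bulk_cutoff state cutoffs (Angstrom).
#' @return Character vector of states per frame.
#' @export
classify_ion_state <- function(d_min, bound_cutoff = 3.0, bulk_cutoff = 10.0) {
  if (inherits(d_min, "distance_series")) d_min <- d_min$d_min
  ifelse(d_min <= bound_cutoff, "bound",
         ifelse(d_min >= bulk_cutoff, "bulk", "intermediate"))
}

#' Ion-water radial distribution function
#'
#' Standard pair-distribution estimator: per selected frame, the histogram
#' of ion-water distances (minimum image when a box is given) normalised by
#' the spherical shell volume `4 pi r^2 dr` and a reference water density.
#' For a diatomic ion the distance to a water is taken from the closer of
#' the ion's two atoms (set `midpoint = TRUE` for the bond midpoint
#' instead). The cumulative water count n(r) is the running total of
#' histogram counts per frame, so `n(r_max)` equals the mean number of
#' waters within `r_max` exactly.
#'
#' @param ion_pos ion coordinates: an n_frames x 3 matrix, or a list (one
#'   element per frame) of `n_ion_atoms x 3` matrices for diatomic ions.
#' @param waters list (one element per frame) of `m x 3` water-oxygen
#'   coordinate matrices, or a single matrix for one frame.
#' @param mask optional logical/index vector selecting frames (e.g. from
#'   [classify_ion_state()]).
#' @param bin_width histogram bin (Angstrom), default 0.05.
#' @param r_max profile range (Angstrom).
#' @param box optional length-3 box for minimum-image distances.
#' @param density reference water density (waters/Angstrom^3); default is
#'   measured from the data (box volume when a box is given, otherwise the
#'   `r_max` sphere).
#' @param state label stored on the profile (`"bound"`, `"bulk"`, `"all"`).
#' @param midpoint use the diatomic bond midpoint instead of the
#'   closest-atom convention.
#' @return An `rdf_profile` data.frame with columns `r` (bin centres), `g`
#'   and `n` (cumulative waters); attributes `density`, `state`,
#'   `bin_width`, `n_frames`.
#' @export
rdf_profile <- function(ion_pos, waters, mask = NULL, bin_width = 0.05,
                        r_max = 10, box = NULL, density = NULL,
                        state = "all", midpoint = FALSE) {
  check_number(bin_width, "bin_width", lower = 0, strict = TRUE)
  check_number(r_max, "r_max", lower = 0, strict = TRUE)
  if (is.matrix(waters)) waters <- list(waters)
  if (is.matrix(ion_pos) && !is.list(ion_pos)) {
    ion_pos <- lapply(seq_len(nrow(ion_pos)), function(i)
      ion_pos[i, , drop = FALSE])
  }
  if (length(ion_pos) != length(waters))
    stop_ib("ion_pos and waters must cover the same frames")
  frames <- seq_along(waters)
  if (!is.null(mask)) frames <- frames[mask]
  if (!length(frames)) stop_ib("no frames selected by the state mask")
  if (all(vapply(frames, function(f) nrow(waters[[f]]), integer(1L)) == 0L))
    stop_ib("no waters in the selected frames")
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1L)
  total_waters <- 0
  for (f in frames) {
    w <- waters[[f]]
    if (!nrow(w)) next
    ip <- ion_pos[[f]]
    if (is.null(dim(ip))) ip <- matrix(ip, ncol = 3L)
    if (midpoint && nrow(ip) == 2L) ip <- matrix(colMeans(ip), ncol = 3L)
    d <- do.call(pmin, lapply(seq_len(nrow(ip)), function(k) {
      d3 <- sweep(w, 2L, ip[k, ])
      if (!is.null(box)) d3 <- min_image(d3, box)
      row_norms(d3)
    }))
    idx <- findInterval(d[d < r_max], breaks, left.open = TRUE)
    idx[idx == 0L] <- 1L  # a water exactly at the reference point
    counts <- counts + tabulate(idx, nbins = length(counts))
    total_waters <- total_waters + nrow(w)
  }
  n_used <- length(frames)
  if (is.null(density)) {
    density <- if (!is.null(box)) (total_waters / n_used) / prod(box)
    else (sum(counts) / n_used) / (4 / 3 * pi * r_max^3)
  }
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  shell_vol <- 4 / 3 * pi * diff(breaks^3)
  g <- (counts / n_used) / (shell_vol * density)
  out <- data.frame(r = mids, g = g, n = cumsum(counts) / n_used)
  class(out) <- c("rdf_profile", "data.frame")
  attr(out, "density") <- density
  attr(out, "state") <- state
  attr(out, "bin_width") <- bin_width
  attr(out, "n_frames") <- n_used
  out
}

# Centered moving average; window forced odd; edges keep raw values.
smooth_profile <- function(g, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L) return(g)
  sm <- stats::filter(g, rep(1 / window, window), sides = 2L)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- g[is.na(sm)]
  sm
}

# Indices of local minima and maxima of a numeric vector, plateau-aware
# (a flat run counts once, at its midpoint).
local_extrema <- function(y) {
  d <- diff(y)
  s <- sign(d)
  # carry the previous non-zero slope sign through plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  ch <- which(diff(s) != 0)  # slope sign changes between i and i+1
  mins <- integer()
  maxs <- integer()
  for (i in ch) {
    if (s[i] != 0 && s[i + 1L] != 0) {
      # plateau-aware position: midpoint of the flat stretch ending here
      j <- i + 1L
      k <- j
      while (k > 1L && y[k - 1L] == y[j]) k <- k - 1L
      pos <- as.integer(round((k + j) / 2))
      if (s[i] < 0 && s[i + 1L] > 0) mins <- c(mins, pos)
      if (s[i] > 0 && s[i + 1L] < 0) maxs <- c(maxs, pos)
    }
  }
  list(minima = mins, maxima = maxs)
}

#' Solvation-shell boundaries from an RDF
#'
#' Shell boundaries are the local minima of the (moving-average smoothed)
#' g(r) that follow the first maximum; the first `n_shells` are returned.
#'
#' @param profile an `rdf_profile`.
#' @param n_shells number of boundaries wanted.
#' @param smooth_window moving-average window in bins (1 = off).
#' @return Numeric vector of boundary radii (Angstrom, bin centres).
#' @export
shell_boundaries <- function(profile, n_shells = 2L, smooth_window = 5L) {
  g <- smooth_profile(profile$g, smooth_window)
  ex <- local_extrema(g)
  if (!length(ex$maxima))
    stop_ib("no maxima found in g(r); found 0 of ", n_shells,
            " required minima")
  mins <- ex$minima[ex$minima > ex$maxima[1L]]
  if (length(mins) < n_shells)
    stop_ib("found only ", length(mins), " of ", n_shells,
            " required minima in g(r)")
  profile$r[mins[seq_len(n_shells)]]
}

#' Shell-resolved water counts for bound and bulk states
#'
#' Applies one set of shell boundaries to the cumulative water counts of a
#' bound-state and a bulk-state RDF and reports per-shell water numbers and
#' the waters shed upon binding (`n_bulk - n_bound`, at one decimal in the
#' `shed` column).
#'
#' @param bound,bulk `rdf_profile` objects for the two states.
#' @param boundaries increasing boundary radii (Angstrom) within both
#'   profiles' ranges.
#' @return A `shell_table` data.frame with `shell`, `r_shell`, `n_bulk`,
#'   `n_bound`, `shed`.
#' @export
shell_water_counts <- function(bound, bulk, boundaries) {
  if (is.unsorted(boundaries, strictly = TRUE))
    stop_ib("boundaries must be strictly increasing")
  for (p in list(bound, bulk)) {
    if (max(boundaries) > max(p$r) || min(boundaries) < min(p$r))
      stop_ib("boundary outside the profile range [",
              signif(min(p$r), 3), ", ", signif(max(p$r), 3), "]")
  }
  cum_at <- function(p) stats::approx(p$r, p$n, xout = boundaries,
                                      rule = 2L)$y
  nb <- diff(c(0, cum_at(bulk)))
  no <- diff(c(0, cum_at(bound)))
  out <- data.frame(shell = seq_along(boundaries), r_shell = boundaries,
                    n_bulk = nb, n_bound = no, shed = round(nb - no, 1L))
  class(out) <- c("shell_table", "data.frame")
  out
}
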