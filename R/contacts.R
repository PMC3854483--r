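#' Per-residue contact stability
#'
#' Percentage of trajectory frames in which each peptide residue touches the
#' nanomaterial: a residue is in contact in a frame when the distance
#' between any of its atoms and any surface atom is strictly below
#' `cutoff` (4 Angstrom by default, capturing van der Waals contact).
#'
#' @param traj a [trajectory()] with residues defined.
#' @param surface a `nanomaterial`, an [atom_set()], or an integer vector of
#'   atom indices into the trajectory designating the surface atoms.
#' @param cutoff contact distance in Angstrom (strict inequality).
#' @return A data frame of class `"contact_stability"` with columns
#'   `residue` and `stability` (percent of frames, 0-100).
#' @export
contact_stability <- function(traj, surface, cutoff = 4.0) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 1L) stop("empty trajectory")
  if (is.null(traj$residues) || !length(traj$residues))
    stop("trajectory has no residue definitions")
  surf_static <- NULL; surf_idx <- NULL
  if (inherits(surface, "nanomaterial")) surf_static <- surface$atoms$coords
  else if (inherits(surface, "atom_set")) surf_static <- surface$coords
  else surf_idx <- as.integer(surface)
  nf <- n_frames(traj)
  res <- traj$residues
  hits <- stats::setNames(numeric(length(res)), names(res))
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    surf <- if (is.null(surf_idx)) surf_static else co[surf_idx, , drop = FALSE]
    for (r in seq_along(res)) {
      d <- min_pair_dist(co[res[[r]], , drop = FALSE], surf,
                         traj$cell, traj$periodic)
      if (d < cutoff) hits[r] <- hits[r] + 1
    }
  }
  out <- data.frame(residue = names(res), stability = 100 * hits / nf,
                    row.names = NULL)
  class(out) <- c("contact_stability", "data.frame")
  out
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic probe-sphere SASA: each atom is dressed with a fixed
#' Fibonacci-lattice point set on its solvent-exposed sphere (van der Waals
#' radius + probe radius) and the accessible fraction is the share of
#' points not buried inside any neighbouring atom's sphere.  Bondi radii
#' are used (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Angstrom).
#'
#' @param atoms an [atom_set()].
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points sphere points per atom (default 960).
#' @return Numeric vector of per-atom accessible areas (Angstrom^2).
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(atoms, "atom_set"), probe >= 0, n_points >= 16L)
  co <- atoms$coords
  n <- nrow(co)
  rad <- vdw_radius(atoms$element) + probe
  sph <- .fibonacci_sphere(n_points)
  areas <- numeric(n)
  # neighbour search radius: two largest dressed radii
  rmax <- max(rad)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(co) - co[i, ])^2))
    nb <- which(d < rad[i] + rmax & seq_len(n) != i)
    nb <- nb[d[nb] < rad[i] + rad[nb]]
    pts <- sweep(sph * rad[i], 2, co[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- colSums((t(pts) - co[j, ])^2)
        free <- free & dj2 > rad[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    areas[i] <- 4 * pi * rad[i]^2 * frac
  }
  areas
}

# deterministic Fibonacci lattice on the unit sphere
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Buried contact area between peptide and surface
#'
#' Half the solvent-accessible surface area lost upon complex formation:
#' `(SASA(peptide) + SASA(surface) - SASA(complex)) / 2`.  This buried-SASA
#' realisation is the package's definition of the peptide-nanomaterial
#' contact area.
#'
#' @param peptide,surface disjoint [atom_set()]s.
#' @param probe probe radius in Angstrom.
#' @param n_points sphere points per atom for the SASA evaluation.
#' @return Buried contact area in Angstrom^2.
#' @export
buried_contact_area <- function(peptide, surface, probe = 1.4,
                                n_points = 960L) {
  stopifnot(inherits(peptide, "atom_set"), inherits(surface, "atom_set"))
  if (min_pair_dist(peptide$coords, surface$coords) < 1e-6)
    stop("overlapping atoms between peptide and surface")
  a <- sum(sasa(peptide, probe, n_points))
  b <- sum(sasa(surface, probe, n_points))
  both <- combine_atoms(peptide, surface)
  ab <- sum(sasa(both, probe, n_points))
  (a + b - ab) / 2
}

#' Radial distribution function
#'
#' g(r) between two atom groups over a trajectory with a periodic cell:
#' the histogram of A-B minimum-image distances normalised by the
#' ideal-gas shell count at the B-group number density, so that
#' uncorrelated groups give g(r) = 1.
#'
#' @param traj a [trajectory()] with a periodic cell (all three axes).
#' @param group_a,group_b atom index vectors of the two groups.
#' @param r_max histogram range in Angstrom; must not exceed half the
#'   smallest cell dimension.
#' @param bin_width histogram bin width in Angstrom.
#' @return A data frame of class `"rdf"` with columns `r` (bin centres),
#'   `g`, and `count` (raw pair counts per bin).
#' @export
rdf <- function(traj, group_a, group_b, r_max, bin_width = 0.1) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$cell) || !all(traj$periodic))
    stop("rdf requires a fully periodic cell for density normalisation")
  if (r_max > min(traj$cell) / 2)
    stop("'r_max' exceeds half the smallest cell dimension")
  group_a <- as.integer(group_a); group_b <- as.integer(group_b)
  if (!length(group_a) || !length(group_b)) stop("empty atom group")
  nf <- n_frames(traj)
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1L)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    d <- pair_dist(co[group_a, , drop = FALSE], co[group_b, , drop = FALSE],
                   traj$cell, traj$periodic)
    d <- d[d > 1e-9 & d <= r_max]      # drop self pairs, clip range
    counts <- counts + .bin_counts(d, breaks)
  }
  vol <- prod(traj$cell)
  rho_b <- length(group_b) / vol
  shell <- 4 / 3 * pi * diff(breaks^3)
  ideal <- shell * rho_b * length(group_a) * nf
  g <- counts / ideal
  out <- data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    g = g, count = counts)
  class(out) <- c("rdf", "data.frame")
  out
}

.bin_counts <- function(x, breaks) {
  if (!length(x)) return(numeric(length(breaks) - 1L))
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, left.open = TRUE)
  idx[idx < 1L] <- 1L
  tabulate(idx, nbins = length(breaks) - 1L)
}

#' @export
plot.rdf <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (Å)", ylab = "g(r)",
                 ...)
  graphics::abline(h = 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Per-residue root-mean-square fluctuation
#'
#' After optionally superposing every frame onto the first (Kabsch rigid
#' fit over all atoms), computes for each atom the mean squared deviation
#' from its time-averaged position, and reports per residue the square root
#' of the atom-averaged mean squared fluctuation.
#'
#' @param traj a [trajectory()] with at least two frames and residues
#'   defined.
#' @param superpose superpose frames onto the first before measuring
#'   fluctuations (default TRUE).
#' @return A data frame of class `"rmsf"` with columns `residue` and
#'   `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L)
    stop("rmsf needs at least two frames")
  if (is.null(traj$residues) || !length(traj$residues))
    stop("trajectory has no residue definitions")
  ref <- frame_coords(traj, 1)
  frames <- lapply(seq_len(n_frames(traj)), function(f) {
    co <- frame_coords(traj, f)
    if (superpose && f > 1L) co <- kabsch_superpose(co, ref) else co
  })
  arr <- simplify2array(frames)                     # n x 3 x nf
  avg <- apply(arr, c(1, 2), mean)
  msf <- rowMeans(apply(arr, 3, function(co) rowSums((co - avg)^2)))
  res <- traj$residues
  val <- vapply(res, function(idx) sqrt(mean(msf[idx])), numeric(1))
  out <- data.frame(residue = names(res), rmsf = unname(val),
                    row.names = NULL)
  class(out) <- c("rmsf", "data.frame")
  out
}
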