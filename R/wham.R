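## Energy units and constants ------------------------------------------------

.kB_kcal <- 0.0019872041   # Boltzmann constant, kcal/mol/K
.kj_per_kcal <- 4.184

#' Energy unit conversion
#'
#' Exact conversion between kJ/mol and kcal/mol (factor 4.184).
#'
#' @param x energy value(s).
#' @return Converted value(s).
#' @export
kj_to_kcal <- function(x) x / .kj_per_kcal

#' @rdname kj_to_kcal
#' @export
kcal_to_kj <- function(x) x * .kj_per_kcal

## Umbrella windows -----------------------------------------------------------

#' Umbrella-sampling window
#'
#' One biased simulation window along the reaction coordinate: the harmonic
#' bias centre, the spring force constant (given in kJ mol^-1 nm^-2, the
#' conventional unit for pulling force constants; 8000 kJ mol^-1 nm^-2 by
#' default) and the sampled reaction-coordinate values in Angstrom.
#'
#' @param center bias centre in Angstrom.
#' @param samples numeric vector of reaction-coordinate samples (Angstrom).
#' @param force_constant spring constant in kJ mol^-1 nm^-2.
#' @return An object of class `"umbrella_window"`.  The field
#'   `k_kcal_A2` holds the force constant converted to kcal mol^-1 A^-2.
#' @export
umbrella_window <- function(center, samples, force_constant = 8000) {
  samples <- as.numeric(samples)
  if (!length(samples) || !all(is.finite(samples)))
    stop("'samples' must be a non-empty finite numeric vector")
  if (!is.finite(force_constant) || force_constant < 0)
    stop("'force_constant' must be non-negative")
  structure(list(center = as.numeric(center), samples = samples,
                 force_constant = force_constant,
                 k_kcal_A2 = kj_to_kcal(force_constant) / 100),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window> centre %.2f A, k = %g kJ/mol/nm^2, %d samples (mean %.2f A)\n",
              x$center, x$force_constant, length(x$samples),
              mean(x$samples)))
  invisible(x)
}

#' Reaction coordinate: nanomaterial COM to glycine alpha-carbon
#'
#' The umbrella-sampling reaction coordinate: the Euclidean distance
#' between the mass-weighted centre of mass of the nanomaterial and the
#' alpha-carbon of the glycine residue of the peptide.
#'
#' @param frame an [atom_set()] holding (at least) the nanomaterial and the
#'   peptide.
#' @param surface_ids atom indices of the nanomaterial within `frame`.
#' @param gly_ca_id atom index of the glycine alpha-carbon.
#' @return Distance in Angstrom.
#' @export
reaction_coordinate <- function(frame, surface_ids, gly_ca_id) {
  stopifnot(inherits(frame, "atom_set"))
  surface_ids <- as.integer(surface_ids)
  gly_ca_id <- as.integer(gly_ca_id)
  n <- n_atoms(frame)
  if (length(gly_ca_id) != 1L || is.na(gly_ca_id) ||
      gly_ca_id < 1L || gly_ca_id > n)
    stop("glycine alpha-carbon selection does not resolve to one atom")
  if (!length(surface_ids) || any(surface_ids < 1L | surface_ids > n))
    stop("surface atom selection out of range")
  com <- centre_of_mass(frame, surface_ids)
  sqrt(sum((frame$coords[gly_ca_id, ] - com)^2))
}

## WHAM -----------------------------------------------------------------------

#' Solve the WHAM equations for a potential of mean force
#'
#' Combines biased histograms from a set of umbrella windows into one
#' unbiased free-energy profile by iterating the standard WHAM
#' self-consistency equations: the unbiased probability of bin b is
#' \deqn{p_b = \frac{\sum_i h_{ib}}{\sum_i N_i e^{-\beta (w_{ib} - g_i)}},
#'   \quad e^{-\beta g_i} = \sum_b p_b e^{-\beta w_{ib}},}
#' where \eqn{w_{ib}} is window i's harmonic bias evaluated at bin centre
#' b.  Iteration stops when the largest change in any window free-energy
#' constant \eqn{g_i} falls below `tol`.  The PMF is \eqn{-k_B T \ln p}
#' zeroed at its minimum, the bound (associated) state.
#'
#' A histogram-overlap diagnostic between adjacent windows (see
#' [window_overlap()]) is computed; non-overlapping adjacent windows
#' trigger a warning and are flagged on the returned profile.
#'
#' @param windows list of [umbrella_window()] objects (at least two for a
#'   composite profile; a single unbiased window degenerates to direct
#'   Boltzmann inversion of its histogram).
#' @param bin_width histogram bin width in Angstrom (default 0.1).
#' @param temperature temperature in Kelvin (default 300).
#' @param tol convergence tolerance on the window free-energy constants,
#'   kcal/mol (default 1e-7).
#' @param max_iter maximum number of WHAM iterations.
#' @return An object of class `"pmf_profile"`: `bin_centers` (Angstrom),
#'   `free_energy` (kcal/mol, zeroed at the minimum; `Inf` in unpopulated
#'   bins), `prob`, `counts`, `converged`, `iterations`, `overlap`
#'   (adjacent-window overlap fractions) and `temperature`.
#' @export
wham_solve <- function(windows, bin_width = 0.1, temperature = 300,
                       tol = 1e-7, max_iter = 1e5) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  stopifnot(length(windows) >= 1L,
            all(vapply(windows, inherits, logical(1), "umbrella_window")))
  beta <- 1 / (.kB_kcal * temperature)
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  lo <- min(all_s); hi <- max(all_s)
  breaks <- seq(floor(lo / bin_width) * bin_width,
                ceiling(hi / bin_width) * bin_width, by = bin_width)
  if (length(breaks) < 2L) breaks <- c(breaks, breaks + bin_width)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nb <- length(mids); nw <- length(windows)

  H <- vapply(windows, function(w) .bin_counts(w$samples, breaks),
              numeric(nb))                          # nb x nw
  N <- colSums(H)
  h <- rowSums(H)
  pop <- h > 0

  # bias energies at bin centres, kcal/mol
  W <- vapply(windows, function(w)
    0.5 * w$k_kcal_A2 * (mids - w$center)^2, numeric(nb))
  EW <- exp(-beta * W)                              # nb x nw, may underflow to 0

  overlap <- if (nw >= 2L) window_overlap(windows, bin_width) else numeric(0)
  if (length(overlap) && any(overlap == 0))
    warning("non-overlapping adjacent umbrella windows; PMF may be unreliable")

  g <- numeric(nw)                                  # free-energy constants
  converged <- FALSE
  it <- 0L
  p <- rep(0, nb)
  while (it < max_iter) {
    it <- it + 1L
    den <- drop(EW %*% (N * exp(beta * g)))         # sum_i N_i e^{beta g_i} e^{-beta w}
    p <- ifelse(pop & den > 0, h / den, 0)
    p <- p / sum(p)
    z <- drop(crossprod(EW, p))                     # sum_b p_b e^{-beta w_ib}
    gnew <- -log(z) / beta
    gnew <- gnew - gnew[1]
    delta <- max(abs(gnew - g))
    g <- gnew
    if (delta < tol) { converged <- TRUE; break }
  }
  fe <- ifelse(p > 0, -log(p) / beta, Inf)
  fe <- fe - min(fe[is.finite(fe)])
  structure(list(bin_centers = mids, free_energy = fe, prob = p,
                 counts = h, converged = converged, iterations = it,
                 overlap = overlap, temperature = temperature,
                 bin_width = bin_width),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  rng <- range(x$bin_centers[x$counts > 0])
  cat(sprintf("<pmf_profile> %d bins over [%.2f, %.2f] A at %d K; %s after %d iterations\n",
              length(x$bin_centers), rng[1], rng[2], x$temperature,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  fin <- is.finite(x$free_energy)
  cat(sprintf("  free energy range: 0 to %.2f kcal/mol\n",
              max(x$free_energy[fin])))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  fin <- is.finite(x$free_energy)
  graphics::plot(x$bin_centers[fin], x$free_energy[fin], type = "l",
                 xlab = "separation d (Å)",
                 ylab = "free energy (kcal/mol)", ...)
  invisible(x)
}

#' Dissociation free energy from a PMF
#'
#' The free energy required to take the complex from its associated
#' minimum (the zero of the profile) to full separation, estimated as the
#' mean free energy over the final `plateau_span` Angstrom of the sampled
#' profile.
#'
#' @param pmf a converged `"pmf_profile"` from [wham_solve()].
#' @param plateau_span length of the terminal plateau to average over,
#'   Angstrom (default 2).
#' @return Dissociation free energy in kcal/mol.
#' @export
dissociation_free_energy <- function(pmf, plateau_span = 2.0) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (!pmf$converged)
    stop("refusing to evaluate an unconverged PMF")
  pop <- pmf$counts > 0 & is.finite(pmf$free_energy)
  xs <- pmf$bin_centers[pop]
  fs <- pmf$free_energy[pop]
  hi <- max(xs)
  sel <- xs >= hi - plateau_span
  if (!any(sel)) stop("terminal plateau is not populated")
  mean(fs[sel])
}

#' Binding energy of a peptide-nanomaterial complex
#'
#' Combination of single-point total energies:
#' `E_b = E_complex - E_peptide - E_nanomaterial`.  All three energies must
#' be in the same unit; the result carries that unit.
#'
#' @param e_complex,e_peptide,e_nanomaterial total energies, or a single
#'   list/vector with fields `e_complex`, `e_peptide`, `e_nanomaterial`
#'   passed as the first argument.
#' @return Binding energy (negative = favourable binding).
#' @export
binding_energy <- function(e_complex, e_peptide = NULL,
                           e_nanomaterial = NULL) {
  if (is.null(e_peptide) && (is.list(e_complex) ||
                             length(e_complex) == 3L)) {
    e <- e_complex
    e_complex <- e[["e_complex"]]
    e_peptide <- e[["e_peptide"]]
    e_nanomaterial <- e[["e_nanomaterial"]]
  }
  vals <- c(e_complex, e_peptide, e_nanomaterial)
  if (length(vals) != 3L || !all(is.finite(vals)))
    stop("three finite energies are required")
  e_complex - e_peptide - e_nanomaterial
}

#' Histogram overlap between adjacent umbrella windows
#'
#' For each adjacent pair of windows (ordered by bias centre) computes the
#' intersection of their normalised sample histograms on a common grid:
#' 1 for identical distributions, 0 for disjoint supports.
#'
#' @param windows list of [umbrella_window()] objects (>= 2).
#' @param bin_width histogram bin width in Angstrom.
#' @return Numeric vector of length `length(windows) - 1` of overlap
#'   fractions in \[0, 1\].
#' @export
window_overlap <- function(windows, bin_width = 0.1) {
  stopifnot(length(windows) >= 2L)
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  windows <- windows[ord]
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  breaks <- seq(floor(min(all_s) / bin_width) * bin_width,
                ceiling(max(all_s) / bin_width) * bin_width, by = bin_width)
  if (length(breaks) < 2L) breaks <- c(breaks, breaks + bin_width)
  P <- vapply(windows, function(w) {
    cts <- .bin_counts(w$samples, breaks)
    cts / sum(cts)
  }, numeric(length(breaks) - 1L))
  vapply(seq_len(ncol(P) - 1L), function(i)
    sum(pmin(P[, i], P[, i + 1L])), numeric(1))
}
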