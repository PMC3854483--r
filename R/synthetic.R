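#' Pose specification for a synthetic aromatic ring
#'
#' Describes how a 6-carbon phenyl ring is posed relative to a hexagonal
#' ring of the nanomaterial surface, together with the stacking label the
#' pose is guaranteed to produce under the default [stacking_params()].
#' The constructor *verifies* that the parameters force the requested
#' label, with safety margins large enough that the small coordinate
#' jitter added by [synth_adsorption_trajectory()] (sigma <= 0.05
#' Angstrom) cannot flip the classification:
#'
#' * `FACE_TO_FACE`: height in \[3.2, 3.8\], tilt <= 22 deg, shift <= 0.55;
#' * `OFFSET`: height in \[3.2, 3.8\], tilt <= 22 deg, shift in
#'   \[0.85, 1.15\];
#' * `NONE`: height >= 5.5 with tilt <= 22 (out of contact), or tilt >= 40
#'   with height in \[3.0, 4.2\] (over-tilted).
#'
#' @param target_state `"NONE"`, `"OFFSET"` or `"FACE_TO_FACE"`.
#' @param height centroid height above the surface-ring centroid along its
#'   outward normal, Angstrom.
#' @param lateral_shift in-plane centroid displacement, Angstrom.
#' @param tilt ring-plane tilt relative to the surface ring, degrees.
#' @param azimuth direction (degrees) of the lateral shift in the surface
#'   ring plane; also sets the tilt axis (perpendicular to the shift).
#' @param ring optional index of the surface ring to pose over (must be
#'   hexagonal); chosen automatically when `NULL`.
#' @return An object of class `"pose_spec"`.
#' @export
pose_spec <- function(target_state, height, lateral_shift = 0, tilt = 0,
                      azimuth = 0, ring = NULL) {
  target_state <- match.arg(target_state, .stack_states)
  ok <- switch(target_state,
    FACE_TO_FACE = height >= 3.2 && height <= 3.8 && tilt <= 22 &&
      lateral_shift <= 0.55,
    OFFSET = height >= 3.2 && height <= 3.8 && tilt <= 22 &&
      lateral_shift >= 0.85 && lateral_shift <= 1.15,
    NONE = (height >= 5.5 && tilt <= 22 && lateral_shift <= 1.15) ||
      (tilt >= 40 && tilt <= 90 && height >= 3.0 && height <= 4.2 &&
         lateral_shift <= 1.15))
  if (!ok)
    stop("inconsistent pose spec: parameters do not force state ",
         target_state)
  structure(list(target_state = target_state, height = height,
                 lateral_shift = lateral_shift, tilt = tilt,
                 azimuth = azimuth, ring = ring),
            class = "pose_spec")
}

# kind-specific outward normal of a surface ring and in-plane frame
.ring_frame <- function(surface, idx) {
  r <- surface$rings[[idx]]
  n <- r$normal
  out_dir <- switch(surface$kind,
    fullerene = r$centroid,
    nanotube = c(r$centroid[1], r$centroid[2], 0),
    graphene = c(0, 0, 1),
    r$normal)
  if (sum(out_dir^2) > 1e-12 && sum(n * out_dir) < 0) n <- -n
  u <- r$coords[1, ] - r$centroid
  u <- u - sum(u * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(centroid = r$centroid, n = n, u = u, v = v)
}

# default anchor hexagon of a surface: the hexagonal ring nearest a
# kind-specific anchor point (top of C60, +x flank of the tube at
# mid-height, centre of the graphene sheet)
.anchor_hexagon <- function(surface, exclude = integer(0), min_sep = 0) {
  sizes <- vapply(surface$rings, function(r) r$size, integer(1))
  hex <- setdiff(which(sizes == 6L), exclude)
  cen <- ring_centroids(surface)
  anchor <- switch(surface$kind,
    fullerene = c(0, 0, max(cen[, 3]) + 1),
    nanotube = c(max(cen[, 1]) + 1, 0, mean(range(cen[, 3]))),
    graphene = c(surface$atoms$cell[1] / 2, surface$atoms$cell[2] / 2, 0),
    colMeans(cen))
  if (min_sep > 0 && length(exclude)) {
    ok <- vapply(hex, function(i) all(sqrt(rowSums(
      (cen[exclude, , drop = FALSE] -
         matrix(cen[i, ], length(exclude), 3, byrow = TRUE))^2)) >= min_sep),
      logical(1))
    hex <- hex[ok]
  }
  d <- sqrt(rowSums((cen[hex, , drop = FALSE] -
                       matrix(anchor, length(hex), 3, byrow = TRUE))^2))
  hex[which.min(d)]
}

#' Pose a synthetic phenyl ring over a nanomaterial surface
#'
#' Places a regular 6-carbon hexagon (C-C 1.39 Angstrom) at the height,
#' lateral shift and tilt requested by a [pose_spec()], relative to a
#' hexagonal surface ring, and returns it together with the stacking label
#' the pose parameters force.  The label is ground truth by construction
#' (the spec constructor rejects parameter combinations that do not force
#' it), so the output serves as an independent oracle for
#' [classify_ring()].
#'
#' @param surface a `nanomaterial` object.
#' @param spec a [pose_spec()].
#' @return List with `atoms` (a 6-atom [atom_set()], members in cyclic
#'   order), `label` (the forced stacking state), `ring` (index of the
#'   surface ring posed over) and `coords` (6 x 3 matrix).
#' @export
place_ring <- function(surface, spec) {
  stopifnot(inherits(surface, "nanomaterial"), inherits(spec, "pose_spec"))
  idx <- spec$ring
  if (is.null(idx)) idx <- .anchor_hexagon(surface)
  if (surface$rings[[idx]]$size != 6L)
    stop("pose target ring must be hexagonal")
  fr <- .ring_frame(surface, idx)
  az <- spec$azimuth * pi / 180
  shift_dir <- cos(az) * fr$u + sin(az) * fr$v
  tilt_axis <- -sin(az) * fr$u + cos(az) * fr$v
  centre <- fr$centroid + spec$height * fr$n + spec$lateral_shift * shift_dir
  R <- rotation_matrix(tilt_axis, spec$tilt)
  m <- drop(R %*% fr$n)
  e1 <- drop(R %*% shift_dir)
  e2 <- c(m[2] * e1[3] - m[3] * e1[2],
          m[3] * e1[1] - m[1] * e1[3],
          m[1] * e1[2] - m[2] * e1[1])
  th <- (seq_len(6L) - 1L) * pi / 3
  coords <- t(vapply(th, function(a)
    centre + 1.39 * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  list(atoms = atom_set("C", coords, group_label = "RING"),
       label = spec$target_state, ring = idx, coords = coords)
}

#' Synthetic adsorption trajectory with ground-truth stacking labels
#'
#' Generates a multi-frame trajectory of an all-atom peptide whose two
#' phenyl rings (Tyr and Phe) are posed over the nanomaterial surface
#' according to a per-frame schedule of [pose_spec()]s, with small seeded
#' Gaussian coordinate jitter.  The jitter (sigma <= 0.05 Angstrom) is
#' within the safety margins of the pose validation, so the per-frame
#' stacking labels implied by the schedule are preserved exactly and are
#' returned as ground truth.
#'
#' The two rings are posed over two distinct surface hexagons at least
#' `ring_sep` Angstrom apart; the rest of the peptide is held away from the
#' surface (ring states depend only on the ring atoms).
#'
#' @param peptide a [build_peptide_model()] result with `tyr` and `phe`
#'   aromatic rings.
#' @param surface a `nanomaterial` object.
#' @param schedule list of frames, each a list with elements `tyr` and
#'   `phe` holding [pose_spec()]s.
#' @param seed integer seed; the output is deterministic per seed.
#' @param jitter_sd Gaussian jitter standard deviation in Angstrom
#'   (default 0.05; larger values void the label guarantee and are
#'   rejected).
#' @param ring_sep minimum separation of the two posed surface hexagons.
#' @return List with `trajectory` (a [trajectory()]), `labels` (data frame
#'   `frame`, `tyr`, `phe`, `category`) and `selectors` (list of the two
#'   6-atom ring index vectors, as [track_trajectory()] expects).
#' @export
synth_adsorption_trajectory <- function(peptide, surface, schedule, seed = 1L,
                                        jitter_sd = 0.05, ring_sep = 6) {
  stopifnot(inherits(peptide, "peptide_model"),
            inherits(surface, "nanomaterial"))
  if (jitter_sd > 0.05)
    stop("'jitter_sd' above 0.05 Angstrom voids the label guarantee")
  sel <- peptide$aromatic_rings[c("tyr", "phe")]
  if (any(vapply(sel, is.null, logical(1))))
    stop("peptide must have exactly one Tyr and one Phe ring")
  ring_t <- .anchor_hexagon(surface)
  ring_p <- .anchor_hexagon(surface, exclude = ring_t, min_sep = ring_sep)
  set.seed(as.integer(seed))
  base <- peptide$atoms$coords
  # park the peptide body far from the surface, rings overwritten below
  fr <- .ring_frame(surface, ring_t)
  off <- fr$centroid + 40 * fr$n - colMeans(base)
  base <- sweep(base, 2, -off)
  frames <- vector("list", length(schedule))
  lab <- vector("list", length(schedule))
  for (f in seq_along(schedule)) {
    sp_t <- schedule[[f]]$tyr
    sp_p <- schedule[[f]]$phe
    if (is.null(sp_t$ring)) sp_t$ring <- ring_t
    if (is.null(sp_p$ring)) sp_p$ring <- ring_p
    co <- base
    pt <- place_ring(surface, sp_t)
    pp <- place_ring(surface, sp_p)
    co[sel$tyr, ] <- pt$coords
    co[sel$phe, ] <- pp$coords
    co <- co + matrix(stats::rnorm(length(co), sd = jitter_sd),
                      nrow(co), 3L)
    frames[[f]] <- co
    lab[[f]] <- data.frame(frame = f, tyr = pt$label, phe = pp$label,
                           category = categorize_pair(pt$label, pp$label))
  }
  traj <- trajectory(frames, element = peptide$atoms$element,
                     group_label = peptide$atoms$group_label,
                     atom_name = peptide$atoms$atom_name,
                     residues = peptide$residues)
  list(trajectory = traj, labels = do.call(rbind, lab), selectors = sel)
}

## ---- biased reaction-coordinate sampling ----------------------------------

.synthetic_potential <- function(potential, pars) {
  switch(potential,
    flat = function(d) rep(0, length(d)),
    harmonic = function(d) 0.5 * pars$a * (d - pars$d0)^2,
    morse_like = function(d) {
      e <- exp(-pars$alpha * (d - pars$d0))
      pars$depth * (1 - e)^2
    },
    stop("unknown potential: ", potential))
}

#' Sample umbrella windows from a known analytic potential
#'
#' Metropolis sampling of the biased density
#' \eqn{\propto \exp[-\beta (U(d) + \tfrac12 k (d - c_i)^2)]} for each
#' window centre \eqn{c_i}, where U is one of three analytic potentials
#' (all in kcal/mol):
#'
#' * `"flat"`: U = 0;
#' * `"harmonic"`: U = a/2 (d - d0)^2 with `pars = list(a=, d0=)`;
#' * `"morse_like"`: U = depth (1 - exp(-alpha (d - d0)))^2 with
#'   `pars = list(depth=, alpha=, d0=)` - a binding well of exactly
#'   `depth` kcal/mol between the minimum and the dissociated plateau.
#'
#' The proposal step is auto-tuned during burn-in toward 30-60%
#' acceptance, and only every `thin`-th Metropolis state is recorded so
#' the returned samples are approximately decorrelated.  All randomness
#' flows from `seed`; identical seeds give identical sample streams.
#'
#' @param potential `"flat"`, `"harmonic"` or `"morse_like"`.
#' @param pars named list of potential parameters (see above).
#' @param centers numeric vector of window centres in Angstrom.
#' @param force_constant bias spring constant in kJ mol^-1 nm^-2
#'   (default 8000).
#' @param temperature temperature in Kelvin.
#' @param n_per_window recorded samples per window.
#' @param seed integer seed.
#' @param burn_in discarded tuning steps per window.
#' @param thin record every `thin`-th Metropolis state (default 10).
#' @return List of [umbrella_window()]s, one per centre, each carrying an
#'   `acceptance` attribute.
#' @export
sample_biased_windows <- function(potential, pars = list(), centers,
                                  force_constant = 8000, temperature = 300,
                                  n_per_window = 5000, seed = 1L,
                                  burn_in = 500L, thin = 10L) {
  potential <- match.arg(potential, c("flat", "harmonic", "morse_like"))
  U <- .synthetic_potential(potential, pars)
  beta <- 1 / (.kB_kcal * temperature)
  k_A <- kj_to_kcal(force_constant) / 100          # kcal/mol/A^2
  set.seed(as.integer(seed))
  lapply(centers, function(cc) {
    etot <- function(d) U(d) + 0.5 * k_A * (d - cc)^2
    d <- cc
    e <- etot(d)
    step <- if (k_A > 0) sqrt(1 / (beta * k_A)) else 0.5
    acc_w <- 0L
    # burn-in with step adaptation in 10 batches
    nb <- max(1L, burn_in %/% 10L)
    for (batch in seq_len(10L)) {
      acc_b <- 0L
      for (s in seq_len(nb)) {
        dn <- d + stats::runif(1, -step, step)
        en <- etot(dn)
        if (stats::runif(1) < exp(-beta * (en - e))) {
          d <- dn; e <- en; acc_b <- acc_b + 1L
        }
      }
      r <- acc_b / nb
      if (r < 0.30) step <- step / 1.3
      else if (r > 0.60) step <- step * 1.3
    }
    thin <- max(1L, as.integer(thin))
    out <- numeric(n_per_window)
    ntot <- n_per_window * thin
    for (s in seq_len(ntot)) {
      dn <- d + stats::runif(1, -step, step)
      en <- etot(dn)
      if (stats::runif(1) < exp(-beta * (en - e))) {
        d <- dn; e <- en; acc_w <- acc_w + 1L
      }
      if (s %% thin == 0L) out[s %/% thin] <- d
    }
    if (acc_w == 0L)
      stop("sampler error: zero acceptance in window at ", cc)
    w <- umbrella_window(cc, out, force_constant)
    attr(w, "acceptance") <- acc_w / ntot
    w
  })
}

#' Synthetic hydration shell around a solute
#'
#' Generates water-oxygen point sets emulating a first hydration shell:
#' `n_shell` points at Gaussian-distributed radial distances
#' (`shell_radius` +/- `shell_sigma`) in random directions around randomly
#' chosen solute atoms, plus `n_background` points uniform in the periodic
#' box.  Supports radial-distribution-function tests with a known peak
#' position.
#'
#' @param solute an [atom_set()]; must fit inside `box`.
#' @param shell_radius mean shell radius in Angstrom.
#' @param shell_sigma radial spread in Angstrom.
#' @param n_shell number of shell points (0 for background only).
#' @param box length-3 orthorhombic box (Angstrom), periodic in all axes.
#' @param n_background number of uniform background points.
#' @param seed integer seed.
#' @return An [atom_set()] of `"O"` atoms (group `"SOL"`) with the
#'   periodic cell attached.
#' @export
synth_hydration_shell <- function(solute, shell_radius = 2.0,
                                  shell_sigma = 0.2, n_shell = 1000L,
                                  box, n_background = 0L, seed = 1L) {
  stopifnot(inherits(solute, "atom_set"), length(box) == 3L, all(box > 0))
  set.seed(as.integer(seed))
  pts <- NULL
  if (n_shell > 0L) {
    who <- sample.int(n_atoms(solute), n_shell, replace = TRUE)
    dir <- matrix(stats::rnorm(3L * n_shell), n_shell, 3L)
    dir <- dir / sqrt(rowSums(dir^2))
    rad <- stats::rnorm(n_shell, shell_radius, shell_sigma)
    pts <- solute$coords[who, , drop = FALSE] + dir * rad
  }
  if (n_background > 0L) {
    bg <- cbind(stats::runif(n_background, 0, box[1]),
                stats::runif(n_background, 0, box[2]),
                stats::runif(n_background, 0, box[3]))
    pts <- rbind(pts, bg)
  }
  if (is.null(pts)) stop("no points requested")
  # wrap into the box
  for (ax in 1:3) pts[, ax] <- pts[, ax] %% box[ax]
  atom_set("O", pts, group_label = "SOL", atom_name = "OW",
           cell = box, periodic = c(TRUE, TRUE, TRUE))
}
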