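#' Aromatic stacking classification parameters
#'
#' Thresholds of the geometric pi-stacking classifier.  A peptide aromatic
#' ring is in *no* stacking register with the surface when its minimum
#' pairwise atom-atom distance to the nanomaterial exceeds `contact_cutoff`,
#' or when the folded angle between the ring-plane normal and the normal of
#' the nearest surface ring exceeds `max_tilt`.  Otherwise the ring is
#' *face-to-face* stacked when the lateral displacement of its centroid from
#' the centroid of the nearest hexagonal surface ring is below
#' `f2f_displacement` (half the 1.42 Angstrom carbon-carbon bond length by
#' default), and *offset* stacked otherwise.
#'
#' @param contact_cutoff atom-atom contact distance in Angstrom (default 4.5).
#' @param max_tilt maximum ring-plane tilt in degrees (default 30).
#' @param f2f_displacement lateral centroid displacement bound for
#'   face-to-face stacking, Angstrom (default 0.71).
#' @return An object of class `"stacking_params"`.
#' @export
stacking_params <- function(contact_cutoff = 4.5, max_tilt = 30,
                            f2f_displacement = 0.71) {
  stopifnot(contact_cutoff > 0, max_tilt > 0, f2f_displacement > 0)
  if (f2f_displacement >= contact_cutoff)
    stop("'f2f_displacement' must be smaller than 'contact_cutoff'")
  structure(list(contact_cutoff = contact_cutoff, max_tilt = max_tilt,
                 f2f_displacement = f2f_displacement),
            class = "stacking_params")
}

.stack_states <- c("NONE", "OFFSET", "FACE_TO_FACE")

#' Classify the stacking state of one aromatic ring
#'
#' Applies the geometric classifier described in [stacking_params()] to a
#' single peptide phenyl ring against a nanomaterial surface.  The tilt is
#' measured against the normal of the nearest surface ring (of any size,
#' which generalises the surface normal to curved C60 and nanotube
#' surfaces) and folded into \[0, 90\] degrees; the face-to-face
#' displacement is the in-plane distance between the peptide-ring centroid,
#' projected along the surface-ring normal, and the centroid of the nearest
#' *hexagonal* surface ring (pentagons are never face-to-face partners).
#'
#' @param ring a `ring` object (see [ring_from_coords()]) or a 6 x 3
#'   coordinate matrix of the ring atoms.
#' @param surface a `nanomaterial` object with perceived rings.
#' @param params a [stacking_params()] object.
#' @return A `ring_state` object with fields `value` (one of `"NONE"`,
#'   `"OFFSET"`, `"FACE_TO_FACE"`), `partner_ring` (index of the nearest
#'   hexagonal surface ring, NA when unstacked), `tilt` (degrees),
#'   `displacement` (Angstrom) and `min_pair_distance` (Angstrom).
#' @export
classify_ring <- function(ring, surface, params = stacking_params()) {
  if (!inherits(ring, "ring")) ring <- ring_from_coords(ring)
  if (ring$size != 6L)
    stop("peptide aromatic rings must have 6 members")
  stopifnot(inherits(surface, "nanomaterial"),
            inherits(params, "stacking_params"))
  sat <- surface$atoms
  mind <- min_pair_dist(ring$coords, sat$coords, sat$cell, sat$periodic)

  cen <- ring_centroids(surface)
  sizes <- vapply(surface$rings, function(r) r$size, integer(1))
  hex <- which(sizes == 6L)
  if (!length(hex))
    stop("surface has no hexagonal rings: cannot classify stacking")
  dcen <- pair_dist(matrix(ring$centroid, 1), cen, sat$cell, sat$periodic)
  nearest <- which.min(dcen)
  nearest_hex <- hex[which.min(dcen[hex])]

  # folded angle between plane normals, in [0, 90] degrees
  ns <- surface$rings[[nearest]]$normal
  cosang <- abs(sum(ring$normal * ns))
  tilt <- acos(min(1, max(-1, cosang))) * 180 / pi

  # lateral displacement w.r.t. the nearest hexagonal ring
  hx <- surface$rings[[nearest_hex]]
  d <- min_image(matrix(ring$centroid - hx$centroid, 1),
                 sat$cell, sat$periodic)[1, ]
  lateral <- d - sum(d * hx$normal) * hx$normal
  displacement <- sqrt(sum(lateral^2))

  if (mind > params$contact_cutoff || tilt > params$max_tilt) {
    value <- "NONE"; partner <- NA_integer_
  } else if (displacement < params$f2f_displacement) {
    value <- "FACE_TO_FACE"; partner <- nearest_hex
  } else {
    value <- "OFFSET"; partner <- nearest_hex
  }
  structure(list(value = value, partner_ring = partner, tilt = tilt,
                 displacement = displacement, min_pair_distance = mind),
            class = "ring_state")
}

#' @export
print.ring_state <- function(x, ...) {
  cat(sprintf("<ring_state> %s (tilt %.1f deg, displacement %.2f A, min pair dist %.2f A)\n",
              x$value, x$tilt, x$displacement, x$min_pair_distance))
  invisible(x)
}

#' Two-ring arrangement category
#'
#' Maps the unordered pair of stacking states of the two peptide aromatic
#' rings onto the six arrangement categories: (1) none/none, (2)
#' offset/none, (3) offset/offset, (4) face-to-face/none, (5)
#' face-to-face/offset, (6) face-to-face/face-to-face.
#'
#' @param a,b `ring_state` objects or state strings (`"NONE"`, `"OFFSET"`,
#'   `"FACE_TO_FACE"`).
#' @return Integer category in 1..6.
#' @examples
#' categorize_pair("FACE_TO_FACE", "OFFSET")  # 5
#' @export
categorize_pair <- function(a, b) {
  lv <- function(s) {
    if (inherits(s, "ring_state")) s <- s$value
    m <- match(s, .stack_states)
    if (is.na(m)) stop("invalid stacking state: ", s)
    m - 1L                                   # NONE 0, OFFSET 1, F2F 2
  }
  x <- sort(c(lv(a), lv(b)), decreasing = TRUE)   # (hi, lo)
  key <- paste(x, collapse = "")
  map <- c("00" = 1L, "10" = 2L, "11" = 3L, "20" = 4L, "21" = 5L, "22" = 6L)
  unname(map[key])
}

#' Track aromatic stacking along a trajectory
#'
#' Classifies both peptide aromatic rings against the nanomaterial surface
#' in every frame and assigns the six-category arrangement label.
#'
#' @param traj a [trajectory()] of the peptide.
#' @param surface a `nanomaterial` object (geometry held fixed, as for a
#'   restrained nanomaterial).
#' @param selectors list with elements `tyr` and `phe`, each a vector of six
#'   atom indices into the trajectory giving the phenyl ring members.
#' @param params a [stacking_params()] object.
#' @return A data frame of class `"stacking_records"` with one row per
#'   frame: `frame`, per-ring state, tilt, displacement and minimum pair
#'   distance columns, and `category` (1..6).
#' @export
track_trajectory <- function(traj, surface, selectors,
                             params = stacking_params()) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- lapply(selectors[c("tyr", "phe")], as.integer)
  for (nm in names(sel))
    if (length(sel[[nm]]) != 6L)
      stop("selector '", nm, "' must resolve to exactly 6 atoms")
  nf <- n_frames(traj)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    st_t <- classify_ring(co[sel$tyr, , drop = FALSE], surface, params)
    st_p <- classify_ring(co[sel$phe, , drop = FALSE], surface, params)
    out[[f]] <- data.frame(
      frame = f,
      state_tyr = st_t$value, tilt_tyr = st_t$tilt,
      disp_tyr = st_t$displacement, mind_tyr = st_t$min_pair_distance,
      state_phe = st_p$value, tilt_phe = st_p$tilt,
      disp_phe = st_p$displacement, mind_phe = st_p$min_pair_distance,
      category = categorize_pair(st_t, st_p))
  }
  rec <- do.call(rbind, out)
  if (is.null(rec))
    rec <- data.frame(frame = integer(), state_tyr = character(),
                      tilt_tyr = numeric(), disp_tyr = numeric(),
                      mind_tyr = numeric(), state_phe = character(),
                      tilt_phe = numeric(), disp_phe = numeric(),
                      mind_phe = numeric(), category = integer())
  class(rec) <- c("stacking_records", "data.frame")
  rec
}

#' Arrangement-category occupancy
#'
#' Percentage of frames spent in each of the six two-ring arrangement
#' categories, plus the aggregation into the three main stacking groups:
#' no stacking (category 1), offset stacking (categories 2-5) and
#' face-to-face stacking (category 6).
#'
#' @param records a `"stacking_records"` data frame from
#'   [track_trajectory()], or an integer vector of categories in 1..6.
#' @return A list of class `"stack_occupancy"` with `per_category` (named
#'   percentages for "1".."6", summing to 100) and `main_groups`
#'   (percentages for `none`, `offset`, `face_to_face`).
#' @export
occupancy <- function(records) {
  cat6 <- if (is.data.frame(records)) records$category else as.integer(records)
  if (!length(cat6)) stop("empty input: no stacking records")
  if (any(is.na(cat6)) || any(cat6 < 1L | cat6 > 6L))
    stop("categories must lie in 1..6")
  counts <- tabulate(cat6, nbins = 6L)
  pct <- 100 * counts / length(cat6)
  names(pct) <- as.character(1:6)
  main <- c(none = pct[["1"]],
            offset = sum(pct[c("2", "3", "4", "5")]),
            face_to_face = pct[["6"]])
  structure(list(per_category = pct, main_groups = main,
                 n_frames = length(cat6)),
            class = "stack_occupancy")
}

#' @export
print.stack_occupancy <- function(x, ...) {
  cat(sprintf("<stack_occupancy> over %d frames\n", x$n_frames))
  cat("  category:", paste(sprintf("%s: %.1f%%", names(x$per_category),
                                   x$per_category), collapse = "  "), "\n")
  cat(sprintf("  main groups: none %.1f%% | offset %.1f%% | face-to-face %.1f%%\n",
              x$main_groups["none"], x$main_groups["offset"],
              x$main_groups["face_to_face"]))
  invisible(x)
}

#' Tracking map: peptide position versus number of stacked rings
#'
#' For each frame, reports the peptide centre of mass together with the
#' number of aromatic rings (0-2) currently in a stacked state (offset or
#' face-to-face), the quantity plotted in aromatic tracking maps.
#'
#' @inheritParams track_trajectory
#' @return A data frame with columns `frame`, `com_x`, `com_y`, `com_z`,
#'   `n_stacked`.
#' @export
tracking_map <- function(traj, surface, selectors,
                         params = stacking_params()) {
  rec <- track_trajectory(traj, surface, selectors, params)
  nf <- n_frames(traj)
  com <- matrix(0, nf, 3)
  m <- element_mass(traj$element)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    com[f, ] <- drop(crossprod(m, co)) / sum(m)
  }
  n_stacked <- (rec$state_tyr != "NONE") + (rec$state_phe != "NONE")
  data.frame(frame = rec$frame, com_x = com[rec$frame, 1],
             com_y = com[rec$frame, 2], com_z = com[rec$frame, 3],
             n_stacked = as.integer(n_stacked))
}
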