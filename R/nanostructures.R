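#' Carbon nanomaterial generators
#'
#' Deterministic, parameter-free construction of the three carbonaceous
#' nanomaterial geometries used throughout the package: a C60 fullerene, an
#' open-ended armchair (n,n) single-wall nanotube, and a periodic graphene
#' sheet.  All generators return a `nanomaterial` object: an [atom_set()] of
#' carbon atoms plus the perceived aromatic rings (see [detect_rings()]).
#'
#' @name nanostructures
NULL

new_nanomaterial <- function(kind, atoms, cc_bond_length,
                             bond_cutoff = 1.7) {
  rings <- detect_rings(atoms, bond_cutoff = bond_cutoff)
  structure(list(kind = kind, atoms = atoms, rings = rings,
                 cc_bond_length = cc_bond_length),
            class = "nanomaterial")
}

#' @export
print.nanomaterial <- function(x, ...) {
  sz <- vapply(x$rings, function(r) r$size, integer(1))
  cat(sprintf("<nanomaterial: %s> %d C atoms, %d rings (%d pentagons, %d hexagons)\n",
              x$kind, n_atoms(x$atoms), length(x$rings),
              sum(sz == 5L), sum(sz == 6L)))
  invisible(x)
}

#' Build a C60 fullerene
#'
#' Constructs buckminsterfullerene analytically as a truncated icosahedron.
#' Each icosahedron edge of length \eqn{L = 2 b_{65} + b_{66}} is truncated at
#' fraction \eqn{t = b_{65}/L} from both ends, which yields exactly the two
#' graphitic bond lengths: hexagon-hexagon bonds \eqn{b_{66}} (the mid
#' segment of each icosahedron edge) and pentagon-hexagon bonds \eqn{b_{65}}
#' (the pentagon edges around each truncated vertex).  All 60 atoms lie on a
#' common sphere centred at the origin; with the default bond lengths the
#' radius is about 3.56 Angstrom, matching the nominal ~3.5 Angstrom radius
#' of C60.
#'
#' @param bond_hh hexagon-hexagon bond length in Angstrom (default 1.40).
#' @param bond_ph pentagon-hexagon bond length in Angstrom (default 1.46).
#' @return A `nanomaterial` object of kind `"fullerene"` with 60 atoms,
#'   12 pentagonal and 20 hexagonal rings.
#' @examples
#' c60 <- build_c60()
#' mean(sqrt(rowSums(c60$atoms$coords^2)))  # ~3.56 A
#' @export
build_c60 <- function(bond_hh = 1.40, bond_ph = 1.46) {
  stopifnot(bond_hh > 0, bond_ph > 0)
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c( 1,  phi, 0), c(-1,  phi, 0), c( 1, -phi, 0), c(-1, -phi, 0),
    c( phi, 0,  1), c( phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1))
  L <- 2 * bond_ph + bond_hh
  ico <- ico * (L / 2)                     # icosahedron edge length L
  t <- bond_ph / L
  D <- as.matrix(stats::dist(ico))
  ed <- which(abs(D - L) < 1e-9 * L & upper.tri(D), arr.ind = TRUE)
  pts <- matrix(0, 2L * nrow(ed), 3L)
  for (e in seq_len(nrow(ed))) {
    v <- ico[ed[e, 1], ]; w <- ico[ed[e, 2], ]
    pts[2L * e - 1L, ] <- v + t * (w - v)
    pts[2L * e, ]      <- w + t * (v - w)
  }
  atoms <- atom_set("C", pts, group_label = "NANO")
  new_nanomaterial("fullerene", atoms, cc_bond_length = bond_hh)
}

#' Build an open-ended armchair (n,n) carbon nanotube
#'
#' Rolls the graphene honeycomb lattice into an armchair tube aligned with
#' the z axis.  The translational unit cell of an (n,n) armchair tube holds
#' 4n atoms and repeats with period \eqn{\sqrt{3}\,a_{cc}} along the axis;
#' the tube is built from the fewest whole cells whose total length reaches
#' `min_length`.  Atoms are mapped onto the cylinder of radius
#' \eqn{3 n a_{cc} / 2\pi}, so every atom is exactly equidistant from the
#' axis; for (5,5) with \eqn{a_{cc}} = 1.42 Angstrom the diameter is 6.78
#' Angstrom.
#'
#' @param n chiral index of the (n,n) armchair tube; must be >= 2.
#' @param min_length minimum tube length in Angstrom (whole translational
#'   cells are used, so the realised length is the smallest multiple of the
#'   cell period at or above this value).
#' @param cc_bond_length carbon-carbon bond length on the unrolled sheet in
#'   Angstrom (default 1.42).
#' @return A `nanomaterial` object of kind `"nanotube"`.
#' @examples
#' swnt <- build_armchair_nanotube(5, 38)
#' n_atoms(swnt$atoms)   # 320
#' @export
build_armchair_nanotube <- function(n, min_length, cc_bond_length = 1.42) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L)
    stop("invalid chirality: armchair index 'n' must be an integer >= 2")
  stopifnot(min_length > 0, cc_bond_length > 0)
  cc <- cc_bond_length
  period <- sqrt(3) * cc                  # translational period along axis
  m <- ceiling(min_length / period)       # whole cells
  circumference <- 3 * cc * n
  radius <- circumference / (2 * pi)
  # 4-atom rectangular cell on the unrolled sheet:
  #   axial coordinate a (period sqrt(3) cc), circumferential coordinate s
  base <- rbind(c(0, 0),
                c(sqrt(3) * cc / 2, cc / 2),
                c(sqrt(3) * cc / 2, 3 * cc / 2),
                c(0, 2 * cc))
  ia <- rep(0:(m - 1L), each = n)
  js <- rep(0:(n - 1L), times = m)
  a <- rep(base[, 1], times = m * n) + period * rep(ia, each = 4L)
  s <- rep(base[, 2], times = m * n) + 3 * cc * rep(js, each = 4L)
  ang <- 2 * pi * s / circumference
  pts <- cbind(radius * cos(ang), radius * sin(ang), a)
  atoms <- atom_set("C", pts, group_label = "NANO")
  new_nanomaterial("nanotube", atoms, cc_bond_length = cc)
}

#' Build a periodic graphene sheet
#'
#' Tiles the 4-atom orthorhombic graphene cell (dimensions
#' \eqn{\sqrt{3}\,a_{cc} \times 3 a_{cc}}) into the smallest whole supercell
#' covering `min_x` by `min_y` Angstrom (rounding up to whole cells so no
#' partial hexagons are produced), or into an explicit `nx` by `ny`
#' supercell.  The sheet lies in the z = 0 plane and the returned cell is
#' periodic in x and y.
#'
#' @param min_x,min_y minimum sheet extent in Angstrom (ignored when
#'   `nx`/`ny` are given).
#' @param cc_bond_length carbon-carbon bond length in Angstrom.
#' @param nx,ny optional explicit replication counts of the 4-atom cell.
#' @return A `nanomaterial` object of kind `"graphene"`; atom count is
#'   `4 * nx * ny`.
#' @examples
#' g <- build_graphene(nx = 27, ny = 20)   # the 2160-atom sheet
#' n_atoms(g$atoms)
#' @export
build_graphene <- function(min_x = NULL, min_y = NULL, cc_bond_length = 1.42,
                           nx = NULL, ny = NULL) {
  cc <- cc_bond_length
  stopifnot(cc > 0)
  ax <- sqrt(3) * cc; ay <- 3 * cc
  if (is.null(nx)) {
    stopifnot(min_x > 0)
    nx <- ceiling(min_x / ax)
  }
  if (is.null(ny)) {
    stopifnot(min_y > 0)
    ny <- ceiling(min_y / ay)
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  base <- rbind(c(0, 0),
                c(ax / 2, cc / 2),
                c(ax / 2, 3 * cc / 2),
                c(0, 2 * cc))
  ix <- rep(0:(nx - 1L), each = ny)
  iy <- rep(0:(ny - 1L), times = nx)
  x <- rep(base[, 1], times = nx * ny) + ax * rep(ix, each = 4L)
  y <- rep(base[, 2], times = nx * ny) + ay * rep(iy, each = 4L)
  pts <- cbind(x, y, 0)
  atoms <- atom_set("C", pts, group_label = "NANO",
                    cell = c(nx * ax, ny * ay, 0),
                    periodic = c(TRUE, TRUE, FALSE))
  new_nanomaterial("graphene", atoms, cc_bond_length = cc)
}

## ---- ring perception -----------------------------------------------------

#' Perceive 5- and 6-membered rings in a carbon lattice
#'
#' Builds the bond graph of a carbon-only [atom_set()] with a distance
#' cutoff (honouring the minimum-image convention on periodic axes) and
#' returns every minimal 5- or 6-membered cycle, in the
#' smallest-set-of-smallest-rings sense appropriate for graphitic lattices:
#' for every pair of bonds meeting at an atom the shortest closing path is
#' found, and the resulting cycles are deduplicated.
#'
#' Each ring carries its member indices (in cyclic order), size, centroid
#' and best-fit-plane unit normal (smallest singular direction of the
#' centred member coordinates).  For rings crossing a periodic boundary the
#' member coordinates are unwrapped before the centroid and normal are
#' computed.  The normal sign is chosen to point toward `orient_toward`
#' when supplied, otherwise toward +z (falling back to the largest
#' component).
#'
#' @param atoms a carbon-only [atom_set()].
#' @param bond_cutoff bond perception distance in Angstrom, in (1.2, 1.7];
#'   the default 1.7 covers both 1.40 and 1.46 Angstrom graphitic bonds.
#' @param orient_toward optional 3-vector; ring normals are oriented to
#'   point toward this position.
#' @return A list of `ring` objects (fields `member_ids`, `size`,
#'   `centroid`, `normal`, `coords`), ordered by size then first member id.
#' @examples
#' rs <- detect_rings(build_c60()$atoms)
#' table(vapply(rs, function(r) r$size, integer(1)))  # 12 pentagons, 20 hexagons
#' @export
detect_rings <- function(atoms, bond_cutoff = 1.7, orient_toward = NULL) {
  stopifnot(inherits(atoms, "atom_set"))
  if (!all(atoms$element == "C"))
    stop("'atoms' must contain only carbon atoms")
  if (bond_cutoff <= 1.2 || bond_cutoff > 1.7)
    stop("'bond_cutoff' must lie in (1.2, 1.7]")
  co <- atoms$coords
  n <- nrow(co)
  D <- pair_dist(co, co, atoms$cell, atoms$periodic)
  diag(D) <- Inf
  adj <- D < bond_cutoff
  deg <- rowSums(adj)
  if (any(deg > 3))
    stop("malformed lattice: atom with more than 3 bonds")
  nb <- lapply(seq_len(n), function(i) which(adj[i, ]))

  seen <- new.env(hash = TRUE)
  rings <- list()
  for (i in seq_len(n)) {
    nbi <- nb[[i]]
    if (length(nbi) < 2L) next
    prs <- utils::combn(nbi, 2L)
    for (p in seq_len(ncol(prs))) {
      j <- prs[1L, p]; k <- prs[2L, p]
      path <- .shortest_path_avoiding(nb, j, k, avoid = i, max_edges = 4L)
      if (is.null(path)) next
      cyc <- c(i, path)                       # cyclic order i, j, ..., k
      if (length(cyc) < 5L || length(cyc) > 6L) next
      key <- paste(sort(cyc), collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      rings[[length(rings) + 1L]] <- cyc
    }
  }
  rings <- lapply(rings, function(cyc)
    .make_ring(cyc, atoms, orient_toward = orient_toward))
  sz <- vapply(rings, function(r) r$size, integer(1))
  first <- vapply(rings, function(r) min(r$member_ids), integer(1))
  rings[order(sz, first)]
}

# BFS shortest path from j to k avoiding atom `avoid`, at most `max_edges`
# edges; returns the path j..k (inclusive) or NULL.
.shortest_path_avoiding <- function(nb, j, k, avoid, max_edges) {
  if (j == k) return(j)
  n <- length(nb)
  parent <- rep(NA_integer_, n)
  parent[j] <- -1L
  frontier <- j
  depth <- 0L
  while (length(frontier) && depth < max_edges) {
    depth <- depth + 1L
    nxt <- integer(0)
    for (u in frontier) {
      for (v in nb[[u]]) {
        if (v == avoid) next
        if (!is.na(parent[v])) next
        parent[v] <- u
        if (v == k) {
          path <- v
          while (parent[path[1]] != -1L) path <- c(parent[path[1]], path)
          return(path)
        }
        nxt <- c(nxt, v)
      }
    }
    frontier <- nxt
  }
  NULL
}

# build a ring object from a cyclic atom index vector, unwrapping periodic
# images by walking the cycle with minimum-image steps
.make_ring <- function(cyc, atoms, orient_toward = NULL) {
  co <- atoms$coords[cyc, , drop = FALSE]
  if (!is.null(atoms$cell) && any(atoms$periodic)) {
    for (m in 2:nrow(co)) {
      step <- min_image(co[m, , drop = FALSE] - co[m - 1L, , drop = FALSE],
                        atoms$cell, atoms$periodic)
      co[m, ] <- co[m - 1L, ] + step
    }
  }
  ring_from_coords(co, member_ids = cyc, orient_toward = orient_toward)
}

#' Construct a ring object from member coordinates
#'
#' Computes the centroid and best-fit-plane unit normal of a 5- or 6-atom
#' ring given its member coordinates (in cyclic order for coordinates that
#' wrap a periodic cell, any order otherwise).
#'
#' @param coords 5 x 3 or 6 x 3 coordinate matrix (Angstrom).
#' @param member_ids optional atom indices of the members.
#' @param orient_toward optional 3-vector the normal should point toward.
#' @return A `ring` object.
#' @export
ring_from_coords <- function(coords, member_ids = seq_len(nrow(coords)),
                             orient_toward = NULL) {
  coords <- as.matrix(coords)
  if (!nrow(coords) %in% c(5L, 6L))
    stop("a ring must have 5 or 6 members")
  centroid <- colMeans(coords)
  cen <- sweep(coords, 2, centroid)
  sv <- svd(cen)
  normal <- sv$v[, 3L]
  normal <- normal / sqrt(sum(normal^2))
  if (!is.null(orient_toward)) {
    if (sum(normal * (orient_toward - centroid)) < 0) normal <- -normal
  } else {
    ref <- if (abs(normal[3]) > 1e-8) normal[3] else
      normal[which.max(abs(normal))]
    if (ref < 0) normal <- -normal
  }
  structure(list(member_ids = as.integer(member_ids),
                 size = nrow(coords),
                 centroid = centroid, normal = normal, coords = coords),
            class = "ring")
}

#' @export
print.ring <- function(x, ...) {
  cat(sprintf("<ring> %d-membered, centroid (%.2f, %.2f, %.2f)\n",
              x$size, x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

# matrix of ring centroids of a nanomaterial (rows = rings)
ring_centroids <- function(nano) {
  t(vapply(nano$rings, function(r) r$centroid, numeric(3)))
}
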