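# Shared fixtures and independent oracles used across test files.
# Surfaces are built once per test run (geometry generation is deterministic).

surf_c60 <- build_c60()
surf_tube <- build_armchair_nanotube(5, 38)
surf_graphene <- build_graphene(30, 30)

# draw one random pose spec that is valid for the requested (or random)
# stacking state under the default parameters
random_pose <- function(state = NULL) {
  if (is.null(state)) state <- sample(c("NONE", "OFFSET", "FACE_TO_FACE"), 1)
  switch(state,
    NONE = if (stats::runif(1) < 0.5)
      pose_spec("NONE", height = stats::runif(1, 5.5, 7.5),
                tilt = stats::runif(1, 0, 22),
                lateral_shift = stats::runif(1, 0, 1.1),
                azimuth = stats::runif(1, 0, 360))
    else
      pose_spec("NONE", height = stats::runif(1, 3.0, 4.2),
                tilt = stats::runif(1, 40, 90),
                lateral_shift = stats::runif(1, 0, 1.1),
                azimuth = stats::runif(1, 0, 360)),
    OFFSET = pose_spec("OFFSET", height = stats::runif(1, 3.2, 3.8),
                       tilt = stats::runif(1, 0, 22),
                       lateral_shift = stats::runif(1, 0.85, 1.15),
                       azimuth = stats::runif(1, 0, 360)),
    FACE_TO_FACE = pose_spec("FACE_TO_FACE",
                             height = stats::runif(1, 3.2, 3.8),
                             tilt = stats::runif(1, 0, 22),
                             lateral_shift = stats::runif(1, 0, 0.55),
                             azimuth = stats::runif(1, 0, 360)))
}

# Independent brute-force ring enumerator: every simple cycle of length 5
# or 6 in the bond graph, found by depth-first path search anchored at the
# cycle's smallest vertex.  No shared code with detect_rings().
brute_force_rings <- function(atoms, bond_cutoff = 1.7) {
  co <- atoms$coords
  n <- nrow(co)
  D <- as.matrix(stats::dist(co))
  adj <- D < bond_cutoff & D > 0
  nb <- lapply(seq_len(n), function(i) which(adj[i, ]))
  found <- character(0)
  walk <- function(path) {
    u <- path[length(path)]
    for (v in nb[[u]]) {
      if (v == path[1] && length(path) >= 5L) {
        found[[length(found) + 1L]] <<- paste(sort(path), collapse = ",")
      } else if (!(v %in% path) && v > path[1] && length(path) < 6L) {
        walk(c(path, v))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  sort(unique(found))
}

# Independent brute-force stacking classifier: plain double loops over
# atoms and rings, no shared helpers with classify_ring().
brute_force_classify <- function(ring_coords, surface,
                                 contact_cutoff = 4.5, max_tilt = 30,
                                 f2f = 0.71) {
  sc <- surface$atoms$coords
  mind <- Inf
  for (i in seq_len(nrow(ring_coords))) for (j in seq_len(nrow(sc))) {
    d <- sqrt(sum((ring_coords[i, ] - sc[j, ])^2))
    if (d < mind) mind <- d
  }
  cen <- colMeans(ring_coords)
  x <- sweep(ring_coords, 2, cen)
  nrm <- svd(x)$v[, 3]
  best <- Inf; best_i <- NA; best_hex <- Inf; best_hex_i <- NA
  for (i in seq_along(surface$rings)) {
    r <- surface$rings[[i]]
    d <- sqrt(sum((cen - r$centroid)^2))
    if (d < best) { best <- d; best_i <- i }
    if (r$size == 6L && d < best_hex) { best_hex <- d; best_hex_i <- i }
  }
  ns <- surface$rings[[best_i]]$normal
  tilt <- acos(min(1, abs(sum(nrm * ns)))) * 180 / pi
  hx <- surface$rings[[best_hex_i]]
  dv <- cen - hx$centroid
  lat <- dv - sum(dv * hx$normal) * hx$normal
  disp <- sqrt(sum(lat^2))
  if (mind > contact_cutoff || tilt > max_tilt) "NONE"
  else if (disp < f2f) "FACE_TO_FACE"
  else "OFFSET"
}

# union-find connected components of a logical adjacency matrix
uf_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}
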