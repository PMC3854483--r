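#' Kabsch superposition and RMSD
#'
#' `kabsch_superpose()` returns the coordinates of `mobile` optimally
#' superposed (least-squares rigid fit, proper rotation) onto `ref`;
#' `kabsch_rmsd()` returns the minimal root-mean-square deviation over all
#' rigid superpositions.
#'
#' @param mobile,ref,a,b n x 3 coordinate matrices or [atom_set()]s with
#'   identical atom counts and ordering.
#' @return `kabsch_superpose()`: an n x 3 matrix; `kabsch_rmsd()`: the RMSD
#'   in Angstrom.
#' @export
kabsch_superpose <- function(mobile, ref) {
  A <- if (inherits(mobile, "atom_set")) mobile$coords else as.matrix(mobile)
  B <- if (inherits(ref, "atom_set")) ref$coords else as.matrix(ref)
  if (!all(dim(A) == dim(B)))
    stop("coordinate sets must have identical atom counts")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(A0 %*% t(R), 2, -cb)
}

#' @rdname kabsch_superpose
#' @export
kabsch_rmsd <- function(a, b) {
  A <- if (inherits(a, "atom_set")) a$coords else as.matrix(a)
  B <- if (inherits(b, "atom_set")) b$coords else as.matrix(b)
  if (!all(dim(A) == dim(B)))
    stop("coordinate sets must have identical atom counts")
  fit <- kabsch_superpose(A, B)
  sqrt(mean(rowSums((fit - B)^2)))
}

#' Single-linkage RMSD clustering with representative structures
#'
#' Clusters conformations as the connected components of the graph linking
#' every pair of frames whose Kabsch RMSD is strictly below `cutoff` (2
#' Angstrom by default, over all atoms supplied).  Clusters are ordered by
#' decreasing size (ties by smallest first frame index) and the
#' representatives are the medoids - the frame minimising the summed RMSD
#' to its cluster mates, ties broken by lowest frame index - of the up to
#' three largest clusters, giving the most frequently sampled structures.
#'
#' @param frames list of n x 3 coordinate matrices or [atom_set()]s, all
#'   with the same atom count and ordering.
#' @param cutoff RMSD linkage cutoff in Angstrom.
#' @return An object of class `"cluster_result"`: list with `clusters`
#'   (list of frame-index vectors), `representatives` (up to three frame
#'   indices), `assignment` (cluster id per frame) and the `rmsd` matrix.
#' @export
single_linkage_cluster <- function(frames, cutoff = 2.0) {
  if (!length(frames)) stop("no frames to cluster")
  co <- lapply(frames, function(f)
    if (inherits(f, "atom_set")) f$coords else as.matrix(f))
  nf <- length(co)
  D <- matrix(0, nf, nf)
  if (nf > 1L) {
    for (i in 1:(nf - 1L)) for (j in (i + 1L):nf) {
      D[i, j] <- D[j, i] <- kabsch_rmsd(co[[i]], co[[j]])
    }
  }
  # connected components of the thresholded graph
  comp <- integer(nf)
  cur <- 0L
  for (s in seq_len(nf)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(D[u, ] < cutoff & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  clusters <- split(seq_len(nf), comp)
  sizes <- lengths(clusters)
  firsts <- vapply(clusters, min, integer(1))
  ord <- order(-sizes, firsts)
  clusters <- unname(clusters[ord])
  assignment <- integer(nf)
  for (k in seq_along(clusters)) assignment[clusters[[k]]] <- k
  nrep <- min(3L, length(clusters))
  reps <- vapply(clusters[seq_len(nrep)], function(members) {
    if (length(members) == 1L) return(members)
    ssum <- rowSums(D[members, members, drop = FALSE])
    members[which.min(ssum)]        # which.min already takes the first tie
  }, integer(1))
  structure(list(clusters = clusters, representatives = reps,
                 assignment = assignment, rmsd = D, cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d frames, %d clusters (cutoff %.2f A)\n",
              length(x$assignment), length(x$clusters), x$cutoff))
  sz <- lengths(x$clusters)
  cat("  sizes:", paste(utils::head(sz, 10), collapse = ", "),
      if (length(sz) > 10) "..." else "", "\n")
  cat("  representatives (frames):",
      paste(x$representatives, collapse = ", "), "\n")
  invisible(x)
}
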