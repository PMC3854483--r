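#' Molecular trajectories
#'
#' A `trajectory` holds an ordered series of frames sharing one topology:
#' per-atom element, atom name and group label, an optional residue
#' partition of the peptide atoms, and an optional periodic cell.
#'
#' @param frames a list of n x 3 coordinate matrices (one per frame), or a
#'   single n x 3 x n_frames array.
#' @param element character vector of chemical symbols, length n.
#' @param group_label per-atom group labels (e.g. `"TYR4"`, `"NANO"`).
#' @param atom_name optional per-atom names (e.g. `"CA"`).
#' @param residues optional named list mapping residue labels to atom index
#'   vectors; residues must be disjoint.
#' @param cell,periodic optional orthorhombic cell (Angstrom) and per-axis
#'   periodicity flags.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(frames, element, group_label = "X", atom_name = NULL,
                       residues = NULL, cell = NULL,
                       periodic = c(FALSE, FALSE, FALSE)) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(f) frames[, , f])
  if (!is.list(frames))
    stop("'frames' must be a list of coordinate matrices")
  frames <- lapply(frames, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  n <- if (length(frames)) nrow(frames[[1]]) else length(element)
  ok <- vapply(frames, function(m) nrow(m) == n && ncol(m) == 3L, logical(1))
  if (!all(ok)) stop("all frames must share one n x 3 atom layout")
  element <- rep_len(as.character(element), n)
  group_label <- rep_len(as.character(group_label), n)
  if (is.null(atom_name)) atom_name <- element
  atom_name <- rep_len(as.character(atom_name), n)
  if (!is.null(residues)) {
    idx <- unlist(residues, use.names = FALSE)
    if (anyDuplicated(idx)) stop("residues must be disjoint atom sets")
    if (any(idx < 1L | idx > n)) stop("residue atom index out of range")
  }
  periodic <- rep_len(as.logical(periodic), 3L)
  structure(list(frames = frames, element = element,
                 group_label = group_label, atom_name = atom_name,
                 residues = residues, cell = cell, periodic = periodic),
            class = "trajectory")
}

#' @rdname trajectory
#' @param x a `trajectory`.
#' @export
n_frames <- function(x) length(x$frames)

#' @rdname trajectory
#' @param f frame index.
#' @export
frame_coords <- function(x, f) x$frames[[f]]

# one frame as an atom_set
frame_atom_set <- function(x, f) {
  atom_set(x$element, x$frames[[f]], x$group_label, x$atom_name,
           x$cell, x$periodic)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms", n_frames(x),
              nrow(x$frames[[1]])))
  if (!is.null(x$residues))
    cat(sprintf(", %d residues", length(x$residues)))
  cat("\n")
  invisible(x)
}
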