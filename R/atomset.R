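#' Atom sets
#'
#' An `atom_set` is the basic coordinate container of the package: a set of
#' named atoms with chemical element, Cartesian coordinates in Angstrom, a
#' per-atom group label (residue name + number for peptides, `"NANO"` for a
#' nanomaterial, `"SOL"` for solvent), and an optional orthorhombic periodic
#' cell with per-axis periodicity flags.
#'
#' Atoms are indexed 1..n in storage order.  Coordinates must be finite; if
#' any periodicity flag is set the corresponding cell length must be positive.
#'
#' @param element character vector of chemical symbols (e.g. `"C"`, `"O"`).
#' @param coords numeric n x 3 matrix of coordinates in Angstrom.
#' @param group_label character vector of per-atom group labels, recycled if
#'   length 1.  Defaults to `"X"`.
#' @param atom_name optional character vector of atom names (e.g. `"CA"`).
#' @param cell optional numeric length-3 vector of orthorhombic cell lengths
#'   (Angstrom).
#' @param periodic logical length-3 vector; which axes are periodic.
#' @return An object of class `"atom_set"`: a list with elements `element`,
#'   `coords`, `group_label`, `atom_name`, `cell`, `periodic`.
#' @examples
#' a <- atom_set("C", matrix(0, 1, 3))
#' n_atoms(a)
#' @export
atom_set <- function(element, coords, group_label = "X", atom_name = NULL,
                     cell = NULL, periodic = c(FALSE, FALSE, FALSE)) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("'coords' must be an n x 3 matrix")
  dimnames(coords) <- NULL
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (!all(is.finite(coords)))
    stop("atom coordinates must be finite")
  element <- rep_len(as.character(element), n)
  group_label <- rep_len(as.character(group_label), n)
  if (is.null(atom_name)) atom_name <- element
  atom_name <- rep_len(as.character(atom_name), n)
  periodic <- rep_len(as.logical(periodic), 3L)
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 3L)
      stop("'cell' must be a length-3 vector of orthorhombic cell lengths")
    if (any(periodic & !(cell > 0)))
      stop("periodic axes require positive cell lengths")
  } else if (any(periodic)) {
    stop("periodicity flags set but no cell supplied")
  }
  structure(list(element = element, coords = coords,
                 group_label = group_label, atom_name = atom_name,
                 cell = cell, periodic = periodic),
            class = "atom_set")
}

#' @rdname atom_set
#' @param x an `atom_set`.
#' @export
n_atoms <- function(x) nrow(x$coords)

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("<atom_set> %d atoms (%s)\n", n_atoms(x),
              paste(names(sort(-table(x$element))), collapse = ",")))
  if (!is.null(x$cell))
    cat(sprintf("  cell %.2f x %.2f x %.2f A, periodic: %s\n",
                x$cell[1], x$cell[2], x$cell[3],
                paste(c("x", "y", "z")[x$periodic], collapse = "") ))
  invisible(x)
}

# subset an atom_set by atom indices
subset_atoms <- function(x, idx) {
  atom_set(x$element[idx], x$coords[idx, , drop = FALSE],
           x$group_label[idx], x$atom_name[idx], x$cell, x$periodic)
}

# merge two atom sets (cell taken from the first that has one)
combine_atoms <- function(a, b) {
  cell <- if (!is.null(a$cell)) a$cell else b$cell
  periodic <- if (!is.null(a$cell)) a$periodic else b$periodic
  atom_set(c(a$element, b$element), rbind(a$coords, b$coords),
           c(a$group_label, b$group_label), c(a$atom_name, b$atom_name),
           cell, periodic)
}

## ---- periodic geometry helpers ------------------------------------------

# minimum-image displacement vectors: rows of `d` wrapped into
# [-cell/2, cell/2) along periodic axes.  `d` is an n x 3 matrix.
min_image <- function(d, cell = NULL, periodic = c(FALSE, FALSE, FALSE)) {
  if (is.null(cell) || !any(periodic)) return(d)
  for (ax in which(periodic)) {
    L <- cell[ax]
    d[, ax] <- d[, ax] - L * round(d[, ax] / L)
  }
  d
}

# all pairwise distances between rows of A and rows of B under the
# minimum-image convention; returns an nA x nB matrix.
pair_dist <- function(A, B, cell = NULL, periodic = c(FALSE, FALSE, FALSE)) {
  nA <- nrow(A); nB <- nrow(B)
  out <- matrix(0, nA, nB)
  # block over A to keep memory bounded for large sets
  block <- max(1L, floor(2e6 / max(nB, 1L)))
  i <- 1L
  while (i <= nA) {
    j <- min(nA, i + block - 1L)
    idx <- i:j
    dx <- outer(A[idx, 1], B[, 1], "-")
    dy <- outer(A[idx, 2], B[, 2], "-")
    dz <- outer(A[idx, 3], B[, 3], "-")
    if (!is.null(cell) && any(periodic)) {
      if (periodic[1]) dx <- dx - cell[1] * round(dx / cell[1])
      if (periodic[2]) dy <- dy - cell[2] * round(dy / cell[2])
      if (periodic[3]) dz <- dz - cell[3] * round(dz / cell[3])
    }
    out[idx, ] <- sqrt(dx * dx + dy * dy + dz * dz)
    i <- j + 1L
  }
  out
}

# minimum pairwise distance between two coordinate blocks
min_pair_dist <- function(A, B, cell = NULL,
                          periodic = c(FALSE, FALSE, FALSE)) {
  min(pair_dist(A, B, cell, periodic))
}

## ---- rigid-body helpers --------------------------------------------------

# rotation matrix from axis (unit or not) and angle in degrees
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c1 + s1 * K + (1 - c1) * tcrossprod(u)
}

# apply rigid transform to an atom_set or bare coordinate matrix
transform_coords <- function(x, R = diag(3), shift = c(0, 0, 0)) {
  if (inherits(x, "atom_set")) {
    x$coords <- sweep(x$coords %*% t(R), 2, -shift)
    x
  } else {
    sweep(x %*% t(R), 2, -shift)
  }
}

## ---- element tables ------------------------------------------------------

# atomic masses (g/mol) for mass-weighted centres of mass
.element_mass <- stats::setNames(
  c(1.008, 12.011, 14.007, 15.999, 32.06, 22.990),
  c("H", "C", "N", "O", "S", "NA"))

element_mass <- function(el) {
  m <- .element_mass[toupper(el)]
  if (anyNA(m)) stop("no mass tabulated for element(s): ",
                     paste(unique(el[is.na(m)]), collapse = ", "))
  unname(m)
}

# Bondi van der Waals radii (Angstrom) used for SASA
.vdw_radius <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

vdw_radius <- function(el) {
  r <- .vdw_radius[toupper(el)]
  if (anyNA(r)) stop("no van der Waals radius tabulated for element(s): ",
                     paste(unique(el[is.na(r)]), collapse = ", "))
  unname(r)
}

# mass-weighted centre of mass of (a subset of) an atom_set
centre_of_mass <- function(x, idx = seq_len(n_atoms(x))) {
  m <- element_mass(x$element[idx])
  drop(crossprod(m, x$coords[idx, , drop = FALSE])) / sum(m)
}
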