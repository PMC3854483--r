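## File I/O: multi-frame XYZ, PDB (via bio3d), single-frame GRO, and
## umbrella-window sample files.

#' Read and write multi-frame XYZ files
#'
#' Plain XYZ: per frame an atom count line, a comment line, then
#' `element x y z` records in Angstrom.  `write_xyz()` accepts an
#' [atom_set()], a [trajectory()] or a list of atom sets; `read_xyz()`
#' returns a [trajectory()] (single-frame files still come back as a
#' 1-frame trajectory).
#'
#' @param x object to write.
#' @param file path.
#' @param comment per-frame comment line(s).
#' @return `read_xyz()`: a [trajectory()].
#' @export
write_xyz <- function(x, file, comment = "") {
  frames <- if (inherits(x, "atom_set")) list(x)
    else if (inherits(x, "trajectory"))
      lapply(seq_len(n_frames(x)), function(f) frame_atom_set(x, f))
    else x
  comment <- rep_len(comment, length(frames))
  con <- base::file(file, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    a <- frames[[f]]
    writeLines(c(as.character(n_atoms(a)), comment[f]), con)
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", a$element,
                       a$coords[, 1], a$coords[, 2], a$coords[, 3]), con)
  }
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list(); element <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(tok, `[[`, character(1), 1L)
    co <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (is.null(element)) element <- el
    frames[[length(frames) + 1L]] <- co
    i <- i + 2L + n
  }
  trajectory(frames, element = element)
}

#' Read and write PDB coordinate files
#'
#' Thin wrappers over **bio3d**'s PDB parser.  `write_pdb_atoms()` writes
#' an [atom_set()] as HETATM (or ATOM) records with the element column
#' filled; residue name and number are recovered from the group labels
#' (e.g. `"TYR4"`; purely alphabetic labels such as `"NANO"` get residue
#' number 1).  `read_pdb_atoms()` returns an [atom_set()].
#'
#' @param atoms an [atom_set()].
#' @param file path.
#' @param type record type, `"HETATM"` or `"ATOM"`.
#' @return `read_pdb_atoms()`: an [atom_set()].
#' @export
write_pdb_atoms <- function(atoms, file, type = "HETATM") {
  stopifnot(inherits(atoms, "atom_set"))
  resid <- sub("[0-9]+$", "", atoms$group_label)
  resno <- suppressWarnings(
    as.integer(sub("^[^0-9]*", "", atoms$group_label)))
  resno[is.na(resno)] <- 1L
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(atoms$coords)),
                   type = rep(type, n_atoms(atoms)),
                   resno = resno, resid = substr(resid, 1, 4),
                   eleno = seq_len(n_atoms(atoms)),
                   elety = atoms$atom_name,
                   elesy = atoms$element)
  invisible(file)
}

#' @rdname write_pdb_atoms
#' @export
read_pdb_atoms <- function(file) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  el <- trimws(at$elesy)
  no_el <- is.na(el) | !nzchar(el)
  el[no_el] <- substr(trimws(at$elety[no_el]), 1, 1)
  atom_set(el, cbind(at$x, at$y, at$z),
           group_label = paste0(trimws(at$resid), at$resno),
           atom_name = trimws(at$elety))
}

#' Read a GROMACS GRO coordinate file (single frame)
#'
#' Parses the fixed-width GRO format and converts positions from nm to
#' Angstrom.  The box line is read into an orthorhombic cell (also
#' converted to Angstrom); periodicity flags are left to the caller.
#'
#' @param file path.
#' @param periodic logical length-3 periodicity flags to attach.
#' @return An [atom_set()].
#' @export
read_gro <- function(file, periodic = c(FALSE, FALSE, FALSE)) {
  lines <- readLines(file)
  if (length(lines) < 3L) stop("malformed GRO file")
  n <- as.integer(trimws(lines[2]))
  rec <- lines[3:(2 + n)]
  resname <- trimws(substr(rec, 6, 10))
  resno <- as.integer(trimws(substr(rec, 1, 5)))
  aname <- trimws(substr(rec, 11, 15))
  x <- as.numeric(substr(rec, 21, 28)) * 10
  y <- as.numeric(substr(rec, 29, 36)) * 10
  z <- as.numeric(substr(rec, 37, 44)) * 10
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "[[:space:]]+")[[1]])
  cell <- if (length(box) >= 3L && all(box[1:3] > 0)) box[1:3] * 10 else NULL
  el <- substr(aname, 1, 1)
  atom_set(el, cbind(x, y, z), group_label = paste0(resname, resno),
           atom_name = aname, cell = cell,
           periodic = if (is.null(cell)) c(FALSE, FALSE, FALSE) else periodic)
}

#' Read and write umbrella-window sample files
#'
#' One plain-text column of reaction-coordinate values (Angstrom) per
#' window, named `window_<center>.dat`.  `write_window_dat()` writes a
#' list of [umbrella_window()]s into a directory; `read_windows()` reads
#' every `window_*.dat` file in a directory back (centres parsed from the
#' file names).
#'
#' @param windows list of [umbrella_window()]s.
#' @param dir directory path.
#' @param force_constant spring constant to attach on read, kJ mol^-1
#'   nm^-2.
#' @return `read_windows()`: a list of [umbrella_window()]s ordered by
#'   centre.
#' @export
write_window_dat <- function(windows, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (w in windows) {
    f <- file.path(dir, sprintf("window_%g.dat", w$center))
    writeLines(sprintf("%.8f", w$samples), f)
  }
  invisible(dir)
}

#' @rdname write_window_dat
#' @export
read_windows <- function(dir, force_constant = 8000) {
  files <- list.files(dir, pattern = "^window_.*\\.dat$", full.names = TRUE)
  if (!length(files)) stop("no window_*.dat files in ", dir)
  centers <- as.numeric(sub("^window_(.*)\\.dat$", "\\1", basename(files)))
  ord <- order(centers)
  mapply(function(f, cc)
    umbrella_window(cc, as.numeric(readLines(f)), force_constant),
    files[ord], centers[ord], SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
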