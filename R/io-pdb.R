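## Multi-model PDB trajectory I/O. Parsing and writing of the fixed-width
## records delegates to bio3d; this layer adds frame-consistency checks,
## element masses and formal-charge annotation, and the in-memory
## trajectory container used by all structure operations.

# atomic masses (amu) for the elements the toy systems use
.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, SE = 78.971)

# residue-name -> formal charge class at physiological pH; toy bead
# residues CAT/ANI and the cationic micelle head HDC are included
.CATIONIC_RES <- c("ARG", "LYS", "HIP", "CAT", "HDC")
.ANIONIC_RES <- c("ASP", "GLU", "ANI")

#' Formal charge class of a residue name
#'
#' Side-chain charge classification at physiological pH: ARG/LYS (and the
#' toy bead residues CAT and HDC) are cationic, ASP/GLU (and ANI) anionic,
#' everything else neutral.
#'
#' @param resname Character vector of residue names.
#' @return Character vector in \code{c("cationic","anionic","neutral")}.
#' @export
charge_class_from_resname <- function(resname) {
  ifelse(toupper(resname) %in% .CATIONIC_RES, "cationic",
         ifelse(toupper(resname) %in% .ANIONIC_RES, "anionic", "neutral"))
}

#' Construct an in-memory trajectory
#'
#' @param coords Numeric array of dimension (n_atoms, 3, n_frames), Angstrom.
#'   A single n x 3 matrix is accepted as one frame.
#' @param atoms \code{data.frame} with one row per atom: \code{name},
#'   \code{element}, \code{resname}, \code{resid} (1-based), \code{chain};
#'   optional \code{mass} (amu) and \code{charge_class} are filled from the
#'   element and residue-name lookups when absent.
#' @return List of class \code{"trajectory"} with elements \code{coords}
#'   and \code{atoms}.
#' @export
trajectory <- function(coords, atoms) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (any(!is.finite(coords)))
    stop("structural error: non-finite coordinates", call. = FALSE)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("name", "element", "resname", "resid", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("structural error: atoms table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(atoms) != dim(coords)[1])
    stop("structural error: atom count (", nrow(atoms),
         ") does not match coordinates (", dim(coords)[1], ")",
         call. = FALSE)
  if (is.null(atoms$mass)) {
    m <- .ELEMENT_MASS[toupper(atoms$element)]
    if (anyNA(m)) {
      warning("unknown element(s) ",
              paste(unique(atoms$element[is.na(m)]), collapse = ", "),
              "; assigning default mass 12.0")
      m[is.na(m)] <- 12.0
    }
    atoms$mass <- unname(m)
  }
  if (is.null(atoms$charge_class))
    atoms$charge_class <- charge_class_from_resname(atoms$resname)
  structure(list(coords = coords, atoms = atoms), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", dim(x$coords)[3], "frame(s) x", dim(x$coords)[1],
      "atoms,", length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj \code{\link{trajectory}}.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks become frames (a file without MODEL records is a
#' single frame). Residue indices are preserved as read (1-based PDB
#' convention); masses come from an element lookup, with a warning and
#' default mass 12.0 for unknown elements.
#'
#' @param path PDB file path.
#' @return \code{\link{trajectory}}.
#' @export
read_pdb_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    # frame-consistency check before handing off to the parser
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("structural error: unbalanced MODEL/ENDMDL records", call. = FALSE)
    counts <- mapply(function(s, e)
      sum(grepl("^(ATOM  |HETATM)", lines[s:e])), model_starts, model_ends)
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1])[1]
      stop("structural error: model ", bad, " has ", counts[bad],
           " atoms, expected ", counts[1], call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_atoms <- nrow(pdb$atom)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(n_atoms, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  ele <- pdb$atom$elesy
  blank <- is.na(ele) | !nzchar(trimws(ele))
  # fall back on the first letter of the atom name when the element
  # column is blank (common in minimal hand-written files)
  ele[blank] <- substr(trimws(pdb$atom$elety[blank]), 1L, 1L)
  atoms <- data.frame(
    name = trimws(pdb$atom$elety),
    element = toupper(trimws(ele)),
    resname = trimws(pdb$atom$resid),
    resid = pdb$atom$resno,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    stringsAsFactors = FALSE)
  trajectory(coords, atoms)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written at PDB precision (0.001 Angstrom); the
#' read/write pair round-trips to that precision.
#'
#' @param traj \code{\link{trajectory}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  na <- dim(traj$coords)[1]
  xyz <- matrix(NA_real_, nf, 3L * na)
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(traj$coords[, , f]))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = traj$atoms$resid,
                   resid = traj$atoms$resname,
                   eleno = seq_len(na),
                   elety = traj$atoms$name,
                   chain = traj$atoms$chain,
                   elesy = traj$atoms$element)
  invisible(path)
}

#' Select atoms of a trajectory
#'
#' Conjunctive filter over the atom table; \code{NULL} criteria are
#' ignored. Returns integer atom indices usable as the \code{sel}
#' argument of every structure operation.
#'
#' @param traj \code{\link{trajectory}}.
#' @param chain,resname,name,element,charge_class Character vectors of
#'   admissible values.
#' @param resid Integer vector of admissible residue indices (1-based).
#' @param allow_empty Return \code{integer(0)} instead of erroring when
#'   nothing matches.
#' @return Integer vector of atom indices.
#' @export
atom_select <- function(traj, chain = NULL, resid = NULL, resname = NULL,
                        name = NULL, element = NULL, charge_class = NULL,
                        allow_empty = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(charge_class)) keep <- keep & a$charge_class %in% charge_class
  idx <- which(keep)
  if (!length(idx) && !allow_empty)
    stop("selection error: no atoms match", call. = FALSE)
  idx
}

# resolve a selection argument: NULL -> all atoms; validate indices
.resolve_sel <- function(traj, sel, what = "selection") {
  if (is.null(sel)) return(seq_len(dim(traj$coords)[1]))
  sel <- as.integer(sel)
  if (!length(sel)) stop("selection error: empty ", what, call. = FALSE)
  if (any(sel < 1L | sel > dim(traj$coords)[1]))
    stop("selection error: atom index out of range in ", what, call. = FALSE)
  sel
}
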