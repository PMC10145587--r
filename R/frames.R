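#' Structural ensemble container
#'
#' A set of coordinate frames (trajectory snapshots or PDB MODELs) sharing
#' one atom table. Coordinates are in angstrom.
#'
#' @param atoms data frame with columns `name`, `element`, `resid`,
#'   `resname`, `chain`, `record` ("ATOM"/"HETATM"); a logical `heavy`
#'   column is derived from `element` if absent
#' @param coords numeric array `n_atoms x 3 x n_frames` (a single
#'   `n_atoms x 3` matrix is promoted to one frame)
#' @return object of class `structure_ensemble`
#' @export
structure_ensemble <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "element", "resid", "resname", "chain", "record")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            dim(coords)[1] == nrow(atoms), dim(coords)[3] >= 1)
  if (is.null(atoms$heavy)) atoms$heavy <- toupper(atoms$element) != "H"
  structure(list(atoms = atoms, coords = coords), class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d atoms (%d heavy), %d frame(s)\n",
              nrow(x$atoms), sum(x$atoms$heavy), n_frames(x)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a [structure_ensemble()]
#' @return integer
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Extract one frame's coordinate matrix
#' @param ensemble a [structure_ensemble()]
#' @param i frame index
#' @return `n_atoms x 3` matrix
#' @export
frame_coords <- function(ensemble, i = 1) {
  stopifnot(i >= 1, i <= n_frames(ensemble))
  m <- ensemble$coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Locate an atom by chain / residue number / atom name
#' @param ensemble a [structure_ensemble()]
#' @param chain chain identifier
#' @param resid 1-based residue number
#' @param name atom name
#' @return integer row index into the atom table
#' @export
atom_index <- function(ensemble, chain, resid, name) {
  a <- ensemble$atoms
  i <- which(a$chain == chain & a$resid == resid & a$name == name)
  if (length(i) == 0) stop(sprintf("atom %s/%s/%s not found", chain, resid, name))
  if (length(i) > 1) stop(sprintf("atom %s/%s/%s is ambiguous", chain, resid, name))
  i
}

#' Build frames with planted geometry
#'
#' Fixture generator: emits an ensemble whose atoms sit at exact declared
#' positions, optionally displaced per-frame by isotropic Gaussian jitter.
#' Used to construct hydrogen-bond, arm-in-groove and RMSF test cases with
#' known ground truth.
#'
#' @param spec data frame with columns `name`, `element`, `chain`,
#'   `resid`, `resname`, `record`, `x`, `y`, `z` and optional `jitter`
#'   (per-atom isotropic Gaussian sigma in A, default 0)
#' @param n_frames number of frames to emit
#' @param seed RNG seed for the jitter
#' @return a [structure_ensemble()]
#' @export
plant_contact_frames <- function(spec, n_frames = 1, seed = 1L) {
  stopifnot(is.data.frame(spec), n_frames >= 1)
  need <- c("name", "element", "chain", "resid", "resname", "record", "x", "y", "z")
  miss <- setdiff(need, names(spec))
  if (length(miss)) stop("spec missing columns: ", paste(miss, collapse = ", "))
  key <- paste(spec$chain, spec$resid, spec$name)
  if (anyDuplicated(key)) {
    stop("clashing atom identifiers: ", paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (is.null(spec$jitter)) spec$jitter <- 0
  stopifnot(all(spec$jitter >= 0))
  base <- as.matrix(spec[, c("x", "y", "z")])
  n <- nrow(spec)
  coords <- array(NA_real_, dim = c(n, 3, n_frames))
  set.seed(seed)
  for (f in seq_len(n_frames)) {
    disp <- matrix(stats::rnorm(3 * n, sd = rep(spec$jitter, 3)), ncol = 3)
    coords[, , f] <- base + disp
  }
  atoms <- spec[, c("name", "element", "chain", "resid", "resname", "record")]
  structure_ensemble(atoms, coords)
}
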