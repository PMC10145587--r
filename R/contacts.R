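#' Geometric hydrogen-bond criteria
#'
#' A donor-hydrogen-acceptor triple qualifies when the donor-acceptor
#' distance is below `distance_cutoff` AND the donor-H-acceptor angle is
#' larger than `angle_cutoff` — strict inequalities, exactly as the
#' conventional 3.5 A / 150 degree rule is stated.
#'
#' @param distance_cutoff donor-acceptor distance cutoff in A
#' @param angle_cutoff donor-hydrogen-acceptor angle cutoff in degrees
#' @return object of class `hbond_criteria`
#' @export
hbond_criteria <- function(distance_cutoff = 3.5, angle_cutoff = 150) {
  stopifnot(distance_cutoff > 0, angle_cutoff > 0, angle_cutoff <= 180)
  structure(list(distance_cutoff = distance_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criteria")
}

# molecule partition for "intermolecular": HETATM ligand vs ATOM receptor;
# if the records do not distinguish, fall back to chain identifiers
molecule_ids <- function(atoms) {
  if (length(unique(atoms$record)) > 1) atoms$record else atoms$chain
}

# hydrogens covalently attached to a heavy atom: same chain+residue and
# within the X-H bond cutoff
attached_hydrogens <- function(ensemble, heavy_idx, frame = 1, bond_cutoff = 1.25) {
  a <- ensemble$atoms
  xyz <- frame_coords(ensemble, frame)
  hs <- which(toupper(a$element) == "H" &
                a$chain == a$chain[heavy_idx] & a$resid == a$resid[heavy_idx])
  if (!length(hs)) return(integer(0))
  d <- sqrt(rowSums((xyz[hs, , drop = FALSE] -
                       matrix(xyz[heavy_idx, ], length(hs), 3, byrow = TRUE))^2))
  hs[d < bond_cutoff]
}

#' Default polar donor / acceptor sets
#'
#' N and O heavy atoms; donors additionally need at least one attached
#' hydrogen (checked later by [find_hbonds()]).
#' @param ensemble a [structure_ensemble()]
#' @return integer atom indices
#' @export
polar_atoms <- function(ensemble) {
  which(toupper(ensemble$atoms$element) %in% c("N", "O"))
}

#' Find intermolecular hydrogen bonds in one frame
#'
#' @param ensemble a [structure_ensemble()] with explicit hydrogens
#' @param frame frame index
#' @param donor_set heavy-atom indices allowed as donors (default: all
#'   N/O); donors without an attached hydrogen are skipped with a warning
#' @param acceptor_set heavy-atom indices allowed as acceptors (default:
#'   all N/O)
#' @param criteria a [hbond_criteria()]
#' @return data frame with columns `donor`, `hydrogen`, `acceptor`
#'   (atom indices), `distance` (donor-acceptor, A), `angle`
#'   (donor-H-acceptor, degrees)
#' @export
find_hbonds <- function(ensemble, frame = 1, donor_set = NULL,
                        acceptor_set = NULL, criteria = hbond_criteria()) {
  stopifnot(inherits(ensemble, "structure_ensemble"),
            inherits(criteria, "hbond_criteria"))
  # with the automatic polar set, an H-less N/O is simply not a donor;
  # only user-declared donors without hydrogens deserve a warning
  donors_declared <- !is.null(donor_set)
  if (is.null(donor_set)) donor_set <- polar_atoms(ensemble)
  if (is.null(acceptor_set)) acceptor_set <- polar_atoms(ensemble)
  xyz <- frame_coords(ensemble, frame)
  mol <- molecule_ids(ensemble$atoms)
  out <- list()
  for (d in donor_set) {
    hs <- attached_hydrogens(ensemble, d, frame)
    if (!length(hs)) {
      if (donors_declared) {
        warning(sprintf("donor %s/%s/%s has no attached hydrogen; skipped",
                        ensemble$atoms$chain[d], ensemble$atoms$resid[d],
                        ensemble$atoms$name[d]))
      }
      next
    }
    acc <- acceptor_set[mol[acceptor_set] != mol[d] & acceptor_set != d]
    if (!length(acc)) next
    da <- sqrt(rowSums((xyz[acc, , drop = FALSE] -
                          matrix(xyz[d, ], length(acc), 3, byrow = TRUE))^2))
    close <- acc[da < criteria$distance_cutoff]
    dist_close <- da[da < criteria$distance_cutoff]
    for (i in seq_along(close)) {
      a_idx <- close[i]
      for (h in hs) {
        ang <- angle3(xyz[d, ], xyz[h, ], xyz[a_idx, ]) * 180 / pi
        if (ang > criteria$angle_cutoff) {
          out[[length(out) + 1]] <- data.frame(
            donor = d, hydrogen = h, acceptor = a_idx,
            distance = dist_close[i], angle = ang)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  do.call(rbind, out)
}

#' Hydrogen-bond counts along a dissociation coordinate
#'
#' For each umbrella window (a set of frames at one reaction-coordinate
#' value) counts intermolecular hydrogen bonds per frame and averages.
#'
#' @param windows named list mapping the window coordinate (names coerced
#'   to numeric R_aA values in A) to [structure_ensemble()] frame sets
#' @param donor_set,acceptor_set,criteria passed to [find_hbonds()]
#' @return object of class `contact_series`: `per_frame` data frame
#'   (`r`, `frame`, `count`) and `summary` (`r`, `mean`)
#' @export
hbond_evolution <- function(windows, donor_set = NULL, acceptor_set = NULL,
                            criteria = hbond_criteria()) {
  stopifnot(length(windows) >= 1, !is.null(names(windows)))
  rvals <- as.numeric(names(windows))
  stopifnot(!anyNA(rvals))
  per <- list()
  for (i in seq_along(windows)) {
    ens <- windows[[i]]
    stopifnot(inherits(ens, "structure_ensemble"))
    if (n_frames(ens) < 1) stop("empty window at r = ", rvals[i])
    counts <- vapply(seq_len(n_frames(ens)), function(f) {
      nrow(find_hbonds(ens, f, donor_set, acceptor_set, criteria))
    }, numeric(1))
    per[[i]] <- data.frame(r = rvals[i], frame = seq_along(counts),
                           count = counts)
  }
  per_frame <- do.call(rbind, per)
  means <- vapply(split(per_frame$count, per_frame$r), mean, numeric(1))
  structure(list(per_frame = per_frame,
                 summary = data.frame(r = as.numeric(names(means)),
                                      mean = unname(means))),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("<contact_series> %d windows, mean count %.3g-%.3g\n",
              nrow(x$summary), min(x$summary$mean), max(x$summary$mean)))
  invisible(x)
}

#' Count ligand arms nestled in grooves
#'
#' An arm counts as bound when the minimum distance from its terminal
#' (outermost ether) oxygen to any quartet guanine nitrogen is below
#' `cutoff` (strict). Returns the per-frame bound-arm count.
#'
#' @param ensemble a [structure_ensemble()]
#' @param arm_oxygens integer vector of terminal-oxygen atom indices, one
#'   per arm
#' @param quartet_nitrogens integer vector of quartet nitrogen atom
#'   indices
#' @param cutoff distance cutoff in A
#' @param frames frame indices (default all)
#' @return integer vector of bound-arm counts, one per requested frame
#' @export
arm_groove_occupancy <- function(ensemble, arm_oxygens, quartet_nitrogens,
                                 cutoff = 3.5, frames = NULL) {
  stopifnot(inherits(ensemble, "structure_ensemble"),
            length(arm_oxygens) >= 1, length(quartet_nitrogens) >= 1,
            cutoff > 0)
  bad <- c(arm_oxygens, quartet_nitrogens)
  if (any(bad < 1 | bad > nrow(ensemble$atoms))) stop("atom index out of range")
  if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
  vapply(frames, function(f) {
    xyz <- frame_coords(ensemble, f)
    qn <- xyz[quartet_nitrogens, , drop = FALSE]
    sum(vapply(arm_oxygens, function(o) {
      dmin <- min(sqrt(rowSums((qn - matrix(xyz[o, ], nrow(qn), 3, byrow = TRUE))^2)))
      dmin < cutoff
    }, logical(1)))
  }, integer(1))
}
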