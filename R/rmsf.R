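#' Kabsch superposition of an ensemble onto a reference frame
#'
#' Each frame is rigidly transformed (rotation + translation, proper
#' rotation only: reflections are corrected by flipping the smallest
#' singular direction) to minimize the mass-unweighted RMSD over the
#' fitting selection.
#'
#' @param ensemble a [structure_ensemble()]
#' @param reference_frame index of the frame used as reference
#' @param selection integer atom indices used for the fit; default all
#'   heavy atoms. Needs >= 3 non-collinear atoms.
#' @return the ensemble with all frames superposed
#' @export
kabsch_superpose <- function(ensemble, reference_frame = 1, selection = NULL) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (is.null(selection)) selection <- which(ensemble$atoms$heavy)
  if (length(selection) < 3) stop("fit selection needs at least 3 atoms")
  ref <- frame_coords(ensemble, reference_frame)[selection, , drop = FALSE]
  if (degenerate_selection(ref)) {
    stop("fit selection is degenerate (collinear or coincident atoms)")
  }
  ref_c <- colMeans(ref)
  ref0 <- sweep(ref, 2, ref_c)
  out <- ensemble
  for (f in seq_len(n_frames(ensemble))) {
    xyz <- frame_coords(ensemble, f)
    mob <- xyz[selection, , drop = FALSE]
    mob_c <- colMeans(mob)
    h <- crossprod(sweep(mob, 2, mob_c), ref0)
    sv <- svd(h)
    d <- sign(det(sv$v %*% t(sv$u)))
    rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    out$coords[, , f] <- sweep(sweep(xyz, 2, mob_c) %*% t(rot), 2, ref_c, `+`)
  }
  out
}

degenerate_selection <- function(xyz) {
  if (nrow(xyz) < 3) return(TRUE)
  s <- svd(sweep(xyz, 2, colMeans(xyz)))$d
  s[2] < 1e-8 * max(s[1], 1)
}

#' Per-frame heavy-atom RMSD against a reference frame
#'
#' Assumes the ensemble is already superposed (see [kabsch_superpose()]).
#' A plateau annotation (first frame from which the moving-average RMSD
#' slope stays below `slope_tol` per frame) is attached as attribute
#' `"plateau_frame"` (`NA` if never flat).
#'
#' @param ensemble superposed [structure_ensemble()]
#' @param reference index of the reference frame
#' @param selection atom indices; default all heavy atoms
#' @param slope_tol plateau threshold in A per frame
#' @param span moving-average window in frames
#' @return [sample_series()] of RMSD values (A)
#' @export
rmsd_series <- function(ensemble, reference = 1, selection = NULL,
                        slope_tol = 0.01, span = 5L) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (is.null(selection)) selection <- which(ensemble$atoms$heavy)
  ref <- frame_coords(ensemble, reference)[selection, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(ensemble)), function(f) {
    d <- frame_coords(ensemble, f)[selection, , drop = FALSE] - ref
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  s <- sample_series(vals)
  n <- length(vals)
  if (n > span) {
    sm <- as.numeric(stats::filter(vals, rep(1 / span, span), sides = 1))
    slope <- abs(diff(sm))
    flat <- which(!is.na(slope) & slope < slope_tol)
    plateau <- NA_integer_
    # first frame from which the slope stays flat to the end
    for (j in flat) {
      if (all(slope[j:length(slope)] < slope_tol, na.rm = TRUE)) {
        plateau <- j + 1L
        break
      }
    }
    attr(s, "plateau_frame") <- plateau
  }
  s
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF of each atom across the (already superposed) frames, relative to
#' either the declared bound-state frame or the ensemble-mean structure.
#'
#' @param ensemble superposed [structure_ensemble()]
#' @param reference_mode `"bound_frame"` (deviations from one frame) or
#'   `"mean"` (deviations from the average structure)
#' @param reference_frame frame index when `reference_mode = "bound_frame"`
#' @return object of class `rmsf_report`: data frame `table` (atom table
#'   plus an `rmsf` column, A), `reference`, plus the inputs
#' @export
rmsf <- function(ensemble, reference_mode = c("bound_frame", "mean"),
                 reference_frame = 1) {
  reference_mode <- match.arg(reference_mode)
  stopifnot(inherits(ensemble, "structure_ensemble"))
  nf <- n_frames(ensemble)
  ref <- if (reference_mode == "bound_frame") {
    frame_coords(ensemble, reference_frame)
  } else {
    apply(ensemble$coords, c(1, 2), mean)
  }
  sq <- matrix(0, nrow(ensemble$atoms), 1)
  for (f in seq_len(nf)) {
    d <- frame_coords(ensemble, f) - ref
    sq <- sq + rowSums(d^2)
  }
  tab <- cbind(ensemble$atoms, rmsf = sqrt(sq[, 1] / nf))
  structure(list(table = tab,
                 reference = if (reference_mode == "mean") "mean" else reference_frame,
                 mode = reference_mode),
            class = "rmsf_report")
}

#' @export
print.rmsf_report <- function(x, ...) {
  cat(sprintf("<rmsf_report> %d atoms, reference = %s; RMSF range [%.3g, %.3g] A\n",
              nrow(x$table), as.character(x$reference),
              min(x$table$rmsf), max(x$table$rmsf)))
  invisible(x)
}

triple_geometry_ok <- function(xyz, min_separation, angle_range) {
  d12 <- vnorm(xyz[1, ] - xyz[2, ])
  d13 <- vnorm(xyz[1, ] - xyz[3, ])
  d23 <- vnorm(xyz[2, ] - xyz[3, ])
  if (min(d12, d13, d23) < min_separation) return("min_separation")
  angs <- c(angle3(xyz[2, ], xyz[1, ], xyz[3, ]),
            angle3(xyz[1, ], xyz[2, ], xyz[3, ]),
            angle3(xyz[1, ], xyz[3, ], xyz[2, ])) * 180 / pi
  if (any(angs < angle_range[1] | angs > angle_range[2])) return("collinearity")
  ""
}

# pick the first geometrically valid triple from a ranked candidate list,
# scanning ordered index combinations (i < j < k in rank order) so that an
# invalid top-3 falls through to the next-best substitution
pick_triple <- function(ranked_idx, xyz, min_separation, angle_range) {
  n <- length(ranked_idx)
  if (n < 3) return(NULL)
  last_reason <- ""
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        trip <- ranked_idx[c(i, j, k)]
        reason <- triple_geometry_ok(xyz[trip, , drop = FALSE],
                                     min_separation, angle_range)
        if (reason == "") return(trip)
        last_reason <- reason
      }
    }
  }
  attr(last_reason, "failed") <- TRUE
  last_reason
}

#' Select restraint atoms from RMSF within a declared rigid region
#'
#' The refinement this toolkit implements: ligand restraint atoms are the
#' *most* mobile heavy atoms inside the user-declared rigid region (e.g.
#' the porphyrin core) — restraining the atoms that fluctuate most within
#' the rigid part suppresses exactly those fluctuations, while atoms in
#' flexible arms are excluded by the region itself. Receptor anchors are
#' drawn from a user-declared candidate set (e.g. quartet-layer atoms)
#' ranked by *smallest* RMSF (a stable anchor). Both triples must satisfy
#' a minimum pairwise separation and a non-collinearity window; ranking
#' ties break deterministically by (RMSF, atom name, residue id).
#'
#' @param report an [rmsf()] report
#' @param ensemble the superposed ensemble (reference-frame coordinates
#'   provide the selection geometry)
#' @param ligand_region integer atom indices of the ligand's rigid region
#' @param receptor_candidates integer atom indices of allowed receptor
#'   anchors
#' @param min_separation minimum pairwise distance within a triple (A)
#' @param angle_range allowed internal angles of a triple (degrees)
#' @param reference_frame frame whose geometry is checked
#' @return list with `ligand` and `receptor` (each a 3-row slice of the
#'   RMSF table, in anchor order A/B/C and a/b/c) and `indices`
#' @export
select_restraint_atoms <- function(report, ensemble, ligand_region,
                                   receptor_candidates,
                                   min_separation = 2,
                                   angle_range = c(20, 160),
                                   reference_frame = 1) {
  stopifnot(inherits(report, "rmsf_report"), inherits(ensemble, "structure_ensemble"),
            length(ligand_region) >= 1, length(receptor_candidates) >= 1)
  tab <- report$table
  xyz <- frame_coords(ensemble, reference_frame)
  rank_region <- function(region, decreasing) {
    region <- region[tab$heavy[region]]
    o <- order(if (decreasing) -tab$rmsf[region] else tab$rmsf[region],
               tab$name[region], tab$resid[region])
    region[o]
  }
  pick_or_stop <- function(region, decreasing, what) {
    ranked <- rank_region(region, decreasing)
    if (length(ranked) < 3) stop("fewer than 3 heavy-atom candidates in the ", what, " region")
    res <- pick_triple(ranked, xyz, min_separation, angle_range)
    if (is.character(res)) {
      stop("no valid ", what, " triple: every combination violates the ",
           res, " rule")
    }
    res
  }
  lig <- pick_or_stop(ligand_region, decreasing = TRUE, "ligand")
  rec <- pick_or_stop(receptor_candidates, decreasing = FALSE, "receptor")
  list(ligand = tab[lig, ], receptor = tab[rec, ],
       indices = list(ligand = lig, receptor = rec))
}
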