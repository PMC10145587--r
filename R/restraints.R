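#' Six-degree-of-freedom orientational restraint specification
#'
#' Boresch-style restraint over three receptor atoms (a, b, c) and three
#' ligand atoms (A, B, C): one distance r = |aA|, two angles
#' theta = angle(b,a,A) and Theta = angle(a,A,B), and three dihedrals
#' phi = dih(c,b,a,A), Phi = dih(b,a,A,B), Psi = dih(a,A,B,C). Force
#' constants are taken in the units MD packages print (kJ/mol/nm^2 for the
#' distance, kJ/mol/rad^2 for the five angular terms) and converted
#' internally to kcal/mol.
#'
#' @param receptor_atoms list of three atom identifiers `a`, `b`, `c`,
#'   each `list(chain =, resid =, name =)`
#' @param ligand_atoms list of three atom identifiers `A`, `B`, `C`
#' @param k_r distance force constant, kJ/mol/nm^2
#' @param k_theta,k_phi,k_Theta,k_Phi,k_Psi angular force constants,
#'   kJ/mol/rad^2
#' @param r0 reference distance (A); `NA` until set
#' @param theta0,Theta0 reference angles (rad, in (0, pi))
#' @param phi0,Phi0,Psi0 reference dihedrals (rad, in (-pi, pi])
#' @return object of class `restraint_spec`
#' @export
restraint_spec <- function(receptor_atoms = NULL, ligand_atoms = NULL,
                           k_r = 1000, k_theta = 1000, k_phi = 1000,
                           k_Theta = 1000, k_Phi = 1000, k_Psi = 1000,
                           r0 = NA_real_, theta0 = NA_real_, Theta0 = NA_real_,
                           phi0 = NA_real_, Phi0 = NA_real_, Psi0 = NA_real_) {
  ks <- c(k_r = k_r, k_theta = k_theta, k_phi = k_phi,
          k_Theta = k_Theta, k_Phi = k_Phi, k_Psi = k_Psi)
  if (any(ks <= 0)) stop("all restraint force constants must be > 0")
  for (ang in c(theta0, Theta0)) {
    if (!is.na(ang) && (ang <= 0 || ang >= pi)) stop("reference angles must lie in (0, pi)")
  }
  for (dih in c(phi0, Phi0, Psi0)) {
    if (!is.na(dih) && (dih <= -pi || dih > pi)) stop("reference dihedrals must lie in (-pi, pi]")
  }
  structure(list(receptor_atoms = receptor_atoms, ligand_atoms = ligand_atoms,
                 k_r = k_r, k_theta = k_theta, k_phi = k_phi,
                 k_Theta = k_Theta, k_Phi = k_Phi, k_Psi = k_Psi,
                 r0 = r0, theta0 = theta0, Theta0 = Theta0,
                 phi0 = phi0, Phi0 = Phi0, Psi0 = Psi0),
            class = "restraint_spec")
}

#' @export
print.restraint_spec <- function(x, ...) {
  cat("<restraint_spec>\n")
  cat(sprintf("  k_r = %g kJ/mol/nm^2; angular k = (%g, %g, %g, %g, %g) kJ/mol/rad^2\n",
              x$k_r, x$k_theta, x$k_phi, x$k_Theta, x$k_Phi, x$k_Psi))
  cat(sprintf("  references: r0 = %.4g A, theta0 = %.4g, Theta0 = %.4g, phi0 = %.4g, Phi0 = %.4g, Psi0 = %.4g rad\n",
              x$r0, x$theta0, x$Theta0, x$phi0, x$Phi0, x$Psi0))
  invisible(x)
}

vnorm <- function(v) sqrt(sum(v^2))

# angle at q spanned by p and s, in (0, pi); errors on degenerate geometry
angle3 <- function(p, q, s, label = "") {
  u <- p - q
  v <- s - q
  nu <- vnorm(u)
  nv <- vnorm(v)
  if (nu < 1e-10 || nv < 1e-10) stop("coincident atoms in angle ", label)
  cross <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
  atan2(vnorm(cross), sum(u * v))
}

# signed dihedral p1-p2-p3-p4 in (-pi, pi] via atan2 (full quadrant)
dihedral4 <- function(p1, p2, p3, p4, label = "") {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  c12 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
           b1[1] * b2[2] - b1[2] * b2[1])
  c23 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
           b2[1] * b3[2] - b2[2] * b3[1])
  if (vnorm(c12) < 1e-10 || vnorm(c23) < 1e-10) {
    stop("collinear atom triplet makes dihedral ", label, " undefined")
  }
  x <- sum(c12 * c23)
  y <- sum(b1 * c23) * vnorm(b2)
  atan2(y, x)
}

resolve_restraint_atoms <- function(ensemble, spec) {
  ids <- c(spec$receptor_atoms[c("a", "b", "c")],
           spec$ligand_atoms[c("A", "B", "C")])
  vapply(ids, function(id) atom_index(ensemble, id$chain, id$resid, id$name),
         integer(1))
}

#' Internal restraint coordinates of one frame
#'
#' @param frame either a `structure_ensemble` (with `frame` selecting the
#'   model, atoms resolved through the spec's identifiers) or a 6 x 3
#'   matrix of positions in the row order a, b, c, A, B, C
#' @param spec a [restraint_spec()]
#' @param frame_index model index when `frame` is an ensemble
#' @return object of class `internal_coords`: `r` (A), `theta`, `Theta`,
#'   `phi`, `Phi`, `Psi` (rad)
#' @export
internal_coords <- function(frame, spec = NULL, frame_index = 1) {
  if (inherits(frame, "structure_ensemble")) {
    stopifnot(inherits(spec, "restraint_spec"))
    xyz <- frame_coords(frame, frame_index)[resolve_restraint_atoms(frame, spec), ]
  } else {
    xyz <- as.matrix(frame)
  }
  stopifnot(nrow(xyz) == 6, ncol(xyz) == 3, all(is.finite(xyz)))
  a <- xyz[1, ]; b <- xyz[2, ]; cc <- xyz[3, ]
  A <- xyz[4, ]; B <- xyz[5, ]; C <- xyz[6, ]
  r <- vnorm(a - A)
  if (r < 1e-10) stop("anchor atoms a and A coincide")
  structure(list(
    r = r,
    theta = angle3(b, a, A, "theta (b,a,A)"),
    Theta = angle3(a, A, B, "Theta (a,A,B)"),
    phi = dihedral4(cc, b, a, A, "phi (c,b,a,A)"),
    Phi = dihedral4(b, a, A, B, "Phi (b,a,A,B)"),
    Psi = dihedral4(a, A, B, C, "Psi (a,A,B,C)")),
    class = "internal_coords")
}

# wrap an angular difference into (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Restraint energy of a configuration at coupling lambda
#'
#' Linear coupling: E = lambda * sum of harmonic terms k/2 (x - x0)^2 over
#' the six internal coordinates, dihedral differences wrapped to
#' (-pi, pi]. Returned in kcal/mol.
#'
#' @param coords an [internal_coords()] result
#' @param spec a [restraint_spec()] with all references set
#' @param lam coupling strength in `[0, 1]` (0 = no restraint)
#' @return energy in kcal/mol
#' @export
restraint_energy <- function(coords, spec, lam = 1) {
  stopifnot(inherits(coords, "internal_coords"), inherits(spec, "restraint_spec"),
            lam >= 0, lam <= 1)
  refs <- c(spec$r0, spec$theta0, spec$Theta0, spec$phi0, spec$Phi0, spec$Psi0)
  if (anyNA(refs)) stop("restraint references are not all set")
  e <- 0.5 * k_dist_to_kcal(spec$k_r) * (coords$r - spec$r0)^2 +
    0.5 * k_ang_to_kcal(spec$k_theta) * (coords$theta - spec$theta0)^2 +
    0.5 * k_ang_to_kcal(spec$k_Theta) * (coords$Theta - spec$Theta0)^2 +
    0.5 * k_ang_to_kcal(spec$k_phi) * wrap_pi(coords$phi - spec$phi0)^2 +
    0.5 * k_ang_to_kcal(spec$k_Phi) * wrap_pi(coords$Phi - spec$Phi0)^2 +
    0.5 * k_ang_to_kcal(spec$k_Psi) * wrap_pi(coords$Psi - spec$Psi0)^2
  lam * e
}

circular_mean <- function(x) {
  s <- mean(sin(x))
  c <- mean(cos(x))
  list(mean = atan2(s, c), resultant = sqrt(s^2 + c^2))
}

#' Fill restraint reference values from an unconstrained ensemble
#'
#' Reference values are the ensemble averages of the internal coordinates
#' over the supplied frames (the bound-state simulation): arithmetic
#' means for r, theta and Theta; circular means for the three dihedrals.
#' A dispersion report (sd for linear coordinates, resultant length for
#' dihedrals) is attached as attribute `"dispersion"`.
#'
#' @param ensemble a [structure_ensemble()] with >= 2 frames
#' @param spec a [restraint_spec()] with atom identifiers set
#' @return the spec with `r0 ... Psi0` filled
#' @export
reference_from_ensemble <- function(ensemble, spec) {
  stopifnot(inherits(ensemble, "structure_ensemble"), n_frames(ensemble) >= 2)
  coords <- lapply(seq_len(n_frames(ensemble)), function(i) {
    internal_coords(ensemble, spec, i)
  })
  getv <- function(field) vapply(coords, `[[`, numeric(1), field)
  disp <- list()
  for (f in c("r", "theta", "Theta")) {
    spec[[paste0(f, "0")]] <- mean(getv(f))
    disp[[f]] <- stats::sd(getv(f))
  }
  for (f in c("phi", "Phi", "Psi")) {
    cm <- circular_mean(getv(f))
    if (cm$resultant < 0.1) {
      stop(sprintf(
        "dihedral %s is too dispersed (resultant length %.3f < 0.1): circular mean degenerate",
        f, cm$resultant))
    }
    spec[[paste0(f, "0")]] <- cm$mean
    disp[[f]] <- cm$resultant
  }
  attr(spec, "dispersion") <- disp
  spec
}

#' Analytic standard-state bulk restraint free energy
#'
#' Free energy of imposing the six harmonic restraints on a ligand free
#' in solution at reference concentration C0 (rigid-rotor closed form):
#' \deqn{\Delta G_{restr}^{bulk} = k_B T \ln\!\left[
#'   \frac{8\pi^2 V_0}{r^{*2}\sin\theta_0 \sin\Theta_0}
#'   \frac{\sqrt{k_r k_\theta k_\phi k_\Theta k_\Phi k_\Psi}}
#'        {(2\pi k_B T)^{3}}\right]}
#' Positive for typical force constants: it costs free energy to confine a
#' freely rotating/translating molecule. Enters the binding free energy
#' with a plus sign.
#'
#' @param spec a [restraint_spec()]; only force constants and the two
#'   reference angles are used
#' @param temperature temperature in K
#' @param standard_conc reference concentration in mol/L
#' @param r_star the distance (A) at which the ligand is considered in
#'   bulk (the restraint's reference distance there)
#' @param sin_theta0,sin_Theta0 optional overrides for the reference-angle
#'   sines (default: from the spec's angles)
#' @return free energy in kcal/mol
#' @export
bulk_restraint_term <- function(spec, temperature = 300, standard_conc = 1,
                                r_star, sin_theta0 = NULL, sin_Theta0 = NULL) {
  stopifnot(inherits(spec, "restraint_spec"), r_star > 0)
  if (is.null(sin_theta0)) sin_theta0 <- sin(spec$theta0)
  if (is.null(sin_Theta0)) sin_Theta0 <- sin(spec$Theta0)
  if (is.na(sin_theta0) || is.na(sin_Theta0) || sin_theta0 <= 0 || sin_Theta0 <= 0) {
    stop("sin(theta0) and sin(Theta0) must be positive and set")
  }
  kt <- kBT(temperature)
  v0 <- standard_volume(standard_conc)
  k_prod <- k_dist_to_kcal(spec$k_r) *
    k_ang_to_kcal(spec$k_theta) * k_ang_to_kcal(spec$k_phi) *
    k_ang_to_kcal(spec$k_Theta) * k_ang_to_kcal(spec$k_Phi) *
    k_ang_to_kcal(spec$k_Psi)
  kt * log(8 * pi^2 * v0 * sqrt(k_prod) /
             (r_star^2 * sin_theta0 * sin_Theta0 * (2 * pi * kt)^3))
}
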