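#' Analytic one-dimensional potentials
#'
#' A small family of closed-form potentials used as ground truth for the
#' toy sampler and every downstream estimator. Energies are in kcal/mol
#' (or any consistent unit; the sampler only ever uses V/kT) and the
#' coordinate is in angstrom or reduced units as declared per instance.
#'
#' Forms:
#' \describe{
#'   \item{flat}{V = 0 on `[xmin, xmax]` (bounds required).}
#'   \item{harmonic}{V = k/2 (x - x0)^2.}
#'   \item{double_well}{V = h ((x - x0)^2 - a^2)^2 / a^4: minima at
#'     x0 +- a with V = 0, barrier of height h at x0.}
#'   \item{piecewise_pmf}{continuous linear interpolation through knots
#'     `(x, w)`; infinite outside the knot range (confining).}
#' }
#'
#' @param form one of `"flat"`, `"harmonic"`, `"double_well"`,
#'   `"piecewise_pmf"`
#' @param k harmonic force constant (energy per length^2)
#' @param x0 center of the harmonic / double-well form
#' @param h barrier height of the double well
#' @param a half-separation of the double-well minima
#' @param knots_x,knots_w knot coordinates and energies for
#'   `piecewise_pmf`; `knots_x` strictly increasing
#' @param support optional `c(xmin, xmax)` bounds outside which the
#'   potential is infinite; required for `flat`
#' @return an object of class `analytic_potential`
#' @examples
#' pot <- analytic_potential("harmonic", k = 1, x0 = 0)
#' potential_energy(pot, c(-1, 0, 2))
#' @export
analytic_potential <- function(form = c("flat", "harmonic", "double_well", "piecewise_pmf"),
                               k = 1, x0 = 0, h = 1, a = 1,
                               knots_x = NULL, knots_w = NULL,
                               support = NULL) {
  form <- match.arg(form)
  if (!is.null(support)) {
    stopifnot(length(support) == 2, support[1] < support[2])
  }
  if (form == "flat" && is.null(support)) {
    stop("a 'flat' potential is not confining: bounds via `support` are required")
  }
  if (form == "piecewise_pmf") {
    stopifnot(!is.null(knots_x), !is.null(knots_w),
              length(knots_x) == length(knots_w), length(knots_x) >= 2)
    if (any(diff(knots_x) <= 0)) stop("piecewise_pmf knots_x must be strictly increasing")
    if (any(!is.finite(knots_w))) stop("piecewise_pmf energies must be finite")
    if (is.null(support)) support <- range(knots_x)
  }
  if (form == "harmonic") stopifnot(k > 0)
  if (form == "double_well") stopifnot(h > 0, a > 0)
  structure(
    list(form = form, k = k, x0 = x0, h = h, a = a,
         knots_x = knots_x, knots_w = knots_w, support = support),
    class = "analytic_potential"
  )
}

#' Evaluate an analytic potential
#'
#' @param pot an [analytic_potential()]
#' @param x numeric coordinates
#' @return energies; `Inf` outside the declared support
#' @export
potential_energy <- function(pot, x) {
  stopifnot(inherits(pot, "analytic_potential"))
  v <- switch(pot$form,
    flat = rep(0, length(x)),
    harmonic = 0.5 * pot$k * (x - pot$x0)^2,
    double_well = pot$h * ((x - pot$x0)^2 - pot$a^2)^2 / pot$a^4,
    piecewise_pmf = stats::approx(pot$knots_x, pot$knots_w, xout = x,
                                  rule = 1)$y
  )
  if (pot$form == "piecewise_pmf") v[is.na(v)] <- Inf
  if (!is.null(pot$support)) {
    v[x < pot$support[1] | x > pot$support[2]] <- Inf
  }
  v
}

#' Is the potential (optionally plus a harmonic bias) confining?
#'
#' Used by the sampler to reject unbounded problems: a potential confines
#' if it has finite support bounds, grows at both ends (harmonic,
#' double_well), or a harmonic bias is applied.
#' @param pot an [analytic_potential()]
#' @param has_bias whether a harmonic bias is being added
#' @return logical
#' @keywords internal
is_confining <- function(pot, has_bias = FALSE) {
  if (!is.null(pot$support)) return(TRUE)
  if (pot$form %in% c("harmonic", "double_well")) return(TRUE)
  has_bias
}

#' Boltzmann expectation by direct quadrature
#'
#' Independent oracle for sampler moments: computes E[f(x)] under
#' exp(-(V + bias)/kT) by trapezoidal integration on a fine grid.
#'
#' @param pot an [analytic_potential()]
#' @param f function of the coordinate
#' @param kt thermal energy in the potential's energy units
#' @param bias optional list(center, k) harmonic bias
#' @param lower,upper integration range (defaults to support)
#' @param n grid size
#' @return the expectation value
#' @export
boltzmann_expectation <- function(pot, f, kt, bias = NULL,
                                  lower = NULL, upper = NULL, n = 20001) {
  rng <- if (!is.null(pot$support)) pot$support else c(lower, upper)
  if (is.null(lower)) lower <- rng[1]
  if (is.null(upper)) upper <- rng[2]
  stopifnot(is.finite(lower), is.finite(upper), lower < upper)
  x <- seq(lower, upper, length.out = n)
  u <- potential_energy(pot, x)
  if (!is.null(bias)) u <- u + 0.5 * bias$k * (x - bias$center)^2
  w <- exp(-(u - min(u[is.finite(u)])) / kt)
  w[!is.finite(w)] <- 0
  dx <- x[2] - x[1]
  z <- sum(w) * dx
  sum(f(x) * w) * dx / z
}
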