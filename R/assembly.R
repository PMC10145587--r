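#' Signed components of the absolute binding free energy
#'
#' The four terms of the thermodynamic-cycle decomposition, each carried
#' with the sign it takes in the total:
#' \deqn{\Delta G^\circ_{bind} = -\Delta G_{restr}^{bound} - w(r^*)
#'   - k_BT\ln\!\left[\int_{bound} e^{-w(r)/k_BT} dr\,
#'   (2\pi k_BT/k_r)^{-1/2}\right] + \Delta G_{restr}^{bulk}}
#'
#' @param minus_dg_restr_bound the -dG_restr(bound) term, kcal/mol
#'   (negative for a restraint that costs free energy to impose)
#' @param pmf_depth_term the -w(r*) term, kcal/mol (negative for a bound
#'   ligand)
#' @param volume_term the bound-volume (third) term, kcal/mol
#' @param dg_restr_bulk the +dG_restr(bulk) analytic term, kcal/mol
#' @param stderrs numeric vector of four standard errors in the same
#'   order (defaults to zeros)
#' @param temperature temperature in K
#' @return object of class `free_energy_components`
#' @export
free_energy_components <- function(minus_dg_restr_bound, pmf_depth_term,
                                   volume_term, dg_restr_bulk,
                                   stderrs = c(0, 0, 0, 0),
                                   temperature = 300) {
  vals <- c(minus_dg_restr_bound, pmf_depth_term, volume_term, dg_restr_bulk)
  stopifnot(all(is.finite(vals)), length(stderrs) == 4, all(stderrs >= 0),
            temperature > 0)
  structure(list(minus_dg_restr_bound = minus_dg_restr_bound,
                 pmf_depth_term = pmf_depth_term,
                 volume_term = volume_term,
                 dg_restr_bulk = dg_restr_bulk,
                 stderrs = as.numeric(stderrs),
                 temperature = temperature),
            class = "free_energy_components")
}

#' Quadrature error propagation
#'
#' Combines independent component standard errors as the square root of
#' the sum of squares.
#'
#' @param stderrs non-negative standard errors
#' @return combined standard error
#' @export
propagate_error <- function(stderrs) {
  stopifnot(all(stderrs >= 0))
  sqrt(sum(stderrs^2))
}

#' Convert a binding free energy to association constants
#'
#' Ka = exp(-dG/kT) relative to the 1 M standard state.
#'
#' @param dg_bind standard binding free energy, kcal/mol
#' @param temperature temperature in K
#' @return list with `ka_molar` (1/M) and `ka_nanomolar` (1/nM)
#' @export
to_association_constant <- function(dg_bind, temperature = 300) {
  stopifnot(temperature > 0)
  ka <- exp(-dg_bind / kBT(temperature))
  list(ka_molar = ka, ka_nanomolar = ka * 1e-9)
}

#' Assemble the absolute binding free energy
#'
#' Sums the four signed components, propagates their uncertainties in
#' quadrature, and converts to association constants.
#'
#' @param components a [free_energy_components()]
#' @return object of class `binding_report`: `dg_bind`, `stderr`
#'   (kcal/mol), `ka_molar`, `ka_nanomolar`, `components`, `temperature`
#' @export
assemble <- function(components) {
  stopifnot(inherits(components, "free_energy_components"))
  dg <- components$minus_dg_restr_bound + components$pmf_depth_term +
    components$volume_term + components$dg_restr_bulk
  ka <- to_association_constant(dg, components$temperature)
  structure(list(dg_bind = dg,
                 stderr = propagate_error(components$stderrs),
                 ka_molar = ka$ka_molar,
                 ka_nanomolar = ka$ka_nanomolar,
                 components = components,
                 temperature = components$temperature),
            class = "binding_report")
}

#' @export
print.binding_report <- function(x, ...) {
  c_ <- x$components
  cat("<binding_report>\n")
  cat(sprintf("  -dG_restr(bound)   %10.3f (+- %.4g) kcal/mol\n",
              c_$minus_dg_restr_bound, c_$stderrs[1]))
  cat(sprintf("  -w(r*)             %10.3f (+- %.4g) kcal/mol\n",
              c_$pmf_depth_term, c_$stderrs[2]))
  cat(sprintf("  volume term        %10.3f (+- %.4g) kcal/mol\n",
              c_$volume_term, c_$stderrs[3]))
  cat(sprintf("  +dG_restr(bulk)    %10.3f (+- %.4g) kcal/mol\n",
              c_$dg_restr_bulk, c_$stderrs[4]))
  cat(sprintf("  dG_bind            %10.3f (+- %.3f) kcal/mol at %g K\n",
              x$dg_bind, x$stderr, x$temperature))
  cat(sprintf("  Ka = %.4g 1/M = %.3f 1/nM\n", x$ka_molar, x$ka_nanomolar))
  invisible(x)
}

#' Fold change in association constant between two systems
#'
#' Ratio Ka(a) / Ka(b) = exp((dG_b - dG_a)/kT); both reports must share a
#' temperature.
#'
#' @param report_a,report_b [assemble()] results at the same temperature
#' @return the ratio (> 1 when a binds more strongly)
#' @export
fold_change <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "binding_report"),
            inherits(report_b, "binding_report"))
  if (report_a$temperature != report_b$temperature) {
    stop("fold change requires both reports at the same temperature")
  }
  report_a$ka_molar / report_b$ka_molar
}
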