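#' Toy sampler configuration
#'
#' Settings for the Metropolis random-walk Monte Carlo sampler that stands
#' in for the MD engine. "Time" is the sample index. Burn-in defaults to
#' 10% of the requested samples; stride 1 keeps every post-burn-in state.
#'
#' @param temperature temperature in K
#' @param n_samples number of retained samples (> 0)
#' @param burn_in discarded initial steps; default `ceiling(0.1 * n_samples * stride)`
#' @param stride keep every stride-th state
#' @param step_size uniform proposal half-width in coordinate units
#' @param seed master RNG seed (integer)
#' @return object of class `sampler_config`
#' @export
sampler_config <- function(temperature = 300, n_samples = 10000,
                           burn_in = NULL, stride = 1L,
                           step_size = 0.5, seed = 1L) {
  stopifnot(temperature > 0, n_samples > 0, stride >= 1, step_size > 0)
  if (is.null(burn_in)) burn_in <- ceiling(0.1 * n_samples * stride)
  stopifnot(burn_in >= 0)
  structure(list(temperature = temperature, n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), stride = as.integer(stride),
                 step_size = step_size, seed = as.integer(seed)),
            class = "sampler_config")
}

form_code <- function(form) {
  match(form, c("flat", "harmonic", "double_well", "piecewise_pmf")) - 1L
}

default_start <- function(pot, bias = NULL) {
  if (!is.null(bias)) return(bias$center)
  switch(pot$form,
    flat = mean(pot$support),
    harmonic = pot$x0,
    double_well = pot$x0 + pot$a,
    piecewise_pmf = pot$knots_x[which.min(pot$knots_w)]
  )
}

#' Sample a Boltzmann distribution by Metropolis Monte Carlo
#'
#' Draws from exp(-(V + bias)/kT) with a uniform random-walk proposal.
#' Exact stationary distribution, deterministic under the config seed.
#' The acceptance fraction is recorded in the series metadata and a
#' warning is raised when it leaves (0.05, 0.95), the range in which the
#' chain mixes usefully.
#'
#' @param potential an [analytic_potential()]
#' @param bias optional harmonic bias `list(center =, k =)` with k in the
#'   potential's energy units per length^2 (already converted)
#' @param config a [sampler_config()]
#' @param x_init starting coordinate; defaults to the minimum (or bias
#'   center)
#' @return [sample_series()] of coordinates; metadata holds `acceptance`
#'   and `temperature`
#' @examples
#' pot <- analytic_potential("harmonic", k = 1)
#' s <- sample_boltzmann(pot, config = sampler_config(
#'   temperature = 1 / KB_KCAL, n_samples = 1000, seed = 42))
#' var(s$value) # ~ 1
#' @export
sample_boltzmann <- function(potential, bias = NULL, config = sampler_config(),
                             x_init = NULL) {
  stopifnot(inherits(potential, "analytic_potential"),
            inherits(config, "sampler_config"))
  if (!is.null(bias)) stopifnot(is.numeric(bias$center), bias$k >= 0)
  if (!is_confining(potential, has_bias = !is.null(bias) && bias$k > 0)) {
    stop("potential is not confining and no bounds or harmonic bias given")
  }
  if (is.null(x_init)) x_init <- default_start(potential, bias)
  sup <- if (is.null(potential$support)) c(-Inf, Inf) else potential$support
  kt <- kBT(config$temperature)
  set.seed(config$seed)
  res <- metropolis_chain_cpp(
    form_code(potential$form), potential$k, potential$x0, potential$h,
    potential$a,
    if (is.null(potential$knots_x)) numeric(0) else potential$knots_x,
    if (is.null(potential$knots_w)) numeric(0) else potential$knots_w,
    sup[1], sup[2],
    !is.null(bias) && bias$k > 0,
    if (is.null(bias)) 0 else bias$center,
    if (is.null(bias)) 0 else bias$k,
    kt, x_init, config$step_size,
    config$n_samples, config$burn_in, config$stride
  )
  acc <- res$n_accept / res$n_steps
  if (acc <= 0.05 || acc >= 0.95) {
    warning(sprintf(
      "Metropolis acceptance fraction %.3f outside (0.05, 0.95); tune step_size",
      acc))
  }
  sample_series(res$samples, seed = config$seed,
                meta = list(acceptance = acc,
                            temperature = config$temperature))
}

# deterministic per-window sub-seeds below 2^31, derived from the master seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Umbrella-sampling window
#'
#' One biased simulation: a harmonic restraint of strength `force_constant`
#' centered at `center`, with the sampled reaction-coordinate series.
#' Force constants are given in kJ/mol/nm^2 as in MD pull codes and stored
#' converted to kcal/mol/A^2.
#'
#' @param center bias center in A
#' @param force_constant in kJ/mol/nm^2 unless `units = "kcal_A2"`
#' @param samples a [sample_series()] of reaction-coordinate values (A)
#' @param units `"kJ_nm2"` (default) or `"kcal_A2"`
#' @return object of class `umbrella_window`
#' @export
umbrella_window <- function(center, force_constant, samples,
                            units = c("kJ_nm2", "kcal_A2")) {
  units <- match.arg(units)
  stopifnot(force_constant > 0, inherits(samples, "sample_series"),
            length(samples) > 0)
  k_kcal <- if (units == "kJ_nm2") k_dist_to_kcal(force_constant) else force_constant
  structure(list(center = center, k_kcal = k_kcal,
                 k_input = force_constant, k_units = units,
                 samples = samples),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window> center = %.3g A, k = %.4g kcal/mol/A^2, n = %d\n",
              x$center, x$k_kcal, length(x$samples)))
  invisible(x)
}

#' Generate a synthetic umbrella-sampling dataset
#'
#' One Metropolis run per window center, each with an independent
#' sub-seed derived from the master seed, biased by the harmonic umbrella
#' potential. With 1 A spacing and the conventional 1000 kJ/mol/nm^2
#' force constant at 300 K, adjacent windows overlap.
#'
#' @param potential the underlying [analytic_potential()] (the true PMF)
#' @param centers strictly increasing window centers (A)
#' @param force_constant umbrella force constant in kJ/mol/nm^2 (or
#'   kcal/mol/A^2 with `units = "kcal_A2"`)
#' @param config a [sampler_config()]; its seed is the master seed
#' @param units unit of `force_constant`
#' @return list of [umbrella_window()]
#' @export
generate_umbrella_dataset <- function(potential, centers,
                                      force_constant = 1000,
                                      config = sampler_config(),
                                      units = c("kJ_nm2", "kcal_A2")) {
  units <- match.arg(units)
  if (length(centers) == 0) stop("empty centers list")
  if (any(diff(centers) <= 0)) stop("centers must be strictly increasing")
  k_kcal <- if (units == "kJ_nm2") k_dist_to_kcal(force_constant) else force_constant
  seeds <- derive_seeds(config$seed, length(centers))
  lapply(seq_along(centers), function(i) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    s <- sample_boltzmann(potential, bias = list(center = centers[i], k = k_kcal),
                          config = cfg_i)
    umbrella_window(centers[i], force_constant, s, units = units)
  })
}

#' Forward/reverse energy-difference samples between adjacent lambda states
#'
#' @param lambda_low,lambda_high coupling values in `[0, 1]`, low < high
#' @param du_forward energy differences U(high) - U(low) evaluated on
#'   low-lambda configurations (kcal/mol)
#' @param du_reverse energy differences U(low) - U(high) evaluated on
#'   high-lambda configurations (kcal/mol)
#' @param temperature temperature in K
#' @return object of class `lambda_pair`
#' @export
lambda_pair <- function(lambda_low, lambda_high, du_forward, du_reverse,
                        temperature = 300) {
  stopifnot(lambda_low >= 0, lambda_high <= 1, lambda_low < lambda_high,
            length(du_forward) > 0, length(du_reverse) > 0, temperature > 0)
  if (inherits(du_forward, "sample_series")) du_forward <- du_forward$value
  if (inherits(du_reverse, "sample_series")) du_reverse <- du_reverse$value
  structure(list(lambda_low = lambda_low, lambda_high = lambda_high,
                 du_forward = as.numeric(du_forward),
                 du_reverse = as.numeric(du_reverse),
                 temperature = temperature),
            class = "lambda_pair")
}

#' Generate a synthetic restraint-switching (lambda) dataset
#'
#' Simulates linear coupling H(lambda) = H0 + lambda * U_restr where
#' U_restr is a harmonic restraint `list(center =, k =)` (k in the
#' potential's energy units per length^2). For each adjacent schedule pair
#' the forward difference (lambda_high - lambda_low) * U_restr(x) is
#' evaluated on configurations sampled at the low endpoint, and the
#' reverse difference -(lambda_high - lambda_low) * U_restr(x) on
#' configurations sampled at the high endpoint.
#'
#' @param potential base [analytic_potential()] (H0)
#' @param restraint harmonic restraint `list(center =, k =)`; `k = 0`
#'   means no restraint
#' @param schedule sorted lambda values starting at 0 and ending at 1
#' @param config a [sampler_config()]
#' @return list of [lambda_pair()] (length `length(schedule) - 1`)
#' @export
generate_lambda_dataset <- function(potential, restraint, schedule,
                                    config = sampler_config()) {
  stopifnot(length(schedule) >= 2)
  if (is.unsorted(schedule, strictly = TRUE)) stop("schedule must be sorted, strictly increasing")
  if (schedule[1] != 0 || schedule[length(schedule)] != 1) {
    stop("schedule must start at 0 and end at 1")
  }
  stopifnot(is.numeric(restraint$center), restraint$k >= 0)
  u_restr <- function(x) 0.5 * restraint$k * (x - restraint$center)^2
  seeds <- derive_seeds(config$seed, length(schedule))
  draws <- lapply(seq_along(schedule), function(i) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    lam <- schedule[i]
    bias <- if (restraint$k * lam > 0) {
      list(center = restraint$center, k = restraint$k * lam)
    } else NULL
    sample_boltzmann(potential, bias = bias, config = cfg_i)
  })
  lapply(seq_len(length(schedule) - 1), function(i) {
    dlam <- schedule[i + 1] - schedule[i]
    lambda_pair(schedule[i], schedule[i + 1],
                du_forward = dlam * u_restr(draws[[i]]$value),
                du_reverse = -dlam * u_restr(draws[[i + 1]]$value),
                temperature = config$temperature)
  })
}
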