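#' Fermi function
#'
#' f(x) = 1 / (1 + exp(x / kT)), the weighting function at the heart of
#' the Bennett acceptance ratio. With the default `kt = 1` the argument is
#' in units of kT.
#'
#' @param x energy argument
#' @param kt thermal energy in the same units as `x`
#' @return values in (0, 1); satisfies f(x) + f(-x) = 1
#' @export
fermi <- function(x, kt = 1) {
  stopifnot(kt > 0)
  1 / (1 + exp(x / kt))
}

#' Bennett acceptance ratio estimate for one pair of states
#'
#' Solves the Bennett self-consistency equation
#' \deqn{\sum_F f(M + (\Delta U_F - \Delta G)/kT) =
#'       \sum_R f(-M + (\Delta U_R + \Delta G)/kT)}
#' with M = ln(n_F / n_R), by bisection (the left side minus the right is
#' monotone in \eqn{\Delta G}). The standard error is the asymptotic BAR
#' variance; with `block_size > 1` the samples are first block-averaged to
#' tame autocorrelation (a deliberate substitute for dH/dlambda
#' fluctuation formulas, which depend on unpublished details).
#'
#' @param pair a [lambda_pair()]
#' @param tol convergence tolerance on delta_g in kcal/mol
#' @param max_iter maximum bisection iterations
#' @param block_size optional contiguous block length for a
#'   block-averaged variance estimate (1 = plain asymptotic variance)
#' @return object of class `bar_estimate` with fields `delta_g`, `stderr`
#'   (kcal/mol), `constant_c`, `n_forward`, `n_reverse`,
#'   `overlap_warning`, `residual`
#' @export
bar_pair <- function(pair, tol = 1e-8, max_iter = 500L, block_size = 1L) {
  stopifnot(inherits(pair, "lambda_pair"), tol > 0, max_iter >= 1)
  kt <- kBT(pair$temperature)
  wf <- pair$du_forward / kt
  wr <- pair$du_reverse / kt
  nf <- length(wf)
  nr <- length(wr)
  m <- log(nf / nr)

  # sum_F fermi(...) - sum_R fermi(...): monotone increasing in the reduced
  # free energy f, so a sign change brackets the unique root
  imbalance <- function(f) {
    sum(fermi(m + wf - f)) - sum(fermi(-m + wr + f))
  }
  lo <- -1
  hi <- 1
  while (imbalance(lo) > 0) lo <- lo * 2
  while (imbalance(hi) < 0) hi <- hi * 2
  if (!is.finite(lo) || !is.finite(hi)) stop("BAR bracketing failed")
  rtol <- tol / kt
  iter <- 0L
  while (hi - lo > rtol) {
    iter <- iter + 1L
    if (iter > max_iter) stop("BAR bisection did not converge in max_iter iterations")
    mid <- (lo + hi) / 2
    if (imbalance(mid) < 0) lo <- mid else hi <- mid
  }
  f_hat <- (lo + hi) / 2
  dg <- f_hat * kt

  # poor phase-space overlap: forward work and negated reverse work
  # distributions do not even share a range
  overlap_warning <- (min(wf) > max(-wr)) || (min(-wr) > max(wf))

  stderr <- bar_stderr(wf, wr, m, f_hat, kt, block_size)

  structure(list(delta_g = dg, stderr = stderr,
                 constant_c = dg + kt * log(nr / nf),
                 n_forward = nf, n_reverse = nr,
                 overlap_warning = overlap_warning,
                 residual = imbalance(f_hat) / max(nf, nr),
                 temperature = pair$temperature,
                 lambda_low = pair$lambda_low,
                 lambda_high = pair$lambda_high),
            class = "bar_estimate")
}

# Bennett's asymptotic variance evaluated at the self-consistent solution.
# With block_size > 1 the Fermi weights are averaged over contiguous blocks
# before computing the relative variances (correlated-input option).
bar_stderr <- function(wf, wr, m, f_hat, kt, block_size = 1L) {
  ff <- fermi(m + wf - f_hat)
  fr <- fermi(-m + wr + f_hat)
  if (block_size > 1L) {
    ff <- block_means(ff, block_size)
    fr <- block_means(fr, block_size)
  }
  relvar <- function(x) {
    mu <- mean(x)
    if (mu == 0) return(Inf)
    v <- mean(x^2) / mu^2 - 1
    max(v, 0) / length(x)
  }
  kt * sqrt(relvar(ff) + relvar(fr))
}

block_means <- function(x, size) {
  n_blocks <- length(x) %/% size
  if (n_blocks < 2) stop("too few samples for block averaging")
  x <- x[seq_len(n_blocks * size)]
  colMeans(matrix(x, nrow = size))
}

#' @export
print.bar_estimate <- function(x, ...) {
  cat(sprintf("<bar_estimate> lambda %.3g -> %.3g: dG = %.4f +- %.4f kcal/mol%s\n",
              x$lambda_low, x$lambda_high, x$delta_g, x$stderr,
              if (x$overlap_warning) " [LOW OVERLAP]" else ""))
  invisible(x)
}

#' One-sided exponential averaging (Zwanzig) free-energy estimate
#'
#' Reference estimator used to benchmark BAR: dG = -kT ln <exp(-dU/kT)>
#' over the forward samples (or the negated result from the reverse
#' direction).
#'
#' @param du energy differences in kcal/mol
#' @param temperature temperature in K
#' @return free-energy difference in kcal/mol
#' @export
zwanzig <- function(du, temperature = 300) {
  kt <- kBT(temperature)
  w <- -du / kt
  # log-sum-exp for stability
  wm <- max(w)
  -kt * (wm + log(mean(exp(w - wm))))
}

#' Chain BAR estimates over a full lambda schedule
#'
#' Verifies the pairs tile a contiguous schedule from 0 to 1, estimates
#' each pair, and reports the summed free energy with quadrature-combined
#' standard errors.
#'
#' @param pairs list of [lambda_pair()]
#' @param tol,max_iter,block_size passed to [bar_pair()]
#' @return object of class `restraint_switching_result` with fields
#'   `estimates` (list of `bar_estimate`), `total`, `total_stderr`,
#'   `schedule`, and a per-pair `table` data frame
#' @export
bar_chain <- function(pairs, tol = 1e-8, max_iter = 500L, block_size = 1L) {
  stopifnot(length(pairs) >= 1)
  lo <- vapply(pairs, function(p) p$lambda_low, numeric(1))
  hi <- vapply(pairs, function(p) p$lambda_high, numeric(1))
  o <- order(lo)
  pairs <- pairs[o]
  lo <- lo[o]
  hi <- hi[o]
  if (lo[1] != 0 || hi[length(hi)] != 1) {
    stop("schedule must cover [0, 1]; got [", lo[1], ", ", hi[length(hi)], "]")
  }
  if (length(pairs) > 1 && any(abs(hi[-length(hi)] - lo[-1]) > 1e-12)) {
    stop("gap or overlap in lambda schedule coverage")
  }
  ests <- lapply(pairs, bar_pair, tol = tol, max_iter = max_iter,
                 block_size = block_size)
  dgs <- vapply(ests, `[[`, numeric(1), "delta_g")
  ses <- vapply(ests, `[[`, numeric(1), "stderr")
  structure(list(
    estimates = ests,
    total = sum(dgs),
    total_stderr = sqrt(sum(ses^2)),
    schedule = c(lo, 1),
    table = data.frame(
      lambda_low = lo, lambda_high = hi, delta_g = dgs, stderr = ses,
      overlap_warning = vapply(ests, `[[`, logical(1), "overlap_warning"))),
    class = "restraint_switching_result")
}

#' @export
print.restraint_switching_result <- function(x, ...) {
  cat(sprintf("<restraint_switching_result> %d pairs, total dG_restr = %.4f +- %.4f kcal/mol\n",
              nrow(x$table), x$total, x$total_stderr))
  invisible(x)
}
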