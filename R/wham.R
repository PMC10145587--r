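#' WHAM configuration
#'
#' Defaults: 0.1 A bins (ten per conventional 1 A window spacing, enough
#' to resolve curvature), offset tolerance 1e-6 kcal/mol, at most 1e5
#' direct iterations.
#'
#' @param bin_width histogram bin width in A
#' @param tol convergence tolerance on the window offsets F_i (kcal/mol)
#' @param max_iter maximum self-consistency iterations
#' @param temperature temperature in K
#' @return object of class `wham_config`
#' @export
wham_config <- function(bin_width = 0.1, tol = 1e-6, max_iter = 1e5,
                        temperature = 300) {
  stopifnot(bin_width > 0, tol > 0, max_iter >= 1, temperature > 0)
  structure(list(bin_width = bin_width, tol = tol,
                 max_iter = as.integer(max_iter), temperature = temperature),
            class = "wham_config")
}

#' Reconstruct a PMF from umbrella windows by WHAM
#'
#' Solves the weighted-histogram self-consistency equations
#' \deqn{P(r) = \frac{\sum_i n_i(r)}{\sum_i N_i e^{(F_i - U_i(r))/kT}},
#'       \qquad e^{-F_i/kT} = \sum_r P(r) e^{-U_i(r)/kT}}
#' by direct iteration, where \eqn{U_i(r) = k_i (r - c_i)^2 / 2} is window
#' i's umbrella bias. The PMF is \eqn{w(r) = -kT \ln P(r)} shifted so its
#' minimum is zero.
#'
#' Per-bin standard errors: `stderr_method = "poisson"` (default, fast)
#' gives counting errors \eqn{kT / \sqrt{n_{eff}(r)}} with per-window
#' counts deflated by the statistical inefficiency of that window's
#' series; it neglects the uncertainty of the window offsets F_i and can
#' under-report by a few tens of percent. `"bootstrap"` runs a
#' moving-block bootstrap over every window's series (block length ~ 5
#' statistical-inefficiency times) and re-solves WHAM per replicate,
#' capturing both noise sources at `n_boot` times the solve cost.
#'
#' @param windows list of [umbrella_window()]
#' @param config a [wham_config()]
#' @param stderr_method `"poisson"` or `"bootstrap"` (see Details)
#' @param n_boot bootstrap replicates when `stderr_method = "bootstrap"`
#' @return object of class `pmf_profile` with fields `bin_centers`, `w`,
#'   `stderr` (kcal/mol), `offsets` (window free energies F_i),
#'   `converged`, `n_iter`, `counts`, `r_star` (NA until
#'   [plateau_rstar()] is applied)
#' @export
wham_solve <- function(windows, config = wham_config(),
                       stderr_method = c("poisson", "bootstrap"),
                       n_boot = 20L) {
  stderr_method <- match.arg(stderr_method)
  stopifnot(length(windows) >= 1,
            all(vapply(windows, inherits, logical(1), "umbrella_window")),
            inherits(config, "wham_config"))
  kt <- kBT(config$temperature)
  h <- config$bin_width
  all_x <- unlist(lapply(windows, function(w) w$samples$value))
  lo <- floor(min(all_x) / h) * h
  edges <- seq(lo, max(all_x) + h, by = h)
  nb <- length(edges) - 1
  centers <- edges[-length(edges)] + h / 2

  n_win <- length(windows)
  counts <- matrix(0, n_win, nb)
  g <- numeric(n_win)
  for (i in seq_len(n_win)) {
    x <- windows[[i]]$samples$value
    idx <- findInterval(x, edges, rightmost.closed = TRUE)
    counts[i, ] <- tabulate(idx, nbins = nb)
    g[i] <- statistical_inefficiency(windows[[i]]$samples)
  }
  pooled <- colSums(counts)

  # keep the dominant connected run of populated bins; stray outlier
  # fragments carrying < 1% of all samples are discarded (standard
  # practice for unsampled tails), anything larger means genuinely
  # disconnected windows and is an error
  runs <- split(seq_len(nb), cumsum(pooled == 0))
  runs <- lapply(runs, function(ix) ix[pooled[ix] > 0])
  runs <- runs[lengths(runs) > 0]
  run_mass <- vapply(runs, function(ix) sum(pooled[ix]), numeric(1))
  main <- which.max(run_mass)
  if (sum(run_mass[-main]) > 0.01 * sum(run_mass)) {
    off <- unlist(runs[-main])
    gap_lo <- centers[min(setdiff(seq_len(nb), unlist(runs)))]
    stop(sprintf(
      "disconnected histogram support: populated bins split around an empty gap near r = %.3g A (%.1f%% of samples stranded)",
      gap_lo, 100 * sum(run_mass[-main]) / sum(run_mass)))
  }
  keep <- runs[[main]]
  counts <- counts[, keep, drop = FALSE]
  centers <- centers[keep]
  pooled <- pooled[keep]
  nb <- length(centers)

  n_i <- rowSums(counts)
  # bin-averaged bias Boltzmann factors, window x bin: averaging
  # exp(-U_i/kT) over each bin (11-point rule) instead of evaluating at
  # the center removes the leading histogram discretization bias where
  # the umbrella potential is steep across a bin
  cvec <- vapply(windows, `[[`, numeric(1), "center")
  kvec <- vapply(windows, `[[`, numeric(1), "k_kcal")
  nodes <- seq(-h / 2, h / 2, length.out = 11)
  expu <- matrix(0, n_win, nb)
  for (q in seq_along(nodes)) {
    wq <- if (q == 1 || q == length(nodes)) 0.5 else 1
    xq <- matrix(centers + nodes[q], n_win, nb, byrow = TRUE)
    expu <- expu + wq * exp(-0.5 * kvec * (xq - cvec)^2 / kt)
  }
  expu <- expu / (length(nodes) - 1)

  sol <- wham_iterate(counts, n_i, expu, kt, config$tol, config$max_iter)
  if (!sol$converged) {
    warning(sprintf("WHAM did not converge in %d iterations (last offset change %.3g)",
                    sol$n_iter, sol$delta))
  }
  w <- sol$w - min(sol$w)

  eff <- colSums(counts / g)
  stderr <- kt / sqrt(eff)
  if (stderr_method == "bootstrap") {
    stderr <- wham_bootstrap_stderr(windows, edges, keep, expu, kt,
                                    config, g, sol, stderr, n_boot)
  }
  structure(list(bin_centers = centers, w = w,
                 stderr = stderr,
                 offsets = sol$f_off, converged = sol$converged,
                 n_iter = sol$n_iter,
                 counts = pooled, r_star = NA_real_,
                 bin_width = h, temperature = config$temperature),
            class = "pmf_profile")
}

# direct self-consistent iteration of the WHAM equations, optionally warm
# started from a previous solution's offsets
wham_iterate <- function(counts, n_i, expu, kt, tol, max_iter,
                         f_init = NULL) {
  pooled <- colSums(counts)
  f_off <- if (is.null(f_init)) numeric(nrow(counts)) else f_init
  converged <- FALSE
  iter <- 0L
  delta <- Inf
  repeat {
    iter <- iter + 1L
    a <- exp(f_off / kt)
    denom <- colSums((n_i * a) * expu)
    p <- pooled / denom
    f_new <- -kt * log(as.vector(expu %*% p))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f_off))
    f_off <- f_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  a <- exp(f_off / kt)
  p <- pooled / colSums((n_i * a) * expu)
  list(w = -kt * log(p), f_off = f_off, converged = converged,
       n_iter = iter, delta = delta)
}

# moving-block bootstrap over each window's sample series: captures both
# counting noise and the window-offset (F_i) noise that a per-bin Poisson
# estimate misses. Replicate profiles are aligned to the full solution by
# an inverse-variance weighted shift before taking per-bin sd.
wham_bootstrap_stderr <- function(windows, edges, keep, expu, kt,
                                  config, g, sol, poisson_se, n_boot) {
  nb <- length(keep)
  n_win <- length(windows)
  reps <- matrix(NA_real_, n_boot, nb)
  for (b in seq_len(n_boot)) {
    counts_b <- matrix(0, n_win, nb)
    for (i in seq_len(n_win)) {
      x <- windows[[i]]$samples$value
      n <- length(x)
      blk <- min(n, max(10L, ceiling(5 * g[i])))
      starts <- sample.int(n - blk + 1L, ceiling(n / blk), replace = TRUE)
      idx <- as.vector(outer(0:(blk - 1L), starts, `+`))[seq_len(n)]
      counts_b[i, ] <- tabulate(findInterval(x[idx], edges,
                                             rightmost.closed = TRUE),
                                nbins = length(edges) - 1)[keep]
    }
    sol_b <- wham_iterate(counts_b, rowSums(counts_b), expu, kt,
                          config$tol, config$max_iter, f_init = sol$f_off)
    w_b <- sol_b$w
    ok <- is.finite(w_b) & is.finite(sol$w)
    shift <- stats::weighted.mean((w_b - sol$w)[ok], 1 / poisson_se[ok]^2)
    reps[b, ] <- w_b - shift
  }
  se <- apply(reps, 2, function(v) stats::sd(v[is.finite(v)]))
  # fall back to the counting estimate where bootstrap support is thin
  bad <- !is.finite(se) | colSums(is.finite(reps)) < max(3, n_boot / 2)
  se[bad] <- poisson_se[bad]
  pmax(se, poisson_se / 3)
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile> %d bins on [%.3g, %.3g] A, depth range %.3g kcal/mol, %s\n",
              length(x$w), min(x$bin_centers), max(x$bin_centers), max(x$w),
              if (x$converged) sprintf("converged in %d iters", x$n_iter) else "NOT converged"))
  if (!is.na(x$r_star)) cat(sprintf("  r* = %.3g A\n", x$r_star))
  invisible(x)
}

#' Construct a PMF profile directly (e.g. from a file or an analytic curve)
#'
#' @param bin_centers strictly increasing coordinates (A)
#' @param w free energies (kcal/mol); shifted so min(w) = 0
#' @param stderr per-bin standard errors (default 0)
#' @param temperature temperature in K
#' @return object of class `pmf_profile`
#' @export
pmf_profile <- function(bin_centers, w, stderr = NULL, temperature = 300) {
  stopifnot(length(bin_centers) == length(w), length(w) >= 2,
            all(diff(bin_centers) > 0), all(is.finite(w)))
  if (is.null(stderr)) stderr <- rep(0, length(w))
  stopifnot(length(stderr) == length(w), all(stderr >= 0))
  structure(list(bin_centers = bin_centers, w = w - min(w), stderr = stderr,
                 offsets = NULL, converged = TRUE, n_iter = 0L,
                 counts = NULL, r_star = NA_real_,
                 bin_width = stats::median(diff(bin_centers)),
                 temperature = temperature),
            class = "pmf_profile")
}

#' Locate the plateau onset r* of a PMF
#'
#' r* is the smallest coordinate beyond the PMF minimum from which the
#' local mean slope of the profile stays below `slope_tol` in magnitude
#' all the way to the end of the sampled range — the point where the
#' ligand has reached bulk. The local slope at r is the least-squares
#' slope of w over the window `[r, r + tail_span]`: averaging over the
#' full span keeps per-bin statistical noise (which would swamp a
#' bin-to-bin finite difference) out of the decision.
#'
#' @param profile a `pmf_profile`
#' @param slope_tol slope threshold in kcal/mol/A
#' @param tail_span slope-averaging window (A)
#' @return r* in A; record it with
#'   `profile$r_star <- plateau_rstar(profile)`
#' @export
plateau_rstar <- function(profile, slope_tol = 0.05, tail_span = 3) {
  stopifnot(inherits(profile, "pmf_profile"), slope_tol > 0, tail_span > 0)
  r <- profile$bin_centers
  w <- profile$w
  i_min <- which.min(w)
  if (max(r) - r[i_min] < tail_span) {
    stop("profile does not span tail_span beyond its minimum; extend the sampled range")
  }
  # regression slope over [r_j, r_j + tail_span] for every start with a
  # full window
  starts <- which(r > r[i_min] & r + tail_span <= max(r) + profile$bin_width / 2)
  if (!length(starts)) {
    stop("profile does not span tail_span beyond its minimum; extend the sampled range")
  }
  flat <- vapply(starts, function(j) {
    in_win <- which(r >= r[j] & r <= r[j] + tail_span)
    rr <- r[in_win]
    abs(sum((rr - mean(rr)) * (w[in_win] - mean(w[in_win]))) /
          sum((rr - mean(rr))^2)) < slope_tol
  }, logical(1))
  # smallest start from which the slope stays flat to the end
  ok <- rev(cumprod(rev(flat))) == 1
  if (!any(ok)) {
    stop("no plateau found below slope_tol; sample a longer range or relax slope_tol")
  }
  r[starts[which(ok)[1]]]
}

#' PMF depth at the dissociation point
#'
#' Under the min-zero convention the depth is simply w(r*): the value of
#' the profile, linearly interpolated, at r*. This is the quantity whose
#' negative enters the binding free energy as the -w(r*) term.
#'
#' @param profile a `pmf_profile`
#' @param r_star dissociation coordinate in A (defaults to the profile's
#'   recorded `r_star`)
#' @return list with `depth` and `stderr` (kcal/mol)
#' @export
pmf_depth <- function(profile, r_star = profile$r_star) {
  stopifnot(inherits(profile, "pmf_profile"))
  if (is.na(r_star)) stop("r_star is not set; run plateau_rstar() or supply it")
  r <- profile$bin_centers
  if (r_star < min(r) || r_star > max(r)) {
    stop(sprintf("r_star = %.3g A outside the profile range [%.3g, %.3g]",
                 r_star, min(r), max(r)))
  }
  list(depth = stats::approx(r, profile$w, xout = r_star)$y,
       stderr = stats::approx(r, profile$stderr, xout = r_star)$y)
}

# default bound region: from the profile start to the first point past the
# minimum where w has risen to within 2 kcal/mol of the plateau value
default_bound_region <- function(profile, r_star) {
  r <- profile$bin_centers
  i_min <- which.min(profile$w)
  w_star <- pmf_depth(profile, r_star)$depth
  past <- which(r > r[i_min] & profile$w >= w_star - 2)
  hi <- if (length(past)) r[min(past)] else r_star
  c(r[1], min(hi, r_star))
}

#' Bound-state volume term of the binding free energy
#'
#' Evaluates \eqn{-kT \ln\left[\int_{bound} e^{-w(r)/kT} dr \,
#' (2\pi kT / k_r)^{-1/2}\right]} by trapezoidal quadrature of the
#' profile over the bound region. For a PMF that is exactly harmonic with
#' curvature k_r the integral equals the Gaussian normalization and the
#' term vanishes; for the deep, narrow wells typical of tight binders it
#' is of order 0.01 kcal/mol.
#'
#' @param profile a `pmf_profile`
#' @param kr pulling force constant, kJ/mol/nm^2 unless `units = "kcal_A2"`
#' @param bound_region `c(lo, hi)` in A; default from the profile start to
#'   the first r past the minimum where w reaches w(r*) - 2 kcal/mol
#' @param temperature temperature in K (defaults to the profile's)
#' @param units unit of `kr`
#' @return the term in kcal/mol
#' @export
bound_volume_term <- function(profile, kr = 1000, bound_region = NULL,
                              temperature = profile$temperature,
                              units = c("kJ_nm2", "kcal_A2")) {
  units <- match.arg(units)
  stopifnot(inherits(profile, "pmf_profile"), kr > 0)
  kr_kcal <- if (units == "kJ_nm2") k_dist_to_kcal(kr) else kr
  kt <- kBT(temperature)
  r <- profile$bin_centers
  if (is.null(bound_region)) {
    bound_region <- default_bound_region(profile, profile$r_star)
  }
  stopifnot(length(bound_region) == 2, bound_region[1] < bound_region[2])
  if (bound_region[1] < min(r) - profile$bin_width ||
      bound_region[2] > max(r) + profile$bin_width) {
    stop("bound_region outside the profile range")
  }
  r_min <- r[which.min(profile$w)]
  if (r_min < bound_region[1] || r_min > bound_region[2]) {
    warning("bound_region excludes the PMF minimum")
  }
  sel <- r >= bound_region[1] & r <= bound_region[2]
  rr <- r[sel]
  f <- exp(-profile$w[sel] / kt)
  integral <- sum(diff(rr) * (f[-1] + f[-length(f)]) / 2)
  -kt * log(integral / sqrt(2 * pi * kt / kr_kcal))
}

#' PMF depth uncertainty from contiguous block splits
#'
#' Every window's series is cut into 2 halves and into 4 quarters; the
#' full WHAM + depth computation is repeated on each block set and the
#' reported error is the larger of the two standard deviations — the
#' conservative convention for trajectory-split error bars.
#'
#' @param windows list of [umbrella_window()]
#' @param config a [wham_config()]
#' @param r_star dissociation coordinate (A), fixed across replicas
#' @return list with `stderr` (kcal/mol), `depth_halves`,
#'   `depth_quarters` (per-replica depths), `sd_halves`, `sd_quarters`
#' @export
error_by_split <- function(windows, config = wham_config(), r_star) {
  stopifnot(length(windows) >= 1, !missing(r_star))
  n_min <- min(vapply(windows, function(w) length(w$samples), integer(1)))
  if (n_min < 4) stop("too few samples per window to split into quarters")
  split_depth <- function(n_blocks) {
    vapply(seq_len(n_blocks), function(b) {
      ws <- lapply(windows, function(w) {
        n <- length(w$samples)
        edges <- floor(seq(0, n, length.out = n_blocks + 1))
        idx <- (edges[b] + 1):edges[b + 1]
        umbrella_window(w$center, w$k_kcal,
                        sample_series(w$samples$value[idx], seed = w$samples$seed),
                        units = "kcal_A2")
      })
      prof <- suppressWarnings(wham_solve(ws, config))
      pmf_depth(prof, r_star)$depth
    }, numeric(1))
  }
  halves <- split_depth(2)
  quarters <- split_depth(4)
  list(stderr = max(stats::sd(halves), stats::sd(quarters)),
       depth_halves = halves, depth_quarters = quarters,
       sd_halves = stats::sd(halves), sd_quarters = stats::sd(quarters))
}
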