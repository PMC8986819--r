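#' Fit configuration for NLLS recovery
#'
#' Settings shared by all Monte-Carlo fitting paths.  Initial guesses are
#' drawn uniformly within a relative window of \code{init_fraction} around
#' the true parameter values; the optimizer is an unconstrained
#' Levenberg-Marquardt algorithm supplied with the analytic Jacobian.
#' Negative iterates and fitted values are permitted and retained (then
#' relabeled); no clamping is applied.
#'
#' @param init_fraction relative half-width of the uniform initial-guess
#'   window around truth, in (0, 1).  Default 0.10.
#' @param max_iterations Levenberg-Marquardt iteration cap.
#' @param ftol,ptol,gtol convergence tolerances on the residual sum of
#'   squares, the parameter step, and the gradient (cosine) criterion.
#' @param amplitude_constraint if \code{TRUE}, the amplitudes are
#'   reparameterized so that they sum to one (\eqn{c_n = 1 - \sum_{i<n}
#'   c_i}) and only the first \eqn{n-1} are free.  Default \code{FALSE}:
#'   all simulation sweeps use the unconstrained fit; the constraint is the
#'   default only on the phantom-emulation pathway.
#' @return Object of class \code{"fit_config"}.
#' @export
fit_config <- function(init_fraction = 0.10, max_iterations = 200L,
                       ftol = 1e-12, ptol = 1e-12, gtol = 0,
                       amplitude_constraint = FALSE) {
  if (!is.numeric(init_fraction) || init_fraction <= 0 || init_fraction >= 1)
    stop("'init_fraction' must be in (0, 1)")
  if (ftol < 0 || ptol < 0 || gtol < 0) stop("tolerances must be nonnegative")
  structure(list(init_fraction = init_fraction,
                 max_iterations = as.integer(max_iterations),
                 ftol = ftol, ptol = ptol, gtol = gtol,
                 amplitude_constraint = isTRUE(amplitude_constraint)),
            class = "fit_config")
}

#' Add i.i.d. Gaussian noise to a signal
#'
#' Returns \code{signal + e} with \code{e} drawn i.i.d. from
#' \eqn{N(0, \sigma^2)} at every grid point; the input is untouched.  An
#' SNR-specified noise level is resolved against the maximum absolute
#' value of the supplied (noiseless) signal.
#'
#' @param signal a \code{"signal_array"}.
#' @param noise a \code{\link{noise_spec}}.
#' @param seed optional integer; if given, the draw is made reproducible by
#'   seeding the RNG locally.  Otherwise the current RNG stream is used.
#' @return A new \code{"signal_array"} of the same shape.
#' @export
add_noise <- function(signal, noise, seed = NULL) {
  stopifnot(inherits(signal, "signal_array"), inherits(noise, "noise_spec"))
  sigma <- resolve_sigma(noise, signal)
  if (!is.null(seed)) set.seed(as.integer(seed))
  e <- stats::rnorm(length(signal$values), mean = 0, sd = sigma)
  noisy <- signal$values + if (is.null(dim(signal$values))) e else
    array(e, dim = dim(signal$values))
  signal_array(noisy, signal$grid)
}

## nls.lm info codes 1-4 indicate a satisfied convergence criterion.
.lm_converged <- function(info) isTRUE(info %in% 1:4)

## Map a full parameter vector to the free vector under the sum-to-one
## amplitude constraint (drop c_n), and back.
.constrain <- function(p, n) p[-n]
.unconstrain <- function(pfree, n, N) {
  c(pfree[seq_len(n - 1L)], 1 - sum(pfree[seq_len(n - 1L)]),
    pfree[seq(n, length.out = N - n)])
}

#' Nonlinear least-squares fit of a multicomponent model
#'
#' Minimizes the sum of squared residuals between the data and the signal
#' model over all grid points (for 2D/3D tensors this is the squared
#' Frobenius norm, identical to the squared 2-norm of the vectorized
#' residual) using an unconstrained Levenberg-Marquardt algorithm
#' (\code{minpack.lm::nls.lm}) with the analytic Jacobian.  The fitted
#' components are relabeled so that fitted T2 values are ascending, with
#' amplitudes (and T1s / ADCs) carried along with their component.
#'
#' @param data a \code{"signal_array"} (noisy or noiseless) on \code{grid}.
#' @param grid the \code{\link{acq_grid}} the data were sampled on.
#' @param init named numeric initial parameter vector in the
#'   \code{\link{model_params}} layout.
#' @param config a \code{\link{fit_config}}.
#' @param n number of components being fitted (inferred from
#'   \code{length(init)} and the grid dimensionality by default).
#' @return Object of class \code{"fit_result"}: \code{params} (relabeled
#'   named vector), \code{residual_norm} (minimized objective, a sum of
#'   squares), \code{converged}, \code{n_iterations}, \code{init_used},
#'   \code{message}.  Optimizer failures are reported via
#'   \code{converged = FALSE}, never as an error.
#' @examples
#' m <- mc_model(c(0.3, 0.7), T2 = c(45, 60))
#' g <- acq_grid(TE = seq(8, 512, by = 8))
#' fit <- fit_nlls(eval_signal(m, g), g, init = model_params(m))
#' fit$params
#' @export
fit_nlls <- function(data, grid, init, config = fit_config(), n = NULL) {
  stopifnot(inherits(grid, "acq_grid"), inherits(config, "fit_config"))
  d <- vectorize(data)
  if (length(d) != grid$M) stop("data shape does not match grid")
  dimensionality <- grid_dimensionality(grid)
  per_comp <- 2L + (dimensionality != "T2") + (dimensionality == "T1T2ADC")
  if (is.null(n)) n <- length(init) %/% per_comp
  N <- n * per_comp
  if (length(init) != N)
    stop("init has length ", length(init), ", expected ", N,
         " for an n = ", n, " component ", dimensionality, " model")
  init <- as.numeric(init)

  resid_full <- function(p) {
    parts <- model_from_params(p, n, dimensionality)
    .signal_tensor(parts, grid) - d
  }
  jac_full <- function(p) {
    parts <- model_from_params(p, n, dimensionality)
    .jacobian_matrix(parts, grid)
  }
  if (config$amplitude_constraint) {
    par0 <- .constrain(init, n)
    fn <- function(par) resid_full(.unconstrain(par, n, N))
    jac <- function(par) {
      B <- jac_full(.unconstrain(par, n, N))
      ## dc_n = -dc_i for free amplitudes i < n
      for (i in seq_len(n - 1L)) B[, i] <- B[, i] - B[, n]
      B[, -n, drop = FALSE]
    }
  } else {
    par0 <- init
    fn <- function(par) as.vector(resid_full(par))
    jac <- jac_full
  }

  ctrl <- minpack.lm::nls.lm.control(maxiter = config$max_iterations,
                                     ftol = config$ftol, ptol = config$ptol,
                                     gtol = config$gtol)
  ## nls.lm signals informational warnings (e.g. iteration cap reached);
  ## the outcome is captured in the info code, so muffle them in batch use
  fit <- tryCatch(
    withCallingHandlers(
      minpack.lm::nls.lm(par = par0, fn = function(par) as.vector(fn(par)),
                         jac = jac, control = ctrl),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(params = setNames(rep(NA_real_, N),
                                            param_labels(n, dimensionality)),
                          residual_norm = NA_real_, converged = FALSE,
                          n_iterations = NA_integer_, init_used = init,
                          message = conditionMessage(fit)),
                     class = "fit_result"))
  }
  p_full <- if (config$amplitude_constraint)
    .unconstrain(fit$par, n, N) else fit$par
  structure(list(params = relabel_params(p_full, n, dimensionality),
                 residual_norm = fit$deviance,
                 converged = .lm_converged(fit$info),
                 n_iterations = fit$niter,
                 init_used = init,
                 message = fit$message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("NLLS fit (", if (x$converged) "converged" else "NOT converged",
      ", ", x$n_iterations, " iterations, RSS = ",
      format(x$residual_norm), ")\n", sep = "")
  print(signif(x$params, 6))
  invisible(x)
}

## Derived per-realization seeds: deterministic in (master seed, index),
## so growing n_realizations leaves earlier draws unchanged.
.sub_seed <- function(seed, k) as.integer((as.numeric(seed) + k) %% 2147483629)

#' Monte-Carlo simulation of noisy acquisition and NLLS recovery
#'
#' For each noise realization: draw fresh i.i.d. Gaussian noise on the
#' noiseless signal (sigma fixed once from the SNR and the noiseless
#' maximum), draw a fresh uniform initial guess within
#' \code{init_fraction} of truth, fit by Levenberg-Marquardt, and relabel
#' by ascending fitted T2.  Means and SDs are computed over converged
#' realizations; failures are counted and excluded, and a failure rate
#' above 5\% flags the summary.
#'
#' @inheritParams nonlinear_covariance
#' @param n_realizations number of noise realizations (\eqn{\ge 2}).
#' @param config a \code{\link{fit_config}}.
#' @param seed master seed; per-realization noise and initial-guess
#'   substreams are derived from it, so results are fully reproducible and
#'   earlier realizations are unchanged when \code{n_realizations} grows.
#' @return Object of class \code{"mc_summary"}: \code{per_realization}
#'   (data frame, one row per realization with fitted parameters and a
#'   convergence flag), \code{mean}, \code{sd} (over converged rows),
#'   \code{n_realizations}, \code{snr_used}, \code{sigma_used},
#'   \code{failure_count}, \code{flagged}.
#' @examples
#' m <- mc_model(c(0.3, 0.7), T2 = c(60, 150))
#' g <- acq_grid(TE = seq(8, 512, by = 8))
#' mc <- run_mc(m, g, noise_spec(snr = 1e4), n_realizations = 50, seed = 1)
#' mc$sd
#' @export
run_mc <- function(model, grid, noise, n_realizations, config = fit_config(),
                   seed = 1L) {
  stopifnot(inherits(model, "mc_model"), inherits(grid, "acq_grid"),
            n_realizations >= 2)
  check_compatible(model, grid)
  clean <- eval_signal(model, grid)
  sigma <- resolve_sigma(noise, clean)
  truth <- model_params(model)
  N <- length(truth)
  n <- model$n
  dimensionality <- model$dimensionality
  f <- config$init_fraction

  rows <- vector("list", n_realizations)
  for (i in seq_len(n_realizations)) {
    noisy <- add_noise(clean, noise_spec(sigma = sigma),
                       seed = .sub_seed(seed, 2 * i))
    set.seed(.sub_seed(seed, 2 * i + 1))
    init <- truth * stats::runif(N, 1 - f, 1 + f)
    if (config$amplitude_constraint)
      init[n] <- 1 - sum(init[seq_len(n - 1L)])
    fit <- fit_nlls(noisy, grid, init, config, n = n)
    rows[[i]] <- data.frame(realization = i,
                            as.list(fit$params),
                            residual_norm = fit$residual_norm,
                            converged = fit$converged)
  }
  tab <- do.call(rbind, rows)
  ok <- tab$converged & stats::complete.cases(tab)
  labs <- param_labels(n, dimensionality)
  est <- as.matrix(tab[ok, labs, drop = FALSE])
  failure_count <- sum(!ok)
  structure(list(per_realization = tab,
                 mean = setNames(colMeans(est), labs),
                 sd = setNames(apply(est, 2, stats::sd), labs),
                 n_realizations = n_realizations,
                 snr_used = if (!is.null(noise$snr)) noise$snr else NA_real_,
                 sigma_used = sigma,
                 failure_count = failure_count,
                 flagged = failure_count > 0.05 * n_realizations,
                 seed = seed,
                 config = config),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte-Carlo summary: %d realizations (%d failed%s), sigma = %g\n",
              x$n_realizations, x$failure_count,
              if (x$flagged) ", FLAGGED: >5% failures" else "",
              x$sigma_used))
  print(rbind(mean = signif(x$mean, 6), sd = signif(x$sd, 4)))
  invisible(x)
}

#' Equal-time SNR for a 1D comparison experiment
#'
#' A higher-dimensional acquisition spends \code{n_indirect} times longer
#' than a single 1D acquisition; an equal-time 1D experiment can average
#' \code{n_indirect} repeats, gaining a factor \eqn{\sqrt{n_{indirect}}}
#' in SNR.  This returns the SNR the matched 1D experiment should use.
#'
#' @param snr_nd SNR of the higher-dimensional experiment.
#' @param n_indirect number of indirect-dimension points (\eqn{\ge 1}).
#' @return \code{snr_nd * sqrt(n_indirect)}.
#' @examples
#' equal_time_snr(400, 25)  # 2000
#' @export
equal_time_snr <- function(snr_nd, n_indirect) {
  stopifnot(n_indirect >= 1)
  snr_nd * sqrt(n_indirect)
}

#' Three-parameter monoexponential calibration fits
#'
#' Least-squares fits of the imaging calibration models: a decay
#' \eqn{A + M_0 e^{-t/T_2}} (\code{kind = "T2-decay"}) or a saturation
#' recovery \eqn{A + M_0 (1 - e^{-t/T_1})} (\code{kind = "T1-saturation"}).
#' The offset \eqn{A} accommodates a magnitude-image noise floor.
#'
#' @param values measured intensities.
#' @param times acquisition times in ms (TE for decay, TR for saturation);
#'   at least 4 points.
#' @param kind which calibration model to fit.
#' @return List with \code{A}, \code{M0}, \code{time_constant} (ms), and
#'   \code{converged}.  Non-convergence is reported, not raised.
#' @export
fit_monoexponential <- function(values, times,
                                kind = c("T2-decay", "T1-saturation")) {
  kind <- match.arg(kind)
  stopifnot(length(values) == length(times), length(times) >= 4)
  decay <- kind == "T2-decay"
  y <- as.numeric(values); t <- as.numeric(times)
  A0 <- if (decay) min(y) else min(y)
  M00 <- max(y) - min(y)
  if (M00 <= 0) M00 <- max(abs(y), 1e-8)
  ## time at which the exponential term has decayed/recovered by 1/e
  frac <- (y - A0) / M00
  target <- if (decay) exp(-1) else 1 - exp(-1)
  T0 <- t[which.min(abs(frac - target))]
  if (!is.finite(T0) || T0 <= 0) T0 <- stats::median(t)
  fn <- function(p) {
    e <- exp(-t / p[3])
    model <- if (decay) p[1] + p[2] * e else p[1] + p[2] * (1 - e)
    model - y
  }
  jac <- function(p) {
    e <- exp(-t / p[3])
    dT <- p[2] * e * t / p[3]^2 * if (decay) 1 else -1
    cbind(1, if (decay) e else 1 - e, dT)
  }
  fit <- tryCatch(
    withCallingHandlers(
      minpack.lm::nls.lm(par = c(A0, M00, T0), fn = fn, jac = jac,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(A = NA_real_, M0 = NA_real_, time_constant = NA_real_,
                converged = FALSE))
  list(A = fit$par[1], M0 = fit$par[2], time_constant = fit$par[3],
       converged = .lm_converged(fit$info))
}

#' Write per-realization Monte-Carlo results to CSV
#'
#' Tidy layout: one row per realization, one column per labeled parameter,
#' plus the residual norm and convergence flag.  Values are written at full
#' double precision so reruns are byte-identical.
#'
#' @param summary an \code{"mc_summary"}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_mc_csv <- function(summary, path) {
  stopifnot(inherits(summary, "mc_summary"))
  tab <- summary$per_realization
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
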