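#' Noise specification
#'
#' Noise level of an acquisition, given either as an SNR or directly as the
#' noise standard deviation \eqn{\sigma} in signal units.  SNR is defined
#' as the ratio of the maximum noiseless signal amplitude to the noise SD;
#' for signed (inversion-recovery) signals the maximum of \eqn{|S|} over
#' the grid is used.
#'
#' @param snr positive signal-to-noise ratio (primary if given);
#'   \code{Inf} denotes the noiseless limit.
#' @param sigma nonnegative noise SD in signal units; exactly one of
#'   \code{snr}, \code{sigma} must be supplied.  \code{sigma = 0} is the
#'   noiseless limit.
#' @return Object of class \code{"noise_spec"}.
#' @examples
#' noise_spec(snr = 400)
#' noise_spec(sigma = 0.0025)
#' @export
noise_spec <- function(snr = NULL, sigma = NULL) {
  if (is.null(snr) == is.null(sigma))
    stop("supply exactly one of 'snr' or 'sigma'")
  if (!is.null(snr) && (is.na(snr) || snr <= 0))
    stop("'snr' must be positive")
  if (!is.null(sigma) && (!is.finite(sigma) || sigma < 0))
    stop("'sigma' must be nonnegative and finite")
  structure(list(snr = snr, sigma = sigma), class = "noise_spec")
}

#' Resolve a noise specification to a sigma
#'
#' @param noise a \code{\link{noise_spec}}.
#' @param signal the noiseless \code{"signal_array"} (or numeric values)
#'   the SNR refers to; ignored when \code{sigma} was given directly.
#' @return The noise SD \eqn{\sigma} (signal units).
#' @export
resolve_sigma <- function(noise, signal = NULL) {
  stopifnot(inherits(noise, "noise_spec"))
  if (!is.null(noise$sigma)) return(noise$sigma)
  if (is.null(signal))
    stop("resolving sigma from SNR requires the noiseless signal")
  v <- if (inherits(signal, "signal_array")) signal$values else signal
  max(abs(v)) / noise$snr
}

## Relative singular-value cutoff below which the Jacobian is declared
## numerically rank-deficient and the covariance undefined.
.RANK_TOL <- 1e-12

stability_report <- function(covariance, sd, condition_number, singular,
                             param_layout, sigma) {
  structure(list(covariance = covariance, sd = sd,
                 condition_number = condition_number, singular = singular,
                 param_layout = param_layout, sigma_used = sigma),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, digits = 4, ...) {
  cat("Linearized stability report (sigma =", format(x$sigma_used), ")\n")
  if (x$singular) {
    cat("  Jacobian numerically rank-deficient: condition number = Inf,",
        "covariance undefined\n")
  } else {
    cat("  condition number:", format(x$condition_number, digits = digits), "\n")
    cat("  parameter SDs:\n")
    print(signif(x$sd, digits))
  }
  invisible(x)
}

## Column scaling that re-expresses relaxation-time parameters in seconds
## for conditioning purposes: dS/dT[s] = 1000 * dS/dT[ms].  Conditioning is
## unit-dependent; with times in seconds the amplitude and time-constant
## sensitivities enter on comparable scales, which is the convention under
## which the built-in 1D/2D/3D conditioning comparisons are made.
## Amplitudes and diffusion parameters (mm^2/ms) are left as supplied.
.cond_unit_scale <- function(layout) {
  ifelse(grepl("^T[12]_", layout), 1000, 1)
}

## Core: covariance (X^T X)^{-1} sigma^2 via SVD (numerically stable; the
## explicit normal-equations inverse squares the condition number).  When
## `cond_scale` is given, the condition number and the rank decision are
## taken on the column-rescaled matrix; the covariance itself is always in
## the supplied units.
.covariance_from_matrix <- function(X, sigma, layout = colnames(X),
                                    cond_scale = NULL) {
  M <- nrow(X); N <- ncol(X)
  if (M < N)
    stop("need at least as many measurements as parameters (M = ", M,
         " < N = ", N, ")")
  sv <- svd(X)
  kappa <- if (is.null(cond_scale)) {
    if (sv$d[1] == 0 || sv$d[N] < .RANK_TOL * sv$d[1]) Inf
    else sv$d[1] / sv$d[N]
  } else {
    condition_number(X * rep(cond_scale, each = M))
  }
  dmax <- sv$d[1]
  singular <- !is.finite(kappa) || !is.finite(dmax) || dmax == 0 ||
    sv$d[N] < .RANK_TOL * dmax
  if (singular) kappa <- Inf
  if (is.null(layout)) layout <- paste0("p", seq_len(N))
  if (singular) {
    cov <- matrix(NA_real_, N, N, dimnames = list(layout, layout))
    sds <- setNames(rep(NA_real_, N), layout)
  } else {
    cov <- sv$v %*% (t(sv$v) / sv$d^2) * sigma^2
    cov <- (cov + t(cov)) / 2              # enforce exact symmetry
    dimnames(cov) <- list(layout, layout)
    sds <- setNames(sqrt(diag(cov)), layout)
  }
  stability_report(cov, sds, kappa, singular, layout, sigma)
}

#' Covariance of linear least-squares estimates
#'
#' For data \eqn{d = Gp + \epsilon} with i.i.d. Gaussian noise of SD
#' \eqn{\sigma}, the least-squares estimate has covariance
#' \eqn{Cov(p^*) = (G^T G)^{-1} \sigma^2}; its diagonal gives the
#' per-parameter variances.  Computed via the singular value decomposition
#' of \eqn{G} rather than explicit inversion of the normal equations.
#'
#' @param G numeric \code{M x N} design matrix, \code{M >= N}.
#' @param sigma noise SD.
#' @return A \code{"stability_report"} with elements \code{covariance},
#'   \code{sd}, \code{condition_number}, \code{singular},
#'   \code{param_layout}, \code{sigma_used}.  A numerically rank-deficient
#'   \code{G} yields \code{condition_number = Inf}, \code{singular = TRUE},
#'   and an all-\code{NA} covariance (the quantity is undefined).
#' @export
linear_covariance <- function(G, sigma) {
  stopifnot(is.matrix(G), is.numeric(G), is.finite(sigma), sigma > 0)
  .covariance_from_matrix(G, sigma)
}

#' Linearized covariance of nonlinear least-squares estimates
#'
#' First-order (Cramer-Rao type) covariance of the NLLS parameter
#' estimates for a multicomponent relaxometry model:
#' \eqn{Cov(p^*) = (B^T B)^{-1} \sigma^2}, where \eqn{B} is the analytic
#' Jacobian of the vectorized signal evaluated at the linearization point.
#' By default the linearization point is the supplied model itself (the
#' true underlying parameters); \code{linearize_at} allows linearizing at a
#' fitted point for diagnostics.
#'
#' @inheritParams eval_signal
#' @param noise a \code{\link{noise_spec}}; an SNR is resolved against the
#'   maximum absolute noiseless signal on this grid.
#' @param linearize_at optional \code{\link{mc_model}} at which to evaluate
#'   the Jacobian instead of \code{model}.
#' @return A \code{"stability_report"}; see \code{\link{linear_covariance}}.
#'   At component coalescence (identical relaxation attributes) the
#'   Jacobian is singular and the report carries the \code{Inf} flag.
#' @examples
#' m <- mc_model(c(0.3, 0.7), T2 = c(60, 150))
#' g <- acq_grid(TE = seq(8, 512, by = 8))
#' nonlinear_covariance(m, g, noise_spec(snr = 1e4))$sd
#' @export
nonlinear_covariance <- function(model, grid, noise, linearize_at = NULL) {
  stopifnot(inherits(model, "mc_model"), inherits(grid, "acq_grid"),
            inherits(noise, "noise_spec"))
  sigma <- resolve_sigma(noise, eval_signal(model, grid))
  at <- if (is.null(linearize_at)) model else linearize_at
  B <- eval_jacobian(at, grid)
  .covariance_from_matrix(B, sigma,
                          cond_scale = .cond_unit_scale(colnames(B)))
}

#' Condition number of a model/grid pairing
#'
#' Evaluates the analytic Jacobian of the model on the grid and returns its
#' 2-norm condition number under the package's conditioning unit
#' convention: relaxation times expressed in seconds, amplitudes
#' dimensionless, diffusion parameters in mm^2/ms (with b in ms/mm^2).
#' Conditioning is intrinsically unit-dependent; this convention puts the
#' amplitude and time-constant sensitivity columns on comparable scales so
#' that condition numbers of 1D, 2D, and 3D models can be compared
#' meaningfully.  Parameter SDs elsewhere are always reported in the input
#' units (ms).
#'
#' @inheritParams eval_signal
#' @return Positive number, or \code{Inf} at numerical rank deficiency
#'   (e.g. component coalescence).
#' @examples
#' g <- acq_grid(TE = seq(8, 512, by = 8))
#' model_condition_number(mc_model(c(0.3, 0.7), T2 = c(45, 60)), g)
#' @export
model_condition_number <- function(model, grid) {
  B <- eval_jacobian(model, grid)
  condition_number(B * rep(.cond_unit_scale(colnames(B)), each = nrow(B)))
}

#' Condition number of a Jacobian (or any) matrix
#'
#' The 2-norm condition number: the ratio of the largest to the smallest
#' singular value.  It measures the worst-case amplification of data noise
#' into parameter error for the linearized problem and is unit-dependent;
#' all built-in sweeps use ms, ms/mm^2 and mm^2/ms consistently.
#'
#' @param B numeric matrix.
#' @return Positive number \eqn{\ge 1}, or \code{Inf} when the smallest
#'   singular value is below \code{1e-12} of the largest.
#' @export
condition_number <- function(B) {
  stopifnot(is.matrix(B), is.numeric(B))
  d <- svd(B, nu = 0, nv = 0)$d
  if (d[1] == 0 || !is.finite(d[1])) return(Inf)
  if (d[length(d)] < .RANK_TOL * d[1]) return(Inf)
  d[1] / d[length(d)]
}

#' Serialize a stability report
#'
#' \code{report_to_json} writes the full report (covariance as nested
#' lists, layout labels as strings); \code{report_row} flattens it to a
#' single-row data frame (one \code{sd_*} column per parameter plus the
#' condition number) for sweep tables.
#'
#' @param report a \code{"stability_report"}.
#' @param path optional file path; if \code{NULL} the JSON string is
#'   returned.
#' @return \code{report_to_json}: the path or JSON string, invisibly.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "stability_report"))
  doc <- list(param_layout = report$param_layout,
              sigma = report$sigma_used,
              singular = report$singular,
              condition_number = if (is.finite(report$condition_number))
                report$condition_number else "Inf",
              sd = as.list(report$sd),
              covariance = apply(report$covariance, 1, as.list))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(txt)))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname report_to_json
#' @return \code{report_row}: a one-row \code{data.frame}.
#' @export
report_row <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  out <- as.data.frame(as.list(setNames(report$sd,
                                        paste0("sd_", report$param_layout))))
  out$condition_number <- report$condition_number
  out$singular <- report$singular
  out
}
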