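## Forward evaluation of the multicomponent relaxometry signal and its
## analytic Jacobian.  The signal at a grid point (TE, TI, b) is
##
##   S = sum_i c_i * exp(-TE/T2_i) * (1 - 2 exp(-TI/T1_i)) * exp(-b * ADC_i)
##
## with the TI and b factors present only when the corresponding dimension
## is acquired.  The inversion-recovery factor is signed: it is negative
## for TI < T1 * ln 2 and vanishes exactly at TI = T1 * ln 2.

## Kernel factor matrices, one column per component.  Inputs are plain
## numeric vectors (no positivity assumed: NLLS iterates are unconstrained).
## exp(-TE_j / T2_i) as an n_TE x n matrix
.k_E2 <- function(TE, T2) exp(-outer(TE, 1 / T2, `*`))
.k_R1 <- function(TI, T1) 1 - 2 * exp(-outer(TI, 1 / T1, `*`))
.k_D  <- function(b, ADC) exp(-outer(b, ADC, `*`))

## Noise-free signal tensor, dims (n_TE[, n_TI[, n_b]]).
.signal_tensor <- function(parts, grid) {
  n <- length(parts$amplitude)
  E2 <- .k_E2(grid$TE, parts$T2)
  has_TI <- !is.null(grid$TI)
  has_b <- !is.null(grid$b)
  if (!has_TI && !has_b) {
    return(as.vector(E2 %*% parts$amplitude))
  }
  R1 <- if (has_TI) .k_R1(grid$TI, parts$T1) else matrix(1, 1, n)
  if (!has_b) {
    ## S[j, k] = sum_i c_i E2[j,i] R1[k,i]
    return(E2 %*% (parts$amplitude * t(R1)))
  }
  D <- .k_D(grid$b, parts$ADC)
  S <- array(0, dim = c(length(grid$TE), length(grid$TI), length(grid$b)))
  for (i in seq_len(n)) {
    S <- S + parts$amplitude[i] *
      outer(outer(E2[, i], R1[, i]), D[, i])
  }
  S
}

## Analytic Jacobian, M x N, columns in model_params() layout.
.jacobian_matrix <- function(parts, grid) {
  n <- length(parts$amplitude)
  has_TI <- !is.null(grid$TI)
  has_b <- !is.null(grid$b)
  TE <- grid$TE
  E2 <- .k_E2(TE, parts$T2)
  dE2 <- E2 * outer(TE, 1 / parts$T2^2, `*`)        # d/dT2 exp(-TE/T2)
  R1 <- if (has_TI) .k_R1(grid$TI, parts$T1) else NULL
  dR1 <- if (has_TI)                                # d/dT1 (1 - 2 e^{-TI/T1})
    -2 * exp(-outer(grid$TI, 1 / parts$T1, `*`)) *
      outer(grid$TI, 1 / parts$T1^2, `*`) else NULL
  D <- if (has_b) .k_D(grid$b, parts$ADC) else NULL
  dD <- if (has_b) -D * matrix(grid$b, nrow = length(grid$b), ncol = n) else NULL

  ## flat column for component i from per-axis factors (TE fastest, b slowest)
  col3 <- function(fTE, fTI, fb) {
    v <- fTE
    if (!is.null(fTI)) v <- as.vector(outer(v, fTI))
    if (!is.null(fb)) v <- as.vector(outer(v, fb))
    v
  }
  M <- length(TE) * (if (has_TI) length(grid$TI) else 1L) *
    (if (has_b) length(grid$b) else 1L)
  dimensionality <- if (has_b) "T1T2ADC" else if (has_TI) "T1T2" else "T2"
  labs <- param_labels(n, dimensionality)
  B <- matrix(0, nrow = M, ncol = length(labs), dimnames = list(NULL, labs))
  for (i in seq_len(n)) {
    fTI <- if (has_TI) R1[, i] else NULL
    fb <- if (has_b) D[, i] else NULL
    B[, paste0("c", i)] <- col3(E2[, i], fTI, fb)
    if (has_TI)
      B[, paste0("T1_", i)] <- parts$amplitude[i] *
        col3(E2[, i], dR1[, i], fb)
    B[, paste0("T2_", i)] <- parts$amplitude[i] * col3(dE2[, i], fTI, fb)
    if (has_b)
      B[, paste0("ADC_", i)] <- parts$amplitude[i] *
        col3(E2[, i], fTI, dD[, i])
  }
  B
}

#' Evaluate the noise-free multicomponent signal on a grid
#'
#' Computes \eqn{S = \sum_i c_i e^{-TE/T_{2,i}} (1 - 2 e^{-TI/T_{1,i}})
#' e^{-b \cdot ADC_i}} at every grid point, the inversion-recovery and
#' diffusion factors applying only when the grid carries the corresponding
#' dimension.  Deterministic; no noise is added.
#'
#' @param model an \code{\link{mc_model}} whose dimensionality matches the
#'   grid (a TI axis requires T1, a b axis requires ADC, and vice versa).
#' @param grid an \code{\link{acq_grid}}.
#' @return An object of class \code{"signal_array"}: list with
#'   \code{values} (a vector for 1D, an \code{n_TE x n_TI} matrix for 2D, an
#'   \code{n_TE x n_TI x n_b} array for 3D — TE is always the first, fastest
#'   varying axis) and \code{grid}.
#' @examples
#' m <- mc_model(c(0.3, 0.7), T2 = c(45, 60))
#' s <- eval_signal(m, acq_grid(TE = seq(8, 512, by = 8)))
#' @export
eval_signal <- function(model, grid) {
  stopifnot(inherits(model, "mc_model"), inherits(grid, "acq_grid"))
  check_compatible(model, grid)
  signal_array(.signal_tensor(model, grid), grid)
}

signal_array <- function(values, grid) {
  structure(list(values = values, grid = grid), class = "signal_array")
}

#' @export
print.signal_array <- function(x, ...) {
  d <- dim(x$values)
  if (is.null(d)) d <- length(x$values)
  cat("Signal array, dims [", paste(d, collapse = " x "), "], range [",
      sprintf("%.4g, %.4g", min(x$values), max(x$values)), "]\n")
  invisible(x)
}

#' Analytic Jacobian of the signal model
#'
#' Closed-form partial derivatives of the vectorized signal with respect to
#' every model parameter, evaluated at the model's own parameter values
#' (the linearization point used throughout the covariance analysis is the
#' true underlying model).  Rows follow the flat measurement order of
#' \code{\link{vectorize}} (TE fastest, then TI, then b); columns follow the
#' \code{\link{model_params}} layout.
#'
#' @inheritParams eval_signal
#' @return An \code{M x N} numeric matrix with column names from
#'   \code{\link{param_labels}} and an attribute \code{"row_map"}, a data
#'   frame giving the (TE, TI, b) coordinates of each row.
#' @export
eval_jacobian <- function(model, grid) {
  stopifnot(inherits(model, "mc_model"), inherits(grid, "acq_grid"))
  check_compatible(model, grid)
  B <- .jacobian_matrix(model, grid)
  attr(B, "row_map") <- grid_row_map(grid)
  B
}

## (TE, TI, b) coordinates of each flat row, TE fastest.
grid_row_map <- function(grid) {
  TI <- if (is.null(grid$TI)) NA_real_ else grid$TI
  b <- if (is.null(grid$b)) NA_real_ else grid$b
  out <- expand.grid(TE = grid$TE, TI = TI, b = b,
                     KEEP.OUT.ATTRS = FALSE)
  out
}

#' Vectorize a signal tensor
#'
#' Flattens the measurement tensor to a length-\code{M} vector in the fixed
#' documented order: TE varies fastest, then TI, then b slowest.  This is
#' the row order of \code{\link{eval_jacobian}}.  The least-squares
#' objective is invariant to this choice; fixing it makes row maps
#' reproducible.
#'
#' @param signal a \code{"signal_array"} (or a bare numeric array).
#' @return Numeric vector of length \code{M}.
#' @seealso \code{\link{devectorize}}
#' @export
vectorize <- function(signal) {
  v <- if (inherits(signal, "signal_array")) signal$values else signal
  as.vector(v)
}

#' Restore a flat vector to its measurement tensor
#'
#' Exact inverse of \code{\link{vectorize}} for the given grid.
#'
#' @param x numeric vector of length \code{grid$M}.
#' @param grid the \code{\link{acq_grid}} defining the tensor shape.
#' @return A \code{"signal_array"}.
#' @export
devectorize <- function(x, grid) {
  stopifnot(inherits(grid, "acq_grid"))
  if (length(x) != grid$M)
    stop("length ", length(x), " does not match grid M = ", grid$M)
  d <- c(length(grid$TE),
         if (!is.null(grid$TI)) length(grid$TI),
         if (!is.null(grid$b)) length(grid$b))
  values <- if (length(d) == 1L) as.numeric(x) else array(x, dim = d)
  signal_array(values, grid)
}
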