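#' Multicomponent relaxation model
#'
#' Constructs the ground-truth physical system for a multiexponential
#' relaxometry experiment: \code{n} monoexponential components, each with a
#' dimensionless amplitude \eqn{c_i} and a transverse relaxation time
#' \eqn{T_{2,i}} (ms), optionally extended with a longitudinal relaxation
#' time \eqn{T_{1,i}} (ms) and an apparent diffusion coefficient
#' \eqn{ADC_i} (mm\eqn{^2}/ms).
#'
#' Components are stored in canonical order: ascending T2, ties broken by
#' ascending T1, then ADC, then amplitude.  Either all components carry a
#' T1 (and/or ADC) or none do; the set of present attributes defines the
#' model dimensionality: \code{"T2"} (1D), \code{"T1T2"} (2D), or
#' \code{"T1T2ADC"} (3D).
#'
#' @param amplitude numeric vector of positive component amplitudes
#'   \eqn{c_i} (dimensionless).
#' @param T2 numeric vector of transverse relaxation times in ms, same
#'   length as \code{amplitude}.
#' @param T1 optional numeric vector of longitudinal relaxation times in ms.
#' @param ADC optional numeric vector of apparent diffusion coefficients in
#'   mm^2/ms (requires \code{T1}).
#' @return An object of class \code{"mc_model"}: a list with elements
#'   \code{amplitude}, \code{T2}, optionally \code{T1} and \code{ADC},
#'   \code{n}, and \code{dimensionality}.
#' @examples
#' mc_model(c(0.3, 0.7), T2 = c(45, 60))
#' mc_model(c(0.3, 0.7), T2 = c(45, 60), T1 = c(1000, 500))
#' @export
mc_model <- function(amplitude, T2, T1 = NULL, ADC = NULL) {
  n <- length(amplitude)
  if (n < 1L) stop("at least one component is required")
  if (length(T2) != n) stop("'T2' must have one value per component")
  if (!is.null(T1) && length(T1) != n)
    stop("'T1' must have one value per component")
  if (!is.null(ADC) && length(ADC) != n)
    stop("'ADC' must have one value per component")
  if (!is.null(ADC) && is.null(T1))
    stop("'ADC' requires 'T1' (diffusion models include T1 sensitization)")
  if (any(!is.finite(amplitude)) || any(amplitude <= 0))
    stop("amplitudes must be positive and finite")
  if (any(!is.finite(T2)) || any(T2 <= 0)) stop("'T2' values must be positive")
  if (!is.null(T1) && (any(!is.finite(T1)) || any(T1 <= 0)))
    stop("'T1' values must be positive")
  if (!is.null(ADC) && (any(!is.finite(ADC)) || any(ADC < 0)))
    stop("'ADC' values must be nonnegative")

  ## canonical component order: ascending T2, ties by T1, ADC, amplitude
  ord <- order(T2,
               if (is.null(T1)) rep(0, n) else T1,
               if (is.null(ADC)) rep(0, n) else ADC,
               amplitude)
  dimensionality <- if (!is.null(ADC)) "T1T2ADC" else if (!is.null(T1)) "T1T2" else "T2"
  structure(list(amplitude = as.numeric(amplitude[ord]),
                 T2 = as.numeric(T2[ord]),
                 T1 = if (is.null(T1)) NULL else as.numeric(T1[ord]),
                 ADC = if (is.null(ADC)) NULL else as.numeric(ADC[ord]),
                 n = n,
                 dimensionality = dimensionality),
            class = "mc_model")
}

#' @export
print.mc_model <- function(x, ...) {
  cat(sprintf("Multicomponent relaxation model (%s, n = %d)\n",
              x$dimensionality, x$n))
  tab <- data.frame(amplitude = x$amplitude, T2.ms = x$T2)
  if (!is.null(x$T1)) tab$T1.ms <- x$T1
  if (!is.null(x$ADC)) tab$ADC.mm2.per.ms <- x$ADC
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Acquisition grid
#'
#' The sampling schedule of a relaxometry experiment: echo times \code{TE}
#' (directly sampled T2 dimension) and, optionally, inversion times
#' \code{TI} and diffusion weightings \code{b} (indirect dimensions).  The
#' total measurement count is \eqn{M = n_{TE} n_{TI} n_b} with absent
#' dimensions counting as one.
#'
#' The measurement tensor is vectorized with TE fastest, then TI, then b
#' slowest; see \code{\link{vectorize}}.
#'
#' @param TE strictly increasing echo times in ms, all positive.
#' @param TI optional strictly increasing inversion times in ms
#'   (nonnegative).
#' @param b optional strictly increasing diffusion weightings in ms/mm^2
#'   (nonnegative).
#' @return An object of class \code{"acq_grid"} with elements \code{TE},
#'   \code{TI}, \code{b}, and \code{M}.
#' @examples
#' acq_grid(TE = seq(8, 512, by = 8))                       # 64 echoes
#' acq_grid(TE = seq(8, 512, by = 8), TI = seq(50, 4850, by = 200))
#' @export
acq_grid <- function(TE, TI = NULL, b = NULL) {
  chk <- function(x, name, min_ok) {
    if (length(x) == 0L) stop("'", name, "' must be nonempty")
    if (any(!is.finite(x)) || any(x < min_ok))
      stop("'", name, "' values out of range")
    if (length(x) > 1L && any(diff(x) <= 0))
      stop("'", name, "' must be strictly increasing")
    as.numeric(x)
  }
  TE <- chk(TE, "TE", min_ok = .Machine$double.xmin)
  if (!is.null(TI)) TI <- chk(TI, "TI", min_ok = 0)
  if (!is.null(b)) b <- chk(b, "b", min_ok = 0)
  M <- length(TE) * max(1L, length(TI)) * max(1L, length(b))
  structure(list(TE = TE, TI = TI, b = b, M = M), class = "acq_grid")
}

#' @export
print.acq_grid <- function(x, ...) {
  cat(sprintf("Acquisition grid: n_TE = %d", length(x$TE)))
  if (!is.null(x$TI)) cat(sprintf(", n_TI = %d", length(x$TI)))
  if (!is.null(x$b)) cat(sprintf(", n_b = %d", length(x$b)))
  cat(sprintf(" (M = %d measurements)\n", x$M))
  invisible(x)
}

## Number of free parameters of the model: n amplitudes plus one time
## constant (or diffusivity) per component per active dimension.
n_params <- function(model) {
  model$n * (2L + !is.null(model$T1) + !is.null(model$ADC))
}

#' Parameter vector layout
#'
#' Flattens a model into the canonical parameter vector used by the
#' Jacobian columns, the covariance matrix, and the NLLS optimizer:
#' amplitudes first, then T1s (if present), then T2s, then ADCs (if
#' present).  For a two-component T1-T2 model this is
#' \code{(c1, c2, T1_1, T1_2, T2_1, T2_2)}.
#'
#' @param model an \code{\link{mc_model}}.
#' @return Named numeric vector; names like \code{"c1"}, \code{"T1_2"}.
#' @seealso \code{\link{model_from_params}} for the inverse.
#' @export
model_params <- function(model) {
  stopifnot(inherits(model, "mc_model"))
  p <- model$amplitude
  if (!is.null(model$T1)) p <- c(p, model$T1)
  p <- c(p, model$T2)
  if (!is.null(model$ADC)) p <- c(p, model$ADC)
  names(p) <- param_labels(model$n, model$dimensionality)
  p
}

#' Parameter labels for a given layout
#'
#' @param n number of components.
#' @param dimensionality one of \code{"T2"}, \code{"T1T2"}, \code{"T1T2ADC"}.
#' @return Character vector of length-\code{N} parameter names.
#' @export
param_labels <- function(n, dimensionality = c("T2", "T1T2", "T1T2ADC")) {
  dimensionality <- match.arg(dimensionality)
  i <- seq_len(n)
  labs <- paste0("c", i)
  if (dimensionality %in% c("T1T2", "T1T2ADC")) labs <- c(labs, paste0("T1_", i))
  labs <- c(labs, paste0("T2_", i))
  if (dimensionality == "T1T2ADC") labs <- c(labs, paste0("ADC_", i))
  labs
}

#' Rebuild a model from a flat parameter vector
#'
#' Inverse of \code{\link{model_params}}.  No validation of positivity is
#' performed (unconstrained NLLS iterates may wander through negative
#' values) and no canonical reordering is applied: the vector is taken at
#' face value.  Use \code{\link{relabel_params}} to restore the ascending-T2
#' convention.
#'
#' @param values numeric vector laid out as \code{\link{model_params}}.
#' @param n number of components.
#' @param dimensionality model dimensionality.
#' @return A list with elements \code{amplitude}, \code{T1}, \code{T2},
#'   \code{ADC} (absent dimensions \code{NULL}); not a validated
#'   \code{mc_model}.
#' @export
model_from_params <- function(values, n, dimensionality = c("T2", "T1T2", "T1T2ADC")) {
  dimensionality <- match.arg(dimensionality)
  has_T1 <- dimensionality %in% c("T1T2", "T1T2ADC")
  has_ADC <- dimensionality == "T1T2ADC"
  expected <- n * (2L + has_T1 + has_ADC)
  if (length(values) != expected)
    stop("parameter vector has length ", length(values), ", expected ", expected)
  k <- 0L
  take <- function() {
    out <- values[k + seq_len(n)]
    k <<- k + n
    unname(out)
  }
  amplitude <- take()
  T1 <- if (has_T1) take() else NULL
  T2 <- take()
  ADC <- if (has_ADC) take() else NULL
  list(amplitude = amplitude, T1 = T1, T2 = T2, ADC = ADC, n = n,
       dimensionality = dimensionality)
}

#' Relabel a fitted parameter vector to the ascending-T2 convention
#'
#' Mixture fits are invariant under permutation of component labels.  The
#' convention adopted throughout is to sort fitted components by ascending
#' fitted T2, carrying amplitudes (and T1s / ADCs) along with their
#' component, so that \code{T2_1 < T2_2} always names the faster-decaying
#' component.
#'
#' @param values flat parameter vector (layout of \code{\link{model_params}}).
#' @param n,dimensionality layout descriptors.
#' @return Relabeled named parameter vector in the same layout.
#' @export
relabel_params <- function(values, n, dimensionality = c("T2", "T1T2", "T1T2ADC")) {
  dimensionality <- match.arg(dimensionality)
  parts <- model_from_params(values, n, dimensionality)
  ord <- order(parts$T2)
  p <- parts$amplitude[ord]
  if (!is.null(parts$T1)) p <- c(p, parts$T1[ord])
  p <- c(p, parts$T2[ord])
  if (!is.null(parts$ADC)) p <- c(p, parts$ADC[ord])
  names(p) <- param_labels(n, dimensionality)
  p
}

grid_dimensionality <- function(grid) {
  if (!is.null(grid$b)) "T1T2ADC" else if (!is.null(grid$TI)) "T1T2" else "T2"
}

## Dimensionality agreement between a model and a grid.  The error names
## the missing attribute explicitly, per the module contract.
check_compatible <- function(model, grid) {
  if (!is.null(grid$TI) && is.null(model$T1))
    stop("grid has a TI dimension but the model has no T1 attribute")
  if (!is.null(grid$b) && is.null(model$ADC))
    stop("grid has a b dimension but the model has no ADC attribute")
  if (is.null(grid$TI) && !is.null(model$T1))
    stop("model has T1 but the grid has no TI dimension")
  if (is.null(grid$b) && !is.null(model$ADC))
    stop("model has ADC but the grid has no b dimension")
  invisible(TRUE)
}

#' Serialize a model (and optionally a grid) to JSON
#'
#' Writes a self-describing JSON document with explicit fields and the unit
#' conventions recorded: times in ms, b in ms/mm^2, ADC in mm^2/ms,
#' amplitudes dimensionless.
#'
#' @param model an \code{\link{mc_model}}.
#' @param grid optional \code{\link{acq_grid}} to store alongside.
#' @param path file path to write; if \code{NULL}, the JSON string is
#'   returned instead.
#' @return Invisibly, the path (or the JSON string when \code{path = NULL}).
#' @export
write_model_json <- function(model, grid = NULL, path = NULL) {
  stopifnot(inherits(model, "mc_model"))
  comps <- lapply(seq_len(model$n), function(i) {
    comp <- list(c = model$amplitude[i], T2 = model$T2[i])
    if (!is.null(model$T1)) comp$T1 <- model$T1[i]
    if (!is.null(model$ADC)) comp$ADC <- model$ADC[i]
    comp
  })
  doc <- list(units = list(time = "ms", b = "ms/mm^2", ADC = "mm^2/ms",
                           amplitude = "dimensionless"),
              components = comps)
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "acq_grid"))
    doc$TE <- grid$TE
    if (!is.null(grid$TI)) doc$TI <- grid$TI
    if (!is.null(grid$b)) doc$b <- grid$b
  }
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(txt)))
  writeLines(txt, path)
  invisible(path)
}

#' Read a model/grid JSON document
#'
#' @param path file written by \code{\link{write_model_json}} (or a JSON
#'   string in the same layout).
#' @return A list with elements \code{model} (\code{\link{mc_model}}) and
#'   \code{grid} (\code{\link{acq_grid}} or \code{NULL}).
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  comps <- doc$components
  model <- mc_model(amplitude = comps$c, T2 = comps$T2,
                    T1 = comps$T1, ADC = comps$ADC)
  grid <- NULL
  if (!is.null(doc$TE))
    grid <- acq_grid(TE = doc$TE, TI = doc$TI, b = doc$b)
  list(model = model, grid = grid)
}
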