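#' Default acquisition grids for the built-in sweeps
#'
#' The standard sampling schedules used by all built-in parameter sweeps:
#' 64 evenly spaced echo times from 8 to 512 ms (step 8 ms); 25 inversion
#' times from 50 to 4850 ms (step 200 ms); 9 diffusion weightings from 0
#' to 2 ms/mm^2 (step 0.25 ms/mm^2).  The 2D grid has
#' \eqn{n_{TI} \times n_{TE} = 1600} measurement points and the 3D grid
#' \eqn{n_{TE} n_{TI} n_b = 14400}.
#'
#' @return Numeric vectors (\code{default_TE} etc.) or an
#'   \code{\link{acq_grid}} (\code{default_grid}).
#' @export
default_TE <- function() seq(8, 512, by = 8)

#' @rdname default_TE
#' @export
default_TI <- function() seq(50, 4850, by = 200)

#' @rdname default_TE
#' @export
default_b <- function() seq(0, 2, by = 0.25)

#' @rdname default_TE
#' @param dimensionality which grid to build: \code{"T2"} (1D),
#'   \code{"T1T2"} (2D), or \code{"T1T2ADC"} (3D).
#' @export
default_grid <- function(dimensionality = c("T2", "T1T2", "T1T2ADC")) {
  dimensionality <- match.arg(dimensionality)
  switch(dimensionality,
         T2 = acq_grid(TE = default_TE()),
         T1T2 = acq_grid(TE = default_TE(), TI = default_TI()),
         T1T2ADC = acq_grid(TE = default_TE(), TI = default_TI(),
                            b = default_b()))
}

## Non-overlapping per-row master seeds for MC sweeps: run_mc consumes
## substream indices up to 2 * n_realizations + 1 from its seed.
.row_seed <- function(seed, i, n_realizations)
  .sub_seed(seed, i * (2 * n_realizations + 10))

sweep_result <- function(rows, spec) {
  structure(list(rows = rows, spec = spec), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Sweep result (", nrow(x$rows), " rows; mode = ", x$spec$mode, ")\n",
      sep = "")
  print(utils::head(x$rows, 10))
  if (nrow(x$rows) > 10) cat("...\n")
  invisible(x)
}

## One analytic row: sds + condition number, NA/Inf-flagged when singular.
.analytic_row <- function(model, grid, noise) {
  report_row(nonlinear_covariance(model, grid, noise))
}

.mc_row <- function(model, grid, noise, n_realizations, config, seed) {
  mc <- run_mc(model, grid, noise, n_realizations, config, seed = seed)
  out <- as.data.frame(as.list(setNames(mc$sd, paste0("mc_sd_", names(mc$sd)))))
  means <- as.data.frame(as.list(setNames(mc$mean,
                                          paste0("mc_mean_", names(mc$mean)))))
  cbind(out, means, mc_failures = mc$failure_count)
}

#' 1D coalescence sweep
#'
#' Reproduces the one-dimensional stability analysis: with
#' \eqn{(c_1, c_2, T_{2,1})} fixed, sweep \eqn{T_{2,2}} and record the
#' linearized SDs and Jacobian condition number (and optionally Monte-Carlo
#' SDs).  As \eqn{T_{2,2} \to T_{2,1}} the two exponentials coalesce, the
#' Jacobian becomes singular, and the SDs diverge; a swept value exactly
#' equal to \eqn{T_{2,1}} yields a singular-flagged row rather than an
#' error.
#'
#' @param T22_values vector of swept \eqn{T_{2,2}} values (ms).
#' @param amplitude,T21 fixed amplitudes and first T2 (ms); defaults
#'   \code{c(0.3, 0.7)} and 60 ms.
#' @param grid acquisition grid (default: 64 echoes, 8..512 ms).
#' @param snr SNR; enters the analytic SDs only as a multiplicative
#'   constant (default 1e4, also the Monte-Carlo default).
#' @param mode \code{"analytic"}, \code{"monte-carlo"}, or \code{"both"}.
#' @param n_realizations,config,seed Monte-Carlo settings (used unless
#'   \code{mode = "analytic"}).
#' @return A \code{"sweep_result"}; \code{rows} has one record per swept
#'   value with \code{sd_*}, \code{condition_number}, \code{singular} and,
#'   in MC modes, \code{mc_sd_*} / \code{mc_mean_*} columns.
#' @examples
#' sw <- sweep_1d_coalescence(c(70, 100, 150))
#' sw$rows[, c("T2_2", "sd_T2_2", "condition_number")]
#' @export
sweep_1d_coalescence <- function(T22_values,
                                 amplitude = c(0.3, 0.7), T21 = 60,
                                 grid = default_grid("T2"),
                                 snr = 1e4,
                                 mode = c("analytic", "monte-carlo", "both"),
                                 n_realizations = 1000,
                                 config = fit_config(), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(T22_values) >= 1)
  T22_values <- as.numeric(T22_values)
  ## noise enters the linearized sds only as a multiplicative constant:
  ## sigma is resolved once, against the first swept setting, and held
  ## fixed across the sweep so that sd curves are exact constant multiples
  ## of sqrt(diag((B^T B)^{-1})).
  ref <- mc_model(amplitude, T2 = c(T21, T22_values[1]))
  sigma <- resolve_sigma(noise_spec(snr = snr), eval_signal(ref, grid))
  noise <- noise_spec(sigma = sigma)
  rows <- lapply(seq_along(T22_values), function(i) {
    T22 <- T22_values[i]
    model <- mc_model(amplitude, T2 = c(T21, T22))
    row <- data.frame(T2_2 = T22)
    if (mode != "monte-carlo")
      row <- cbind(row, .analytic_row(model, grid, noise))
    if (mode != "analytic" && T22 != T21)
      row <- cbind(row, .mc_row(model, grid, noise, n_realizations, config,
                                .row_seed(seed, i, n_realizations)))
    row
  })
  rows <- do.call(.rbind_fill, list(rows))
  sweep_result(rows, list(stage = "sweep_1d_coalescence", mode = mode,
                          amplitude = amplitude, T21 = T21,
                          T22_values = T22_values, snr = snr,
                          sigma = sigma,
                          n_realizations = n_realizations, seed = seed,
                          grid = grid, config = config))
}

#' 2D T1-separation sweep
#'
#' With the amplitudes, both T2s, and \eqn{T_{1,1}} fixed, sweep
#' \eqn{T_{1,2}} and record linearized SDs / condition number (and
#' optionally Monte-Carlo SDs) for the inversion-recovery CPMG model.  The
#' SDs peak where \eqn{T_{1,2} = T_{1,1}} — the indirect dimension then
#' carries no discriminating information — and decrease as the two T1s
#' separate, while remaining finite as long as the T2s differ.
#'
#' @param T12_values swept \eqn{T_{1,2}} values (ms).  \code{T1} of the
#'   second listed component is swept; the first keeps \code{T11}.
#' @param amplitude,T2 fixed amplitudes and T2 pair (ms).  Default preset
#'   \code{c(0.3, 0.7)}, \code{c(60, 45)} (the analytic preset; the
#'   Monte-Carlo figures use \code{T2 = c(45, 60)}).
#' @param T11 fixed \eqn{T_{1,1}} (ms), attached to the first listed
#'   component.
#' @param grid 2D acquisition grid (default 64 x 25 = 1600 points).
#' @param snr SNR (default 400, the 2D Monte-Carlo setting).
#' @inheritParams sweep_1d_coalescence
#' @return A \code{"sweep_result"} with one row per \eqn{T_{1,2}} value.
#' @export
sweep_2d_T1separation <- function(T12_values,
                                  amplitude = c(0.3, 0.7), T2 = c(60, 45),
                                  T11 = 1000,
                                  grid = default_grid("T1T2"),
                                  snr = 400,
                                  mode = c("analytic", "monte-carlo", "both"),
                                  n_realizations = 1000,
                                  config = fit_config(), seed = 1L) {
  mode <- match.arg(mode)
  T12_values <- as.numeric(T12_values)
  ref <- mc_model(amplitude, T2 = T2, T1 = c(T11, T12_values[1]))
  sigma <- resolve_sigma(noise_spec(snr = snr), eval_signal(ref, grid))
  noise <- noise_spec(sigma = sigma)
  rows <- lapply(seq_along(T12_values), function(i) {
    T12 <- T12_values[i]
    model <- mc_model(amplitude, T2 = T2, T1 = c(T11, T12))
    row <- data.frame(T1_2 = T12)
    if (mode != "monte-carlo")
      row <- cbind(row, .analytic_row(model, grid, noise))
    if (mode != "analytic")
      row <- cbind(row, .mc_row(model, grid, noise, n_realizations, config,
                                .row_seed(seed, i, n_realizations)))
    row
  })
  rows <- do.call(.rbind_fill, list(rows))
  sweep_result(rows, list(stage = "sweep_2d_T1separation", mode = mode,
                          amplitude = amplitude, T2 = T2, T11 = T11,
                          T12_values = T12_values, snr = snr,
                          sigma = sigma,
                          n_realizations = n_realizations, seed = seed,
                          grid = grid, config = config))
}

#' Condition numbers of matched 1D / 2D / 3D models
#'
#' Compares the Jacobian condition number of the 1D T2-only model with the
#' 2D T1-T2 model (and, when \code{ADC} is supplied, the 3D T1-T2-ADC
#' model) across a sweep of \eqn{T_{1,2}}.  The 1D condition number has no
#' T1 dependence and is constant across the sweep; at
#' \eqn{T_{1,2} = T_{1,1}} the 2D value is close to the 1D one, and it
#' drops below it as the T1s separate.
#'
#' @inheritParams sweep_2d_T1separation
#' @param ADC optional length-2 vector \code{c(ADC1, ADC2)} in mm^2/ms to
#'   add a 3D column on the default b grid.
#' @param grid_1d,grid_2d,grid_3d acquisition grids for each dimensionality.
#' @return A \code{"sweep_result"}; rows hold \code{T1_2},
#'   \code{cond_1d}, \code{cond_2d}, and optionally \code{cond_3d}.
#' @examples
#' sw <- sweep_condition_numbers(c(500, 1000, 2000),
#'                               amplitude = c(0.3, 0.7), T2 = c(60, 45))
#' sw$rows
#' @export
sweep_condition_numbers <- function(T12_values,
                                    amplitude = c(0.3, 0.7), T2 = c(60, 45),
                                    T11 = 1000, ADC = NULL,
                                    grid_1d = default_grid("T2"),
                                    grid_2d = default_grid("T1T2"),
                                    grid_3d = default_grid("T1T2ADC")) {
  T12_values <- as.numeric(T12_values)
  model_1d <- mc_model(amplitude, T2 = T2)
  cond_1d <- model_condition_number(model_1d, grid_1d)
  rows <- lapply(T12_values, function(T12) {
    model_2d <- mc_model(amplitude, T2 = T2, T1 = c(T11, T12))
    row <- data.frame(T1_2 = T12, cond_1d = cond_1d,
                      cond_2d = model_condition_number(model_2d, grid_2d))
    if (!is.null(ADC)) {
      model_3d <- mc_model(amplitude, T2 = T2, T1 = c(T11, T12), ADC = ADC)
      row$cond_3d <- model_condition_number(model_3d, grid_3d)
    }
    row
  })
  sweep_result(do.call(rbind, rows),
               list(stage = "sweep_condition_numbers", mode = "analytic",
                    amplitude = amplitude, T2 = T2, T11 = T11, ADC = ADC,
                    T12_values = T12_values,
                    grid_1d = grid_1d, grid_2d = grid_2d, grid_3d = grid_3d))
}

#' 3D (T1,2 x ADC2) stability surface
#'
#' Linearized SD surfaces for the three-dimensional T1-T2-ADC model over a
#' grid of the two indirect-dimension parameters of the second component,
#' \eqn{(T_{1,2}, ADC_2)}, with everything else fixed.  Each row also
#' carries the condition numbers of the matched 3D, 2D (same parameters
#' without ADC), and 1D (T2 only) models: instability is greatest where
#' both \eqn{T_{1,2} = T_{1,1}} and \eqn{ADC_2 = ADC_1}, and each added
#' dimension's condition number is bounded above by the next-lower one.
#'
#' @param T12_values,ADC2_values swept axes (ms, mm^2/ms).
#' @param amplitude,T2,T11,ADC1 fixed parameters; defaults
#'   \code{c(0.7, 0.3)}, \code{c(45, 60)} ms, 1000 ms, 1.5 mm^2/ms.
#' @param grid 3D acquisition grid (default 64 x 25 x 9 = 14400 points).
#' @param snr SNR (multiplicative scale for the SDs).
#' @return A \code{"sweep_result"}; rows over the full
#'   \code{T12 x ADC2} grid with \code{sd_*}, \code{cond_3d},
#'   \code{cond_2d}, \code{cond_1d}.
#' @export
sweep_3d <- function(T12_values, ADC2_values,
                     amplitude = c(0.7, 0.3), T2 = c(45, 60),
                     T11 = 1000, ADC1 = 1.5,
                     grid = default_grid("T1T2ADC"),
                     snr = 400) {
  T12_values <- as.numeric(T12_values)
  ADC2_values <- as.numeric(ADC2_values)
  ref <- mc_model(amplitude, T2 = T2, T1 = c(T11, T12_values[1]),
                  ADC = c(ADC1, ADC2_values[1]))
  sigma <- resolve_sigma(noise_spec(snr = snr), eval_signal(ref, grid))
  noise <- noise_spec(sigma = sigma)
  grid_2d <- acq_grid(TE = grid$TE, TI = grid$TI)
  grid_1d <- acq_grid(TE = grid$TE)
  cond_1d <- model_condition_number(mc_model(amplitude, T2 = T2), grid_1d)
  pairs <- expand.grid(T1_2 = T12_values, ADC_2 = ADC2_values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    T12 <- pairs$T1_2[i]; ADC2 <- pairs$ADC_2[i]
    model <- mc_model(amplitude, T2 = T2, T1 = c(T11, T12),
                      ADC = c(ADC1, ADC2))
    model_2d <- mc_model(amplitude, T2 = T2, T1 = c(T11, T12))
    row <- cbind(data.frame(T1_2 = T12, ADC_2 = ADC2),
                 .analytic_row(model, grid, noise))
    row$cond_3d <- row$condition_number
    row$cond_2d <- model_condition_number(model_2d, grid_2d)
    row$cond_1d <- cond_1d
    row
  })
  sweep_result(do.call(rbind, rows),
               list(stage = "sweep_3d", mode = "analytic",
                    amplitude = amplitude, T2 = T2, T11 = T11, ADC1 = ADC1,
                    T12_values = T12_values, ADC2_values = ADC2_values,
                    snr = snr, sigma = sigma, grid = grid))
}

## rbind data frames whose column sets may differ (singular rows drop MC
## columns); missing columns are filled with NA.
.rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  filled <- lapply(rows, function(r) {
    miss <- setdiff(cols, names(r))
    for (m in miss) r[[m]] <- NA
    r[cols]
  })
  do.call(rbind, filled)
}

#' Plot a sweep result
#'
#' Quick base-graphics view: parameter SDs (log scale) against the swept
#' variable, or condition numbers for a condition-number sweep.
#'
#' @param x a \code{"sweep_result"}.
#' @param which character vector of row columns to draw; default: all
#'   \code{sd_*} columns (or all \code{cond_*} columns if no SDs).
#' @param ... passed to \code{matplot}.
#' @return Invisibly, \code{x}.
#' @export
plot.sweep_result <- function(x, which = NULL, ...) {
  rows <- x$rows
  xcol <- names(rows)[1]
  if (is.null(which)) {
    which <- grep("^sd_", names(rows), value = TRUE)
    if (length(which) == 0)
      which <- grep("^cond_", names(rows), value = TRUE)
  }
  y <- as.matrix(rows[, which, drop = FALSE])
  ok <- is.finite(rowSums(y))
  graphics::matplot(rows[[xcol]][ok], y[ok, , drop = FALSE], type = "b",
                    pch = 1, log = "y", xlab = xcol, ylab = "value", ...)
  graphics::legend("topright", legend = which, col = seq_along(which),
                   lty = seq_along(which), cex = 0.8)
  invisible(x)
}
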