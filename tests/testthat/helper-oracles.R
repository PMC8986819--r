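# Independent oracles used to cross-check the analytic implementation.
# These deliberately avoid the package's own evaluation paths.

# Central finite-difference Jacobian of the vectorized signal, built on a
# naive pointwise evaluation of the model formula.
naive_signal_point <- function(amplitude, T2, T1, ADC, TE, TI = NA, b = NA) {
  s <- 0
  for (i in seq_along(amplitude)) {
    term <- amplitude[i] * exp(-TE / T2[i])
    if (!is.na(TI)) term <- term * (1 - 2 * exp(-TI / T1[i]))
    if (!is.na(b)) term <- term * exp(-b * ADC[i])
    s <- s + term
  }
  s
}

# Flat signal vector by explicit loops over the grid, TE fastest then TI
# then b (the documented vectorization order).
naive_signal_flat <- function(amplitude, T2, T1, ADC, grid) {
  TIs <- if (is.null(grid$TI)) NA_real_ else grid$TI
  bs <- if (is.null(grid$b)) NA_real_ else grid$b
  out <- numeric(0)
  for (bv in bs) for (ti in TIs) for (te in grid$TE)
    out <- c(out, naive_signal_point(amplitude, T2, T1, ADC, te, ti, bv))
  out
}

fd_jacobian <- function(model, grid, h_scale = 1e-6) {
  p <- model_params(model)
  n <- model$n
  dimensionality <- model$dimensionality
  cols <- lapply(seq_along(p), function(l) {
    h <- h_scale * max(1, abs(p[l]))
    pp <- p; pm <- p
    pp[l] <- p[l] + h; pm[l] <- p[l] - h
    up <- model_from_params(pp, n, dimensionality)
    um <- model_from_params(pm, n, dimensionality)
    (naive_signal_flat(up$amplitude, up$T2, up$T1, up$ADC, grid) -
       naive_signal_flat(um$amplitude, um$T2, um$T1, um$ADC, grid)) / (2 * h)
  })
  do.call(cbind, cols)
}

# Random well-posed model/grid pairs for property tests.
rand_model <- function(dimensionality = c("T2", "T1T2", "T1T2ADC"),
                       n = 2L) {
  dimensionality <- match.arg(dimensionality)
  amp <- runif(n, 0.2, 1)
  T2 <- sort(runif(n, 20, 200)) * c(1, cumprod(rep(1.5, n - 1)))
  T1 <- if (dimensionality != "T2") runif(n, 300, 2000) else NULL
  ADC <- if (dimensionality == "T1T2ADC") runif(n, 0.3, 3) else NULL
  mc_model(amp, T2 = T2, T1 = T1, ADC = ADC)
}

rand_grid <- function(dimensionality = c("T2", "T1T2", "T1T2ADC")) {
  dimensionality <- match.arg(dimensionality)
  TE <- sort(sample(seq(4, 600, by = 4), sample(5:12, 1)))
  TI <- if (dimensionality != "T2")
    sort(sample(seq(20, 4000, by = 20), sample(4:8, 1))) else NULL
  b <- if (dimensionality == "T1T2ADC")
    sort(sample(seq(0, 2, by = 0.25), sample(3:5, 1))) else NULL
  acq_grid(TE = TE, TI = TI, b = b)
}
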