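#' Synthetic two-gel phantom experiment specification
#'
#' Defines a synthetic stand-in for a two-gel relaxometry phantom study:
#' repeated noisy 1D CPMG and 2D IR-CPMG acquisitions of a two-component
#' gel.  Defaults emulate a doped-agarose two-plug phantom: amplitudes
#' (0.47, 0.53), \eqn{T_2} = (36.3, 45.9) ms, \eqn{T_1} = (157, 405) ms;
#' a CPMG echo train of 2048 echoes at TE = 0.4, 0.8, ..., 819.2 ms; 24
#' inversion times spaced geometrically from 15 ms to 2 s (the standard
#' nonlinear IR schedule; an explicit schedule can be supplied instead);
#' SNR about 9000 for the signal-averaged 1D pathway and about 2000 for
#' 2D; 100 repeats.
#'
#' @param gel_model the ground-truth \code{\link{mc_model}} (must carry T1).
#' @param TE CPMG echo times in ms.
#' @param TI inversion-time schedule in ms (default: 24 geometric steps,
#'   15 to 2000 ms).
#' @param snr_1d,snr_2d pathway SNRs (the 1D pathway folds its signal
#'   averaging into a higher SNR).
#' @param n_repeats number of repeated acquisitions per pathway.
#' @param seed master seed for the noise realizations.
#' @return Object of class \code{"experiment_spec"} including the derived
#'   \code{grid_1d} and \code{grid_2d}.
#' @examples
#' spec <- gel_experiment(n_repeats = 5)
#' length(spec$grid_1d$TE)   # 2048
#' length(spec$grid_2d$TI)   # 24
#' @export
gel_experiment <- function(gel_model = mc_model(c(0.47, 0.53),
                                                T2 = c(36.3, 45.9),
                                                T1 = c(157, 405)),
                           TE = seq(0.4, 819.2, by = 0.4),
                           TI = exp(seq(log(15), log(2000), length.out = 24)),
                           snr_1d = 9000, snr_2d = 2000,
                           n_repeats = 100, seed = 1L) {
  stopifnot(inherits(gel_model, "mc_model"), !is.null(gel_model$T1),
            n_repeats >= 1)
  structure(list(gel_model = gel_model,
                 grid_1d = acq_grid(TE = TE),
                 grid_2d = acq_grid(TE = TE, TI = TI),
                 snr_1d = snr_1d, snr_2d = snr_2d,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

## 1D pathway model: the CPMG acquisition has no inversion preparation,
## so the T2-only projection of the gel is what it samples.
.gel_1d_model <- function(gel) mc_model(gel$amplitude, T2 = gel$T2)

#' Generate the emulated phantom acquisitions
#'
#' Produces \code{n_repeats} independent Gaussian-noise realizations of the
#' noiseless gel signal for each pathway.  Both pathways share the gel
#' model; each resolves its own sigma from its SNR against its own
#' noiseless signal maximum.  Fully reproducible from the spec's seed.
#'
#' @param spec an \code{\link{gel_experiment}} specification.
#' @return Object of class \code{"experiment_data"}: lists \code{one_d} and
#'   \code{two_d} of noisy \code{"signal_array"}s (length
#'   \code{n_repeats} each) plus the \code{spec} and the resolved
#'   \code{sigma_1d} / \code{sigma_2d}.
#' @export
emulate_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  clean_1d <- eval_signal(.gel_1d_model(spec$gel_model), spec$grid_1d)
  clean_2d <- eval_signal(spec$gel_model, spec$grid_2d)
  sigma_1d <- resolve_sigma(noise_spec(snr = spec$snr_1d), clean_1d)
  sigma_2d <- resolve_sigma(noise_spec(snr = spec$snr_2d), clean_2d)
  one_d <- lapply(seq_len(spec$n_repeats), function(i)
    add_noise(clean_1d, noise_spec(sigma = sigma_1d),
              seed = .sub_seed(spec$seed, 2 * i)))
  two_d <- lapply(seq_len(spec$n_repeats), function(i)
    add_noise(clean_2d, noise_spec(sigma = sigma_2d),
              seed = .sub_seed(spec$seed, 2 * i + 1)))
  structure(list(one_d = one_d, two_d = two_d, spec = spec,
                 sigma_1d = sigma_1d, sigma_2d = sigma_2d),
            class = "experiment_data")
}

## Fit a collection of already-noisy signals and summarize like run_mc.
.fit_collection <- function(signals, grid, truth, n, dimensionality,
                            config, seed, sigma, snr) {
  f <- config$init_fraction
  rows <- lapply(seq_along(signals), function(i) {
    set.seed(.sub_seed(seed, i))
    init <- truth * stats::runif(length(truth), 1 - f, 1 + f)
    if (config$amplitude_constraint)
      init[n] <- 1 - sum(init[seq_len(n - 1L)])
    fit <- fit_nlls(signals[[i]], grid, init, config, n = n)
    data.frame(realization = i, as.list(fit$params),
               residual_norm = fit$residual_norm, converged = fit$converged)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$converged & stats::complete.cases(tab)
  labs <- param_labels(n, dimensionality)
  est <- as.matrix(tab[ok, labs, drop = FALSE])
  failure_count <- sum(!ok)
  structure(list(per_realization = tab,
                 mean = setNames(colMeans(est), labs),
                 sd = setNames(apply(est, 2, stats::sd), labs),
                 n_realizations = length(signals),
                 snr_used = snr, sigma_used = sigma,
                 failure_count = failure_count,
                 flagged = failure_count > 0.05 * length(signals),
                 seed = seed, config = config),
            class = "mc_summary")
}

#' Analyze the emulated phantom acquisitions
#'
#' Fits every repeat of each pathway by NLLS (1D: biexponential T2 decay;
#' 2D: the full T1-T2 model), relabels by ascending fitted T2, and
#' summarizes per pathway.  The amplitude sum-to-one constraint is applied
#' by default on this pathway, mirroring constrained phantom fits; under
#' the constraint the two amplitude histograms are exact mirror images and
#' \code{sd(c1) == sd(c2)}.
#'
#' @param data an \code{"experiment_data"} from
#'   \code{\link{emulate_experiment}}.
#' @param config a \code{\link{fit_config}}; default applies the amplitude
#'   constraint.
#' @param seed seed for the initial-guess draws.
#' @return List with \code{"mc_summary"} elements \code{one_d} and
#'   \code{two_d} (shared parameters c1, c2, T2_1, T2_2; the 2D summary
#'   additionally holds T1_1, T1_2).
#' @export
analyze_emulated <- function(data,
                             config = fit_config(amplitude_constraint = TRUE),
                             seed = NULL) {
  stopifnot(inherits(data, "experiment_data"))
  spec <- data$spec
  if (is.null(seed)) seed <- .sub_seed(spec$seed, 990000)
  gel <- spec$gel_model
  truth_2d <- model_params(gel)
  truth_1d <- model_params(.gel_1d_model(gel))
  list(one_d = .fit_collection(data$one_d, spec$grid_1d, truth_1d,
                               gel$n, "T2", config,
                               .sub_seed(seed, 1), data$sigma_1d, spec$snr_1d),
       two_d = .fit_collection(data$two_d, spec$grid_2d, truth_2d,
                               gel$n, "T1T2", config,
                               .sub_seed(seed, 2), data$sigma_2d, spec$snr_2d))
}

#' Near-degeneracy of distinct biexponential models
#'
#' Evaluates two classic biexponential models with very different
#' component parameters,
#' \eqn{S_1(t) = 0.2 e^{-t/20} + 0.8 e^{-t/150}} and
#' \eqn{S_2(t) = 0.28 e^{-t/40} + 0.7 e^{-t/163}}, on a common time grid
#' and tabulates their pointwise difference.  Despite the disparate
#' parameters the two curves are nearly superposed — the redundancy at the
#' heart of the ill-posedness of multiexponential analysis.
#'
#' @param t_grid nonempty numeric vector of times (same units as the decay
#'   constants; t = 0 is allowed).
#' @return A data frame with columns \code{t}, \code{S1}, \code{S2},
#'   \code{diff}, carrying attributes \code{max_abs_diff} and
#'   \code{t_at_max}.
#' @examples
#' d <- lanczos_demo(seq(0, 400, by = 1))
#' attr(d, "max_abs_diff")
#' @export
lanczos_demo <- function(t_grid = seq(0, 400, by = 1)) {
  stopifnot(length(t_grid) >= 1, all(is.finite(t_grid)), all(t_grid >= 0))
  t <- as.numeric(t_grid)
  S1 <- 0.2 * exp(-t / 20) + 0.8 * exp(-t / 150)
  S2 <- 0.28 * exp(-t / 40) + 0.7 * exp(-t / 163)
  out <- data.frame(t = t, S1 = S1, S2 = S2, diff = S1 - S2)
  k <- which.max(abs(out$diff))
  attr(out, "max_abs_diff") <- abs(out$diff[k])
  attr(out, "t_at_max") <- t[k]
  out
}

#' Export emulated acquisitions as a long-format CSV
#'
#' One row per (repeat, grid point): columns \code{repeat_id}, \code{TI}
#' (NA for the 1D pathway), \code{TE}, \code{value}; a JSON sidecar records
#' the generating specification.  Real spectrometer tables exported in the
#' same layout can be substituted for the emulated ones.
#'
#' @param data an \code{"experiment_data"}.
#' @param pathway \code{"1d"} or \code{"2d"}.
#' @param path CSV output path; the sidecar is written to
#'   \code{<path>.json}.
#' @return The CSV path, invisibly.
#' @export
write_emulated_csv <- function(data, pathway = c("1d", "2d"), path) {
  stopifnot(inherits(data, "experiment_data"))
  pathway <- match.arg(pathway)
  signals <- if (pathway == "1d") data$one_d else data$two_d
  grid <- if (pathway == "1d") data$spec$grid_1d else data$spec$grid_2d
  rm <- grid_row_map(grid)
  tabs <- lapply(seq_along(signals), function(i)
    data.frame(repeat_id = i, TI = rm$TI, TE = rm$TE,
               value = vectorize(signals[[i]])))
  tab <- do.call(rbind, tabs)
  tab$value <- format(tab$value, digits = 17, trim = TRUE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  spec <- data$spec
  sidecar <- list(pathway = pathway,
                  gel = list(amplitude = spec$gel_model$amplitude,
                             T2 = spec$gel_model$T2, T1 = spec$gel_model$T1),
                  snr = if (pathway == "1d") spec$snr_1d else spec$snr_2d,
                  n_repeats = spec$n_repeats, seed = spec$seed,
                  TE = grid$TE, TI = grid$TI, units = "ms")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
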