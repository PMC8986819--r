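## Configuration loading and result writing shared by all pipeline stages.
## A run is reproducible from its config file alone: the config carries the
## stage name, the master seed, and every tunable, with documented defaults
## filled in and echoed back on load.

.STAGES <- c("demo-fig1", "sweep1d", "sweep2d", "sweep3d", "cond",
             "emulate", "analyze")

.default_or <- function(cfg, field, default) {
  if (is.null(cfg[[field]])) default else cfg[[field]]
}

#' Load and validate a pipeline run configuration
#'
#' Reads a JSON configuration, checks it against the stage's schema, fills
#' documented defaults, and returns the completed configuration.  Schema
#' violations raise an error naming the offending field.  Times are ms, b
#' in ms/mm^2, ADC in mm^2/ms throughout.
#'
#' Recognized stages: \code{demo-fig1}, \code{sweep1d}, \code{sweep2d},
#' \code{sweep3d}, \code{cond}, \code{emulate}, \code{analyze}.  For
#' example a minimal \code{sweep1d} config needs only
#' \code{\{"stage": "sweep1d", "T22_values": [70, 100, 150]\}}; the TE
#' grid (8..512 ms step 8), SNR (1e4), realization count (1000), and seed
#' (1) are filled in.
#'
#' @param path path to a JSON file (or a JSON string).
#' @return Object of class \code{"run_config"}: the validated, completed
#'   configuration list.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$stage))
    stop("config field 'stage' is required (one of: ",
         paste(.STAGES, collapse = ", "), ")")
  if (!cfg$stage %in% .STAGES)
    stop("config field 'stage': unknown stage '", cfg$stage, "'")
  cfg$seed <- .default_or(cfg, "seed", 1L)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config field 'seed' must be a single integer")
  cfg$log_level <- .default_or(cfg, "log_level", "info")

  need <- function(field) {
    if (is.null(cfg[[field]]))
      stop("config field '", field, "' is required for stage '",
           cfg$stage, "'")
    cfg[[field]]
  }
  pos <- function(field) {
    v <- cfg[[field]]
    if (!is.null(v) && (!is.numeric(v) || any(v <= 0)))
      stop("config field '", field, "' must be positive")
    v
  }

  if (cfg$stage == "sweep1d") {
    need("T22_values"); pos("T22_values")
    if (!is.null(cfg$TI))
      stop("config field 'TI': the sweep1d stage model has no T1 attribute")
    cfg$amplitude <- .default_or(cfg, "amplitude", c(0.3, 0.7))
    cfg$T21 <- .default_or(cfg, "T21", 60)
    cfg$TE <- .default_or(cfg, "TE", default_TE())
    cfg$snr <- .default_or(cfg, "snr", 1e4)
    cfg$mode <- .default_or(cfg, "mode", "analytic")
    cfg$n_realizations <- .default_or(cfg, "n_realizations", 1000)
  } else if (cfg$stage %in% c("sweep2d", "cond")) {
    need("T12_values"); pos("T12_values")
    cfg$amplitude <- .default_or(cfg, "amplitude", c(0.3, 0.7))
    cfg$T2 <- .default_or(cfg, "T2", c(60, 45))
    cfg$T11 <- .default_or(cfg, "T11", 1000)
    cfg$TE <- .default_or(cfg, "TE", default_TE())
    cfg$TI <- .default_or(cfg, "TI", default_TI())
    if (cfg$stage == "sweep2d") {
      cfg$snr <- .default_or(cfg, "snr", 400)
      cfg$mode <- .default_or(cfg, "mode", "analytic")
      cfg$n_realizations <- .default_or(cfg, "n_realizations", 1000)
    }
  } else if (cfg$stage == "sweep3d") {
    need("T12_values"); need("ADC2_values")
    cfg$amplitude <- .default_or(cfg, "amplitude", c(0.7, 0.3))
    cfg$T2 <- .default_or(cfg, "T2", c(45, 60))
    cfg$T11 <- .default_or(cfg, "T11", 1000)
    cfg$ADC1 <- .default_or(cfg, "ADC1", 1.5)
    cfg$TE <- .default_or(cfg, "TE", default_TE())
    cfg$TI <- .default_or(cfg, "TI", default_TI())
    cfg$b <- .default_or(cfg, "b", default_b())
    cfg$snr <- .default_or(cfg, "snr", 400)
  } else if (cfg$stage %in% c("emulate", "analyze")) {
    cfg$amplitude <- .default_or(cfg, "amplitude", c(0.47, 0.53))
    cfg$T2 <- .default_or(cfg, "T2", c(36.3, 45.9))
    cfg$T1 <- .default_or(cfg, "T1", c(157, 405))
    if (length(cfg$T1) != length(cfg$amplitude))
      stop("config field 'T1' must have one value per component")
    cfg$TE <- .default_or(cfg, "TE", seq(0.4, 819.2, by = 0.4))
    cfg$TI <- .default_or(cfg, "TI",
                          exp(seq(log(15), log(2000), length.out = 24)))
    cfg$snr_1d <- .default_or(cfg, "snr_1d", 9000)
    cfg$snr_2d <- .default_or(cfg, "snr_2d", 2000)
    cfg$n_repeats <- .default_or(cfg, "n_repeats", 100)
  } else if (cfg$stage == "demo-fig1") {
    cfg$t_max <- .default_or(cfg, "t_max", 400)
    cfg$t_step <- .default_or(cfg, "t_step", 1)
  }
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' Writes the config back to JSON; \code{load_config(save_config(cfg))}
#' round-trips.
#'
#' @param cfg a \code{"run_config"} (or plain list with a \code{stage}).
#' @param path output path.
#' @return The path, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Execute a pipeline stage from a configuration
#'
#' Dispatches a validated \code{\link{load_config}} configuration to the
#' corresponding pipeline function.  With a fixed config file the tabular
#' outputs are byte-identical across runs.
#'
#' @param cfg a \code{"run_config"}.
#' @return The stage's result object (a \code{"sweep_result"}, an
#'   \code{"experiment_data"}, a list of \code{"mc_summary"}s, or the
#'   demo table).
#' @export
run_stage <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  switch(cfg$stage,
    "demo-fig1" = lanczos_demo(seq(0, cfg$t_max, by = cfg$t_step)),
    "sweep1d" = sweep_1d_coalescence(cfg$T22_values,
                                     amplitude = cfg$amplitude, T21 = cfg$T21,
                                     grid = acq_grid(TE = cfg$TE),
                                     snr = cfg$snr, mode = cfg$mode,
                                     n_realizations = cfg$n_realizations,
                                     seed = cfg$seed),
    "sweep2d" = sweep_2d_T1separation(cfg$T12_values,
                                      amplitude = cfg$amplitude, T2 = cfg$T2,
                                      T11 = cfg$T11,
                                      grid = acq_grid(TE = cfg$TE, TI = cfg$TI),
                                      snr = cfg$snr, mode = cfg$mode,
                                      n_realizations = cfg$n_realizations,
                                      seed = cfg$seed),
    "sweep3d" = sweep_3d(cfg$T12_values, cfg$ADC2_values,
                         amplitude = cfg$amplitude, T2 = cfg$T2,
                         T11 = cfg$T11, ADC1 = cfg$ADC1,
                         grid = acq_grid(TE = cfg$TE, TI = cfg$TI, b = cfg$b),
                         snr = cfg$snr),
    "cond" = sweep_condition_numbers(cfg$T12_values,
                                     amplitude = cfg$amplitude, T2 = cfg$T2,
                                     T11 = cfg$T11, ADC = cfg$ADC,
                                     grid_1d = acq_grid(TE = cfg$TE),
                                     grid_2d = acq_grid(TE = cfg$TE, TI = cfg$TI)),
    "emulate" = emulate_experiment(.cfg_experiment(cfg)),
    "analyze" = analyze_emulated(emulate_experiment(.cfg_experiment(cfg))))
}

.cfg_experiment <- function(cfg) {
  gel_experiment(gel_model = mc_model(cfg$amplitude, T2 = cfg$T2, T1 = cfg$T1),
                 TE = cfg$TE, TI = cfg$TI,
                 snr_1d = cfg$snr_1d, snr_2d = cfg$snr_2d,
                 n_repeats = cfg$n_repeats, seed = cfg$seed)
}

## Full-precision numeric formatting so rerun CSVs are byte-identical and
## round-trip through read.csv exactly.
.full_precision <- function(tab) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) format(x, digits = 17, trim = TRUE))
  tab
}

#' Write stage results to a directory
#'
#' Writes CSV tables (full double precision, fixed column order), a JSON
#' summary, and a provenance block (stage spec echo, seed, package
#' version) into \code{outdir}, overwriting existing files of the same
#' names.  Returns the manifest of files written.
#'
#' @param result a \code{"sweep_result"}, \code{"mc_summary"}, or the
#'   output of \code{\link{analyze_emulated}} / \code{\link{lanczos_demo}}.
#' @param outdir output directory (created if absent).
#' @param name base filename; defaults to the result's stage name.
#' @return Character vector of the paths written, invisibly.
#' @export
write_results <- function(result, outdir, name = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  emit_csv <- function(tab, file) {
    p <- file.path(outdir, file)
    utils::write.csv(.full_precision(tab), p, row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
  }
  emit_json <- function(obj, file) {
    p <- file.path(outdir, file)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <<- c(written, p)
  }
  version <- as.character(utils::packageVersion("relaxstab"))
  if (inherits(result, "sweep_result")) {
    if (is.null(name)) name <- result$spec$stage
    emit_csv(result$rows, paste0(name, ".csv"))
    prov <- result$spec
    prov$grid <- NULL; prov$grid_1d <- NULL; prov$grid_2d <- NULL
    prov$grid_3d <- NULL; prov$config <- NULL
    emit_json(list(provenance = prov, package_version = version),
              paste0(name, "_provenance.json"))
  } else if (inherits(result, "mc_summary")) {
    if (is.null(name)) name <- "mc"
    emit_csv(result$per_realization, paste0(name, ".csv"))
    emit_json(list(mean = as.list(result$mean), sd = as.list(result$sd),
                   n_realizations = result$n_realizations,
                   snr = result$snr_used, sigma = result$sigma_used,
                   failure_count = result$failure_count,
                   seed = result$seed, package_version = version),
              paste0(name, "_summary.json"))
  } else if (is.list(result) && inherits(result$one_d, "mc_summary")) {
    written <- c(written,
                 write_results(result$one_d, outdir, name = "pathway_1d"),
                 write_results(result$two_d, outdir, name = "pathway_2d"))
  } else if (is.data.frame(result)) {
    if (is.null(name)) name <- "table"
    emit_csv(result, paste0(name, ".csv"))
  } else {
    stop("no writer for objects of class ", paste(class(result), collapse = "/"))
  }
  manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(list(files = basename(written),
                            package_version = version),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(written, manifest))
}
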