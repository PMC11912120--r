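# File I/O, configuration and the end-to-end pipeline.

.detect_sep <- function(line) {
  if (grepl(",", line, fixed = TRUE)) "," else if (grepl("\t", line,
                                                         fixed = TRUE)) "\t"
  else " "
}

#' Read a two-column spectrum file
#'
#' Delimited text with two numeric columns (comma, tab or whitespace
#' separated) and an optional single header line. The first column becomes
#' the mass axis when it is strictly monotone and non-integer; otherwise it
#' is treated as a plain sample index.
#'
#' @param path File path.
#' @return An [ms_spectrum].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("format error in ", path, ": fewer than 2 data rows",
         call. = FALSE)
  }
  sep <- .detect_sep(lines[[1L]])
  split1 <- function(s) {
    if (sep == " ") strsplit(trimws(s), "[ \t]+")[[1L]]
    else strsplit(s, sep, fixed = TRUE)[[1L]]
  }
  first <- split1(lines[[1L]])
  header <- suppressWarnings(anyNA(as.numeric(first)))
  start <- if (header) 2L else 1L
  if (length(lines) - start + 1L < 2L) {
    stop("format error in ", path, ": fewer than 2 data rows",
         call. = FALSE)
  }
  col1 <- numeric(0)
  col2 <- numeric(0)
  for (i in seq.int(start, length(lines))) {
    parts <- split1(lines[[i]])
    if (length(parts) != 2L) {
      stop("format error in ", path, " line ", i, ": expected 2 columns, ",
           "got ", length(parts), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals)) {
      stop("format error in ", path, " line ", i, ": non-numeric cell",
           call. = FALSE)
    }
    col1 <- c(col1, vals[1L])
    col2 <- c(col2, vals[2L])
  }
  d1 <- diff(col1)
  monotone <- all(d1 > 0) || all(d1 < 0)
  integer_axis <- all(col1 == round(col1))
  mass_axis <- if (monotone && !integer_axis) col1 else NULL
  ms_spectrum(col2, mass_axis = mass_axis,
              metadata = list(source = path,
                              header = if (header) first else NULL))
}

#' Write a spectrum as two-column delimited text
#'
#' Writes `mz,intensity` when a mass axis is present, `index,intensity`
#' otherwise, at full float precision so that a read/write round trip is
#' the identity.
#'
#' @param spectrum An [ms_spectrum] (or numeric vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  y <- as_intensities(spectrum)
  axis <- if (inherits(spectrum, "ms_spectrum")) spectrum$mass_axis
  if (is.null(axis)) {
    header <- "index,intensity"
    axis <- seq_along(y) - 1L
    axis_txt <- format(axis, trim = TRUE, scientific = FALSE)
  } else {
    header <- "mz,intensity"
    axis_txt <- sprintf("%.17g", axis)
  }
  writeLines(c(header, paste(axis_txt, sprintf("%.17g", y), sep = ",")),
             path)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' @param input Path to a spectrum file, or `NULL` to use the built-in
#'   simulator profile.
#' @param wavelet Wavelet name or `"auto"` for ESER selection.
#' @param level Decomposition depth.
#' @param levels Detail levels to filter.
#' @param rule `"hard"` or `"soft"`.
#' @param tophat_window Top-hat window width (odd), or `NULL` for the 1%
#'   default.
#' @param peak_window,noise_window S/N index intervals, or `NULL` to take
#'   the simulator profile's defaults (simulated input only).
#' @param seed RNG seed; mandatory when simulating.
#' @param n_samples Simulated transient length.
#' @param candidates Candidate list for `wavelet = "auto"`.
#' @param report_digits Rounding applied to reported percentages.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, wavelet = "rbio5.5", level = 11L,
                       levels = 1:6, rule = "hard", tophat_window = NULL,
                       peak_window = NULL, noise_window = NULL, seed = NULL,
                       n_samples = 200000L, candidates = wavelet_catalogue(),
                       report_digits = 2L) {
  if (is.null(input) && is.null(seed)) {
    stop("a seed is mandatory for simulated input", call. = FALSE)
  }
  structure(list(input = input, wavelet = wavelet, level = as.integer(level),
                 levels = as.integer(levels), rule = rule,
                 tophat_window = tophat_window, peak_window = peak_window,
                 noise_window = noise_window, seed = seed,
                 n_samples = as.integer(n_samples), candidates = candidates,
                 report_digits = as.integer(report_digits)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key/value YAML holding any subset of the [run_config()] fields.
#'
#' @param path YAML file path.
#' @return List of class `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Run the full denoising pipeline
#'
#' (Optionally simulate) -> (optionally ESER-select the wavelet) ->
#' EBW-denoise -> top-hat baseline correction -> S/N report. With an output
#' directory the artifact bundle is written to disk: the denoised spectrum,
#' the ESER table (when `wavelet = "auto"`), a threshold/energy report, the
#' S/N report, and a log recording the package version, a configuration
#' hash and the seed. The bundle is a pure function of (input bytes,
#' config, seed).
#'
#' @param config A [run_config()] (or path to a YAML config file).
#' @param output_dir Optional directory for the artifact bundle.
#' @return List of class `pipeline_result` with `spectrum`, `truth`
#'   (simulated input only), `fit` (the [ebw_denoise()] object),
#'   `corrected` (baseline-corrected denoised intensities), `report`
#'   (an `sn_report`), `eser_table` (when auto-selecting) and `config`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  if (is.null(config$input)) {
    prof <- default_profile(config$n_samples)
    sim <- stage("simulate",
                 simulate_spectrum(prof$peaks, prof$scan, prof$noise_sigma,
                                   config$seed, prof$mass_range))
    spec <- sim$spectrum
    truth <- sim$truth
    if (is.null(config$peak_window)) config$peak_window <- prof$peak_window
    if (is.null(config$noise_window)) config$noise_window <- prof$noise_window
  } else {
    spec <- stage("read", read_spectrum(config$input))
    if (is.null(config$peak_window) || is.null(config$noise_window)) {
      stop("pipeline stage 'config' failed: peak_window and noise_window ",
           "are required for file input", call. = FALSE)
    }
  }

  eser_tab <- NULL
  wavelet <- config$wavelet
  if (identical(wavelet, "auto")) {
    eser_tab <- stage("select-wavelet",
                      eser_scan(spec, config$candidates, config$level))
    wavelet <- select_wavelet(eser_tab)$wavelet
  }

  fit <- stage("denoise",
               ebw_denoise(spec, wavelet = wavelet, level = config$level,
                           levels = config$levels, rule = config$rule))
  corrected <- stage("baseline",
                     tophat_correct(fitted(fit), config$tophat_window))
  raw_corrected <- tophat_correct(spec, config$tophat_window)
  report <- stage("report",
                  sn_report(raw_corrected, corrected, config$peak_window,
                            config$noise_window))

  result <- structure(list(spectrum = spec, truth = truth, fit = fit,
                           corrected = corrected, report = report,
                           eser_table = eser_tab, config = config),
                      class = "pipeline_result")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    denoised_spec <- ms_spectrum(corrected,
                                 sample_rate = spec$sample_rate,
                                 mode = spec$mode,
                                 mass_axis = spec$mass_axis)
    write_spectrum(denoised_spec, file.path(output_dir, "denoised.csv"))
    if (!is.null(eser_tab)) {
      write_eser_table(eser_tab, file.path(output_dir, "eser_table.tsv"))
    }
    thr <- list(method = fit$method, wavelet = fit$wavelet,
                level = fit$level, levels = fit$levels, rule = fit$rule,
                thresholds = fit$thresholds,
                coefficients_zeroed = fit$coefficients_zeroed,
                energy_before = as.list(fit$energy_before$per_level_energy),
                energy_after = as.list(fit$energy_after$per_level_energy))
    jsonlite::write_json(thr, file.path(output_dir, "threshold_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    sn <- unclass(report)
    sn$percent_increase <- round(sn$percent_increase, config$report_digits)
    jsonlite::write_json(sn, file.path(output_dir, "sn_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    cfg <- unclass(config)
    log <- list(package_version =
                  as.character(utils::packageVersion("ebwdenoise")),
                config_hash = .config_hash(cfg),
                seed = config$seed,
                wavelet_used = fit$wavelet)
    jsonlite::write_json(log, file.path(output_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  result
}

# Stable hash of the configuration: md5 of its deparsed canonical form.
.config_hash <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  print(x$fit)
  print(x$report)
  invisible(x)
}
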