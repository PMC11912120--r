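# S3 methods for the ebw_denoise fit object.

#' @export
print.ebw_denoise <- function(x, ...) {
  cat(x$method, " wavelet denoise: '", x$wavelet, "', J = ", x$level,
      ", ", x$rule, " rule on cD", paste(range(x$levels), collapse = "-cD"),
      "\n", sep = "")
  if (!is.null(x$selection)) {
    cat("  wavelet chosen by ESER (", x$selection$policy, ")\n", sep = "")
  }
  removed <- x$energy_before$total_energy - x$energy_after$total_energy
  cat("  signal length ", length(x$raw), "; coefficient energy removed ",
      format(removed, digits = 4), " (",
      format(100 * removed / max(x$energy_before$total_energy,
                                 .Machine$double.xmin), digits = 3),
      "% of total)\n", sep = "")
  invisible(x)
}

#' @export
summary.ebw_denoise <- function(object, ...) {
  lev <- seq_len(object$level)
  tab <- data.frame(
    level = paste0("cD", lev),
    threshold = object$thresholds,
    zeroed = object$coefficients_zeroed,
    energy_before = object$energy_before$per_level_energy[lev],
    energy_after = object$energy_after$per_level_energy[lev]
  )
  out <- list(fit = object, bands = tab)
  class(out) <- "summary.ebw_denoise"
  out
}

#' @export
print.summary.ebw_denoise <- function(x, ...) {
  print(x$fit)
  cat("\nPer-level thresholds and band energies:\n")
  print(x$bands, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-level thresholds of a denoise fit
#'
#' @param object An `ebw_denoise` object.
#' @param ... Unused.
#' @return Named numeric vector `cD1..cDJ`; `NA` for untouched levels.
#' @export
coef.ebw_denoise <- function(object, ...) {
  stats::setNames(object$thresholds, paste0("cD", seq_len(object$level)))
}

#' @export
fitted.ebw_denoise <- function(object, ...) object$denoised

#' Removed component of a denoise fit
#'
#' The raw signal minus the denoised one: the interference and noise that
#' the thresholding removed.
#'
#' @param object An `ebw_denoise` object.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
residuals.ebw_denoise <- function(object, ...) object$raw - object$denoised

#' Plot raw, denoised and removed components
#'
#' @param x An `ebw_denoise` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ebw_denoise <- function(x, ...) {
  old <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  idx <- seq_along(x$raw)
  graphics::plot(idx, x$raw, type = "l", ylab = "raw", xlab = "", ...)
  graphics::plot(idx, x$denoised, type = "l", ylab = "denoised", xlab = "",
                 ...)
  graphics::plot(idx, x$raw - x$denoised, type = "l", ylab = "removed",
                 xlab = "sample", ...)
  invisible(x)
}
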