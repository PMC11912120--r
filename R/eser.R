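# Energy-to-Shannon-entropy ratio (ESER) mother-wavelet selection.
#
# Each detail band is treated as a discrete probability distribution
# p_k = c_k^2 / sum(c^2). A band that concentrates its energy in few large
# coefficients has low Shannon entropy; dividing band energy by that entropy
# rewards wavelets that represent the transient compactly. The wavelet
# attaining the highest ESER on the detail bands is selected. The
# approximation band is excluded: selection is driven by the detail
# coefficients, where the noise-related microstructure lives.

#' Shannon entropy of a coefficient band
#'
#' Entropy in bits of the normalized squared-coefficient distribution, with
#' the `0 * log(0) = 0` convention. An all-zero band is degenerate and
#' returns 0 with attribute `degenerate = TRUE`.
#'
#' @param coeffs Non-empty numeric vector.
#' @return Entropy in bits, bounded by `log2(length(coeffs))`.
#' @examples
#' shannon_entropy(rep(3, 8))            # log2(8) = 3
#' shannon_entropy(c(sqrt(2), 1, 1))     # p = (1/2, 1/4, 1/4): 1.5 bits
#' @export
shannon_entropy <- function(coeffs) {
  if (length(coeffs) == 0L) stop("empty coefficient array", call. = FALSE)
  e <- coeffs^2
  total <- sum(e)
  if (total == 0) {
    return(structure(0, degenerate = TRUE))
  }
  p <- e / total
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Energy-to-Shannon-entropy ratio of a band
#'
#' `R = sum(c^2) / H` with `H` the [shannon_entropy()] of the band, in
#' intensity-squared per bit. The ratio is scale-covariant: scaling the
#' coefficients by `c` multiplies it by `c^2` (entropy is scale-invariant).
#' Bands with zero entropy (all-zero, or a single nonzero coefficient) have
#' no defined ratio and return `NA` so the caller can exclude them.
#'
#' @param coeffs Non-empty numeric vector.
#' @return The ratio, or `NA_real_` when the entropy is zero.
#' @export
eser <- function(coeffs) {
  if (length(coeffs) == 0L) stop("empty coefficient array", call. = FALSE)
  energy <- sum(coeffs^2)
  h <- shannon_entropy(coeffs)
  if (h <= 0) return(NA_real_)
  energy / as.numeric(h)
}

#' ESER scan across candidate wavelets
#'
#' Decomposes the transient with every candidate wavelet to depth `level`
#' and tabulates per-detail-level energy, Shannon entropy and their ratio.
#'
#' @param x Numeric vector or [ms_spectrum].
#' @param wavelets Character vector of catalogue names (default: the full
#'   catalogue).
#' @param level Decomposition depth (default 11, capped informatively if
#'   too deep for short signals).
#' @param mode Boundary handling passed to [wt_decompose()].
#' @return A data frame of class `eser_table` with columns `wavelet`,
#'   `level`, `energy`, `entropy`, `eser` and logical `degenerate`; one row
#'   per (wavelet, detail level). Attributes record `depth`, `mode` and the
#'   signal length.
#' @export
eser_scan <- function(x, wavelets = wavelet_catalogue(), level = 11L,
                      mode = c("periodized", "symmetric")) {
  x <- as_intensities(x)
  mode <- match.arg(mode)
  unknown <- setdiff(wavelets, wavelet_catalogue())
  if (length(unknown) > 0L) {
    stop("unknown wavelet(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(wavelets, function(w) {
    dec <- wt_decompose(x, w, level, mode)
    energy <- vapply(dec$details, function(d) sum(d^2), numeric(1))
    entropy <- vapply(dec$details, function(d) as.numeric(shannon_entropy(d)),
                      numeric(1))
    ratio <- ifelse(entropy > 0, energy / entropy, NA_real_)
    data.frame(wavelet = w, level = seq_len(level), energy = energy,
               entropy = entropy, eser = ratio,
               degenerate = energy == 0 | entropy == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, depth = as.integer(level), mode = mode,
            signal_length = length(x),
            class = c("eser_table", "data.frame"))
}

#' Select the mother wavelet from an ESER table
#'
#' `max-any-level` (the default) returns the wavelet attaining the single
#' highest ratio at any detail level; `sum-over-levels` ranks wavelets by
#' the sum of their per-level ratios. Degenerate bands are excluded. Ties
#' break lexicographically by wavelet name.
#'
#' @param table An `eser_table` from [eser_scan()].
#' @param policy `"max-any-level"` or `"sum-over-levels"`.
#' @return List of class `wavelet_selection` with `wavelet` (the winner),
#'   `policy`, `score`, and `ranking` (a data frame of all candidates in
#'   decreasing score order).
#' @export
select_wavelet <- function(table, policy = c("max-any-level",
                                             "sum-over-levels")) {
  stopifnot(inherits(table, "eser_table") || is.data.frame(table))
  policy <- match.arg(policy)
  usable <- table[!is.na(table$eser) & !table$degenerate, , drop = FALSE]
  if (nrow(usable) == 0L) {
    stop("all bands are degenerate; no wavelet can be selected",
         call. = FALSE)
  }
  score <- if (policy == "max-any-level") {
    tapply(usable$eser, usable$wavelet, max)
  } else {
    tapply(usable$eser, usable$wavelet, sum)
  }
  ranking <- data.frame(wavelet = names(score), score = as.numeric(score),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$score, ranking$wavelet), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(wavelet = ranking$wavelet[1L], policy = policy,
                 score = ranking$score[1L], ranking = ranking),
            class = "wavelet_selection")
}

#' @export
print.wavelet_selection <- function(x, ...) {
  cat("Selected wavelet: '", x$wavelet, "' (policy ", x$policy,
      ", score ", format(x$score), ")\n", sep = "")
  top <- utils::head(x$ranking, 5L)
  cat("Top candidates:\n")
  print(top)
  invisible(x)
}

#' Write an ESER table as long-format delimited text
#'
#' @param table An `eser_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eser_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
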