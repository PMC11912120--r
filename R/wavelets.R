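# Wavelet filter catalogue.
#
# Filter banks are stored as plain-text tables under inst/extdata: the
# analysis low-pass filter (dec_lo) for orthogonal families, and the
# dec_lo/rec_lo pair for biorthogonal ones. Everything else is derived:
#   * orthogonal rec_lo is the reversal of dec_lo,
#   * reverse-biorthogonal (rbio) wavelets swap dec_lo and rec_lo,
#   * high-pass filters follow the alternating-sign quadrature-mirror
#     relations dec_hi[k] = (-1)^(k+1) rec_lo[k], rec_hi[k] = (-1)^k dec_lo[k]
#     (0-based k).
# All filters in the catalogue have even length, which the transform code
# relies on for its alignment offsets.

.wavelet_cache <- new.env(parent = emptyenv())

.load_catalogue <- function() {
  if (!is.null(.wavelet_cache$catalogue)) {
    return(.wavelet_cache$catalogue)
  }
  cat_env <- new.env(parent = emptyenv())

  read_lines <- function(file) {
    path <- system.file("extdata", file, package = "ebwdenoise", mustWork = TRUE)
    ln <- readLines(path)
    ln[!startsWith(ln, "#") & nzchar(ln)]
  }

  for (file in c("filters_daubechies.txt", "filters_orthogonal.txt")) {
    for (ln in read_lines(file)) {
      parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
      name <- parts[[1]]
      dec_lo <- as.numeric(parts[-1])
      assign(name, list(dec_lo = dec_lo, rec_lo = rev(dec_lo),
                        orthogonal = TRUE), envir = cat_env)
    }
  }

  bior <- list()
  for (ln in read_lines("filters_biorthogonal.txt")) {
    parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
    name <- parts[[1]]
    side <- parts[[2]]
    bior[[name]][[side]] <- as.numeric(parts[-(1:2)])
  }
  for (name in names(bior)) {
    dec_lo <- bior[[name]]$dec
    rec_lo <- bior[[name]]$rec
    assign(name, list(dec_lo = dec_lo, rec_lo = rec_lo, orthogonal = FALSE),
           envir = cat_env)
    rname <- sub("^bior", "rbio", name)
    assign(rname, list(dec_lo = rec_lo, rec_lo = dec_lo, orthogonal = FALSE),
           envir = cat_env)
  }

  .wavelet_cache$catalogue <- cat_env
  cat_env
}

#' List the wavelet catalogue
#'
#' Names of all discrete wavelets available for decomposition: Haar,
#' Daubechies (db1--db38), Symlets (sym2--sym20), Coiflets (coif1--coif17),
#' and the biorthogonal and reverse-biorthogonal spline families (15 each)
#' -- 105 filter banks in total. Every catalogue entry satisfies perfect
#' reconstruction to better than 1e-8 relative error.
#'
#' @return Character vector of wavelet names, sorted.
#' @examples
#' length(wavelet_catalogue())
#' "rbio5.5" %in% wavelet_catalogue()
#' @export
wavelet_catalogue <- function() {
  sort(ls(.load_catalogue()))
}

#' Retrieve a wavelet filter bank
#'
#' @param name Catalogue identifier, e.g. `"db4"` or `"rbio5.5"`.
#' @return A list of class `wavelet_filters` with components `name`,
#'   `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` (numeric filters of equal, even
#'   length) and logical `orthogonal`.
#' @examples
#' f <- wavelet_filters("db2")
#' sum(f$dec_lo)  # ~ sqrt(2)
#' @export
wavelet_filters <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  cat_env <- .load_catalogue()
  if (!exists(name, envir = cat_env, inherits = FALSE)) {
    stop("unknown wavelet '", name, "'; see wavelet_catalogue()", call. = FALSE)
  }
  w <- get(name, envir = cat_env, inherits = FALSE)
  n <- length(w$dec_lo)
  k <- seq_len(n) - 1L
  structure(list(
    name = name,
    dec_lo = w$dec_lo,
    dec_hi = (-1)^(k + 1) * w$rec_lo,
    rec_lo = w$rec_lo,
    rec_hi = (-1)^k * w$dec_lo,
    orthogonal = w$orthogonal
  ), class = "wavelet_filters")
}

#' @export
print.wavelet_filters <- function(x, ...) {
  cat("Wavelet '", x$name, "': ", length(x$dec_lo), "-tap ",
      if (x$orthogonal) "orthogonal" else "biorthogonal",
      " filter bank\n", sep = "")
  invisible(x)
}
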