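# Shared fixtures: all built in code at test time.

# A fixed 16-sample vector used for the frozen transform-oracle tests.
fixture16 <- function() {
  c(1, 3, -2, 4, 0.5, -1, 2, 7, -3.5, 0, 1.5, -4, 2.5, 6, -0.5, 1)
}

# Seeded Gaussian vector without disturbing the caller's RNG.
seeded_normal <- function(n, seed, sd = 1) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rnorm(n, sd = sd)
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# Brute-force morphological opening with edge replication: O(n * w) sliding
# min then max, the independent oracle for the van Herk implementation.
brute_opening <- function(x, w) {
  n <- length(x)
  r <- (w - 1L) %/% 2L
  at <- function(v, i) v[pmin(pmax(i, 1L), n)]
  eroded <- vapply(seq_len(n), function(i) min(at(x, (i - r):(i + r))),
                   numeric(1))
  vapply(seq_len(n), function(i) max(at(eroded, (i - r):(i + r))),
         numeric(1))
}
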