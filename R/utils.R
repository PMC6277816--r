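# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize rows of a matrix of 3-vectors
#' @param v numeric matrix (n x 3)
#' @return matrix with unit rows; zero rows left as zero
#' @keywords internal
normalize_rows <- function(v) {
  n <- sqrt(rowSums(v^2))
  nz <- n > 0
  v[nz, ] <- v[nz, , drop = FALSE] / n[nz]
  v
}

vec_norm <- function(x) sqrt(sum(x^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Cross products of rows of two n x 3 matrices.
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Deterministic integer seed derived from a master seed and a stage label,
# kept below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
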