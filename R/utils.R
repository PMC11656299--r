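# Internal helpers: seed streams, local RNG scoping, separable filtering.

# Derive a child seed deterministically from (seed, key); keeps results
# reproducible from a single integer while decorrelating pipeline stages.
.childSeed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(as.character(key)))
    h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

.gaussKernel1d <- function(sigma, radius = as.integer(sigma * 3.5 + 0.5)) {
  x <- (-radius):radius
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

# Reflect-padding that duplicates the edge sample (scipy.ndimage "reflect"):
# indices ... 2 1 | 1 2 ... n | n n-1 ...
.reflectIdx <- function(n, r) {
  c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
}

# Separable 2-D correlation with reflect padding; kernel is 1-D, symmetric.
.sepFilter2 <- function(img, kernel) {
  r <- (length(kernel) - 1L) / 2L
  p <- img[.reflectIdx(nrow(img), r), .reflectIdx(ncol(img), r), drop = FALSE]
  # filter rows (dimension 1)
  out <- matrix(0, nrow(img), ncol(p))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * p[k:(k + nrow(img) - 1L), , drop = FALSE]
  # filter cols (dimension 2)
  res <- matrix(0, nrow(img), ncol(img))
  for (k in seq_along(kernel))
    res <- res + kernel[k] * out[, k:(k + ncol(img) - 1L), drop = FALSE]
  res
}

# Separable 2-D "valid" correlation (no padding); output shrinks by the
# kernel radius on every side.
.sepFilter2Valid <- function(img, kernel) {
  kl <- length(kernel)
  nr <- nrow(img) - kl + 1L
  nc <- ncol(img) - kl + 1L
  stopifnot(nr >= 1L, nc >= 1L)
  out <- matrix(0, nr, ncol(img))
  for (k in seq_len(kl))
    out <- out + kernel[k] * img[k:(k + nr - 1L), , drop = FALSE]
  res <- matrix(0, nr, nc)
  for (k in seq_len(kl))
    res <- res + kernel[k] * out[, k:(k + nc - 1L), drop = FALSE]
  res
}

.assertCongruent <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical dimensions", what), call. = FALSE)
}

.asSlices <- function(x) {
  # Accept a matrix (single slice) or 3-D array; return list of matrices.
  if (is.matrix(x)) return(list(x))
  d <- dim(x)
  lapply(seq_len(d[3]), function(k) x[, , k])
}
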