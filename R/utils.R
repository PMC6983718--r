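#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: each named stream gets its own seed from
# the master seed so that perturbing one simulation component leaves the
# others' random draws untouched. Plain 32-bit-safe integer hashing.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483629 + 1)
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# MD5 checksum of an arbitrary R object via deterministic serialization.
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Separable Gaussian blur with edge-replicating ("nearest") border handling.
# sigma is in matrix cells; sigma = 0 returns the input unchanged.
gaussian_blur <- function(mat, sigma) {
  stopifnot(is.matrix(mat), sigma >= 0)
  if (sigma == 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), -r:r, "+")
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + m[idx[, j], , drop = FALSE] * k[j]
    out
  }
  t(blur1(t(blur1(mat))))
}

# Bilinear interpolation of matrix `m` (rows = y, cols = x) at continuous
# 0-based pixel-center coordinates. Points outside the grid are clamped.
bilinear_sample <- function(m, x, y) {
  ny <- nrow(m); nx <- ncol(m)
  x <- pmin(pmax(x, 0), nx - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), ny - 2); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}
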