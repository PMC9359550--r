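# Internal numerical helpers: deterministic seed derivation, bilinear
# interpolation on regular grids, Gauss-Hermite nodes.

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own stream from one
#' master seed, so that e.g. pass-repeated sessions can share a stimulus
#' stream while the observer's sensory noise stays fresh per pass.
#'
#' @param seed master seed (integer-valued).
#' @param ... integer or character stream labels; characters are hashed.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    for (ki in k) {
      h <- (h * 48271 + as.numeric(ki) + 1) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate expr with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Vectorised bilinear interpolation of matrix z (rows ~ xg, cols ~ yg) at
# query points (x, y).  Queries outside the grid are clamped to the edge;
# callers choose grids wide enough that clamping only affects extreme
# outliers.
bilinear <- function(xg, yg, z, x, y) {
  nx <- length(xg); ny <- length(yg)
  ix <- findInterval(x, xg, rightmost.closed = TRUE)
  iy <- findInterval(y, yg, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), nx - 1L)
  iy <- pmin(pmax(iy, 1L), ny - 1L)
  x0 <- xg[ix]; x1 <- xg[ix + 1L]
  y0 <- yg[iy]; y1 <- yg[iy + 1L]
  tx <- pmin(pmax((x - x0) / (x1 - x0), 0), 1)
  ty <- pmin(pmax((y - y0) / (y1 - y0), 0), 1)
  z00 <- z[cbind(ix, iy)]
  z10 <- z[cbind(ix + 1L, iy)]
  z01 <- z[cbind(ix, iy + 1L)]
  z11 <- z[cbind(ix + 1L, iy + 1L)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}

# Gauss-Hermite nodes/weights (Golub-Welsch via symmetric tridiagonal
# eigendecomposition), for integrals of g(y) against a N(mu, sigma^2)
# density: sum(w * g(mu + sqrt(2) * sigma * x)) with weights normalised
# to 1.
gauss_hermite <- function(n) {
  if (n == 1L) return(list(x = 0, w = 1))
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1L)] <- b
  A[cbind(i + 1L, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1L, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord] / sum(w))
}

# Trapezoid integration on a (possibly irregular) grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

clip01 <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a
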