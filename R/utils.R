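# Internal numerics shared across modules.

# Half-up decimal rounding (display only; internal values keep full precision).
roundHalfUp <- function(x, digits = 0L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

# Truncate towards zero at a fixed number of decimals (display only).
truncDecimals <- function(x, digits = 0L) {
  s <- 10^digits
  trunc(x * s) / s
}

# Running (truncated-at-edges) window sum along the first dimension of a
# matrix. Works for double and complex input.
.runSumFirst <- function(m, k) {
  n <- nrow(m)
  if (k <= 1L || n == 1L) return(m)
  h <- (k - 1L) %/% 2L
  cs <- m
  for (i in 2:n) cs[i, ] <- cs[i - 1L, ] + m[i, ]
  out <- m
  for (i in 1:n) {
    hi <- min(i + h, n)
    lo <- i - h
    out[i, ] <- if (lo > 1L) cs[hi, ] - cs[lo - 1L, ] else cs[hi, ]
  }
  out
}

# Box (moving-window) sum of a 3-d array with odd window sizes k = (kz, kx, ky).
# Windows are truncated at the array boundary, no padding values are invented.
boxSum3d <- function(a, k) {
  d <- dim(a)
  stopifnot(length(d) == 3L, length(k) == 3L, all(k >= 1L))
  for (ax in 1:3) {
    kk <- as.integer(k[ax])
    if (kk <= 1L) next
    perm <- c(ax, setdiff(1:3, ax))
    p <- aperm(a, perm)
    dp <- dim(p)
    m <- .runSumFirst(matrix(p, nrow = dp[1L]), kk)
    dim(m) <- dp
    a <- aperm(m, order(perm))
  }
  a
}

# Normalized 1-d Gaussian kernel truncated at 3 sigma.
.gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

# Convolve along the first dimension with boundary renormalization (the
# kernel mass falling outside the array is redistributed, so a constant
# field stays constant up to machine precision).
.convFirst <- function(m, g) {
  n <- nrow(m)
  r <- (length(g) - 1L) %/% 2L
  out <- matrix(0, n, ncol(m))
  wt <- numeric(n)
  idx <- seq_len(n)
  for (t in seq_along(g)) {
    off <- t - r - 1L
    src <- idx + off
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    out[idx[ok], ] <- out[idx[ok], ] + g[t] * m[src[ok], ]
    wt[idx[ok]] <- wt[idx[ok]] + g[t]
  }
  out / wt
}

#' Separable 3-d Gaussian filter
#'
#' Smooths a 3-d array with an isotropic Gaussian kernel (standard
#' deviation in pixels, truncated at three sigma) applied separably along
#' each axis. Boundaries use renormalized (truncated-kernel) weights so
#' that constant regions are preserved exactly.
#'
#' @param a numeric 3-d array.
#' @param sigma kernel standard deviation in pixels (applied to all axes).
#' @return array of the same dimension as `a`.
#' @export
gaussianFilter3d <- function(a, sigma = 1.1) {
  d <- dim(a)
  stopifnot(length(d) == 3L, sigma > 0)
  g <- .gaussKernel1d(sigma)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    perm <- c(ax, setdiff(1:3, ax))
    p <- aperm(a, perm)
    dp <- dim(p)
    m <- .convFirst(matrix(p, nrow = dp[1L]), g)
    dim(m) <- dp
    a <- aperm(m, order(perm))
  }
  a
}

# Structured error for invalid acquisition geometry arguments.
.geometryError <- function(msg) {
  stop(structure(
    class = c("jmoctGeometryError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
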