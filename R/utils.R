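#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a reproducible per-stage seed from one user seed.
## Kept strictly below 2^31 - 1 so set.seed() always accepts it.
derive_seed <- function(seed, stage) {
  (as.double(seed) * 131 + stage) %% 2147483647
}

## Map an out-of-range 1-based index into [1, n] by mirror (symmetric)
## reflection: ... a2 a1 | a1 a2 ... an | an an-1 ...
reflect_index <- function(j, n) {
  while (any(bad <- (j < 1L | j > n))) {
    j[bad & j < 1L] <- 1L - j[bad & j < 1L]
    j[bad & j > n]  <- 2L * n + 1L - j[bad & j > n]
  }
  j
}

## Banded convolution matrix for one axis: M[i, j] accumulates the kernel
## weight with which input sample j contributes to output sample i.
conv_matrix <- function(n, kernel, pad = c("zero", "reflect")) {
  pad <- match.arg(pad)
  h <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (o in -h:h) {
    w <- kernel[o + h + 1L]
    j <- seq_len(n) + o
    if (pad == "reflect") {
      jj <- reflect_index(j, n)
      for (i in seq_len(n)) M[i, jj[i]] <- M[i, jj[i]] + w
    } else {
      ok <- j >= 1L & j <= n
      idx <- which(ok)
      M[cbind(idx, j[ok])] <- M[cbind(idx, j[ok])] + w
    }
  }
  M
}

## Separable convolution of a 3-D array along one axis via the banded matrix.
conv_axis3 <- function(a, kernel, axis, pad = "zero") {
  d <- dim(a)
  if (length(kernel) == 1L) return(a * kernel)
  M <- conv_matrix(d[axis], kernel, pad)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  out <- M %*% matrix(ap, nrow = dp[1])
  dim(out) <- dp
  aperm(out, order(perm))
}

## Uniform (box) mean filter, side 2*radius+1 per axis, reflect padding.
box_filter3 <- function(a, radius) {
  if (radius == 0L) return(a)
  k <- rep(1 / (2 * radius + 1), 2 * radius + 1)
  for (ax in 1:3) a <- conv_axis3(a, k, ax, pad = "reflect")
  a
}

gaussian_kernel1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  h <- max(1L, as.integer(ceiling(3.5 * sigma_vox)))
  k <- stats::dnorm(-h:h, sd = sigma_vox)
  k / sum(k)
}

## Gaussian PSF blur, zero padding (photons leaving the volume are lost).
gaussian_filter3 <- function(a, sigma_vox) {
  for (ax in 1:3) {
    k <- gaussian_kernel1d(sigma_vox[ax])
    if (length(k) > 1L) a <- conv_axis3(a, k, ax, pad = "zero")
  }
  a
}
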