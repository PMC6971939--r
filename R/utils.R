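# Orthonormal 2D DFT pair used project-wide: forward and inverse both carry
# 1/sqrt(N) so Parseval holds exactly and the adjoint equals the inverse.
fft2_ortho <- function(x) stats::fft(x) / sqrt(length(x))

ifft2_ortho <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# Map a zero-centered integer k-coordinate in [-n/2, n/2 - 1] to the
# natural 1-based DFT index of an n-point transform.
k_index <- function(k, n) ((k + n) %% n) + 1L

# Voxel-center physical coordinate (mm), zero-centered grid.
grid_coord <- function(i, n, voxel) (i - (n + 1) / 2) * voxel

# Run code with a temporary RNG state seeded by `seed` (NULL = leave the
# global stream alone).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Vectorized trilinear interpolation of a 3D array at continuous 1-based
# voxel coordinates (N x 3 matrix). Points outside the grid return NA.
interp3_trilinear <- function(arr, pts) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  g <- function(i, j, k) arr[cbind(i, j, k)]
  v <- g(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    g(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    g(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    g(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    g(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    g(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    g(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[ok] <- v
  out
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels, replicate
# padding). Used for surface-normal estimation from binary masks.
smooth3_gauss <- function(arr, sigma = 1.2) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv_dim <- function(a, dim_idx) {
    d <- dim(a)
    perm <- c(dim_idx, setdiff(1:3, dim_idx))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[dim_idx])
    n <- nrow(m)
    idx_pad <- c(rep(1L, r), seq_len(n), rep(n, r))
    mp <- m[idx_pad, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    }
    res <- array(out, dim(ap))
    aperm(res, order(perm))
  }
  for (dd in 1:3) arr <- conv_dim(arr, dd)
  arr
}
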