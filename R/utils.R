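# Internal numeric helpers shared across modules.

# Centered lateral coordinate vector in mm for n samples at spacing d (mm).
lateral_axis <- function(n, d) (seq_len(n) - (n + 1) / 2) * d

# Moving-average smoothing along rows of a matrix (across columns), width w
# (odd). Used to tame speckle before gradient computation.
boxcar_cols <- function(m, w) {
  if (w <= 1L) return(m)
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  nc <- ncol(m)
  cs <- cbind(0, t(apply(m, 1L, cumsum)))
  lo <- pmax(seq_len(nc) - h - 1L, 0L)
  hi <- pmin(seq_len(nc) + h, nc)
  out <- (cs[, hi + 1L, drop = FALSE] - cs[, lo + 1L, drop = FALSE])
  sweep(out, 2L, hi - lo, "/")
}

# 1D Gaussian kernel with sd `sigma` in sample units, truncated at 3 sigma.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Convolve each column of a matrix with kernel k (reflected edges).
conv_cols_k <- function(m, k) {
  if (length(k) == 1L) return(m * k)
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  idx <- seq_len(n)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    ii <- idx + (j - r - 1L)
    ii <- ifelse(ii < 1L, 2L - ii, ii)
    ii <- ifelse(ii > n, 2L * n - ii, ii)
    ii <- pmin(pmax(ii, 1L), n)   # kernels wider than the matrix
    out <- out + k[j] * m[ii, , drop = FALSE]
  }
  out
}

# NA-aware separable Gaussian smoothing of a matrix; sigmas in sample units.
# Normalized convolution: missing cells get the kernel-weighted mean of their
# valid neighbours; cells with no valid neighbour stay NA.
smooth_gauss_na <- function(m, sigma_r, sigma_c) {
  valid <- is.finite(m)
  m0 <- ifelse(valid, m, 0)
  w <- matrix(as.numeric(valid), nrow(m), ncol(m))
  kr <- gauss_kernel(sigma_r)
  kc <- gauss_kernel(sigma_c)
  num <- t(conv_cols_k(t(conv_cols_k(m0, kr)), kc))
  den <- t(conv_cols_k(t(conv_cols_k(w, kr)), kc))
  out <- num / den
  out[den < 1e-12] <- NA_real_
  out
}

# 3x3 median filter ignoring NA; border cells use the available neighbourhood.
median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2L || nc < 2L) return(m)
  stack <- array(NA_real_, c(nr, nc, 9L))
  s <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    s <- s + 1L
    rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    stack[, , s] <- m[rs, cs]
  }
  apply(stack, c(1L, 2L), function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  })
}

# Bilinear interpolation of matrix `m` at fractional (row, col) index
# coordinates; NA outside the grid or when any corner is NA.
bilinear_idx <- function(m, ri, ci) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(ri))
  ok <- is.finite(ri) & is.finite(ci) & ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  if (!any(ok)) return(out)
  r0 <- pmin(floor(ri[ok]), nr - 1L); c0 <- pmin(floor(ci[ok]), nc - 1L)
  fr <- ri[ok] - r0; fc <- ci[ok] - c0
  v00 <- m[cbind(r0, c0)]
  v10 <- m[cbind(r0 + 1L, c0)]
  v01 <- m[cbind(r0, c0 + 1L)]
  v11 <- m[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
  out
}

# Parabolic vertex offset from three samples around a discrete extremum.
# Returns a value in [-0.5, 0.5]; 0 when the fit is degenerate.
parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || abs(den) < 1e-300) return(0)
  d <- 0.5 * (ym1 - yp1) / den
  max(-0.5, min(0.5, d))
}

# Deterministic per-eye seed derived from a base seed (kept below 2^31).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629)
}
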