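#' @keywords internal
"_PACKAGE"

#' Round half away from zero (table-style rounding)
#'
#' `base::round()` rounds half to even, which disagrees with printed
#' report tables on exact .5 ties; report formatting uses this instead.
#' Applied only at display time, never inside computations.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 2-D linear (zero-padded) convolution of `mat` with `kern` via FFT.
# Returns a matrix the size of `mat`; kern must have odd dimensions and is
# centred. Used for threat kernels and neighbourhood shares; exact to
# floating-point roundoff (~1e-12 relative), verified against direct loops.
conv2_fft <- function(mat, kern) {
  stopifnot(nrow(kern) %% 2 == 1, ncol(kern) %% 2 == 1)
  nr <- nrow(mat); nc <- ncol(mat)
  kr <- nrow(kern); kc <- ncol(kern)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  A <- matrix(0, pr, pc); A[seq_len(nr), seq_len(nc)] <- mat
  K <- matrix(0, pr, pc); K[seq_len(kr), seq_len(kc)] <- kern
  out <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  r0 <- (kr - 1L) / 2L; c0 <- (kc - 1L) / 2L
  out[r0 + seq_len(nr), c0 + seq_len(nc)]
}

# Periodic Gaussian smoothing of white noise -> spatially autocorrelated
# field, standardised to zero mean / unit sd.
smooth_field <- function(nr, nc, range_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells <= 0) return(scale_field(z))
  # separable Gaussian taps truncated at 3 sigma
  h <- ceiling(3 * range_cells)
  g <- stats::dnorm(-h:h, sd = range_cells)
  g <- g / sum(g)
  kern <- outer(g, g)
  # reflect-pad so edges are not dimmed
  zp <- pad_reflect(z, h)
  s <- conv2_fft(zp, kern)[h + seq_len(nr), h + seq_len(nc)]
  scale_field(s)
}

scale_field <- function(m) {
  v <- as.vector(m)
  (m - mean(v)) / stats::sd(v)
}

pad_reflect <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(h, nr))), seq_len(nr), nr + 1 - seq_len(min(h, nr)))
  ci <- c(rev(seq_len(min(h, nc))), seq_len(nc), nc + 1 - seq_len(min(h, nc)))
  # if h exceeds dim, recycle reflections (rare; tiny grids in tests)
  while (length(ri) < nr + 2 * h) ri <- c(ri[1], ri, ri[length(ri)])
  while (length(ci) < nc + 2 * h) ci <- c(ci[1], ci, ci[length(ci)])
  m[ri, ci, drop = FALSE]
}
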