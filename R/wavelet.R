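## Maximal overlap discrete wavelet transform (MODWT) with the
## least-asymmetric 8-tap (la8 / sym8-tap Daubechies) filter, and
## universal hard-threshold denoising. The MODWT is shift-invariant and
## defined for any signal length; boundaries are handled by reflection.

# la8 scaling filter (least-asymmetric Daubechies, L = 8)
LA8_SCALING <- c(-0.075765714789273330, -0.029635527645998510,
                  0.497618667632015450,  0.803738751805916140,
                  0.297857795605277360, -0.099219543576847220,
                 -0.012603967262037833,  0.032223100604042702)

# quadrature-mirror wavelet filter: h_l = (-1)^l g_{L-1-l}
la8_filters <- function() {
  g <- LA8_SCALING
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * rev(g)
  # MODWT rescaling by 1/sqrt(2) per level
  list(g = g / sqrt(2), h = h / sqrt(2))
}

circ_filter <- function(v, f, step) {
  # y[t] = sum_l f[l+1] * v[(t - step*l) mod N], t = 1..N (0-based mod)
  N <- length(v)
  y <- numeric(N)
  t0 <- 0:(N - 1)
  for (l in seq_along(f) - 1L) {
    idx <- ((t0 - step * l) %% N) + 1L
    y <- y + f[l + 1L] * v[idx]
  }
  y
}

circ_filter_inv <- function(w, f, step) {
  # y[t] = sum_l f[l+1] * w[(t + step*l) mod N]
  N <- length(w)
  y <- numeric(N)
  t0 <- 0:(N - 1)
  for (l in seq_along(f) - 1L) {
    idx <- ((t0 + step * l) %% N) + 1L
    y <- y + f[l + 1L] * w[idx]
  }
  y
}

#' Maximal overlap discrete wavelet transform
#'
#' Circular MODWT pyramid with the la8 filter. Output coefficients have
#' the same length as the input at every level (shift-invariant).
#'
#' @param x Numeric signal.
#' @param levels Decomposition depth J.
#' @return List with `W` (list of detail coefficient vectors, levels
#'   1..J) and `V` (final smooth coefficients).
#' @export
modwt_la8 <- function(x, levels) {
  flt <- la8_filters()
  W <- vector("list", levels)
  V <- x
  for (j in seq_len(levels)) {
    step <- 2L^(j - 1L)
    W[[j]] <- circ_filter(V, flt$h, step)
    V <- circ_filter(V, flt$g, step)
  }
  list(W = W, V = V)
}

#' Inverse maximal overlap discrete wavelet transform
#'
#' @param wt A decomposition from [modwt_la8()].
#' @return The reconstructed signal.
#' @export
imodwt_la8 <- function(wt) {
  flt <- la8_filters()
  V <- wt$V
  for (j in rev(seq_along(wt$W))) {
    step <- 2L^(j - 1L)
    V <- circ_filter_inv(wt$W[[j]], flt$h, step) +
      circ_filter_inv(V, flt$g, step)
  }
  V
}

#' Wavelet denoising by MODWT hard thresholding
#'
#' Reflection-extends the signal, takes the la8 MODWT to
#' `min(levels, floor(log2(n)))` levels, hard-thresholds every detail
#' level at the universal threshold `sigma * sqrt(2 log n)` with
#' `sigma = MAD(finest detail) / 0.6745`, reconstructs, and returns the
#' original-length signal.
#'
#' @param x Numeric signal, length >= 16.
#' @param levels Maximum decomposition depth (default 4).
#' @return Denoised signal, same length as `x`.
#' @export
modwt_denoise <- function(x, levels = 4L) {
  n <- length(x)
  if (n < 16L) stop("signal too short for wavelet denoising (need >= 16)")
  J <- min(levels, floor(log2(n)))
  xr <- c(x, rev(x))                       # reflection boundary
  wt <- modwt_la8(xr, J)
  sigma <- stats::mad(wt$W[[1L]], center = 0, constant = 1) / 0.6745
  lambda <- sigma * sqrt(2 * log(length(xr)))
  wt$W <- lapply(wt$W, function(w) ifelse(abs(w) > lambda, w, 0))
  y <- imodwt_la8(wt)
  y[seq_len(n)]
}
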