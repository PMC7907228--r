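#' Centered DFT frequency indices
#'
#' Integer frequency index for each position of an unshifted DFT axis of
#' length `n`: `0, 1, ..., floor((n-1)/2), -ceiling((n-1)/2), ..., -1`.
#' Summing over these indices is equivalent to summing over the
#' zero-frequency-centered spectrum, without shifting the matrix.
#'
#' @param n axis length.
#' @return Integer vector of length `n`.
#' @keywords internal
freq_index <- function(n) {
  half <- floor((n - 1) / 2)
  c(0:half, seq.int(half - n + 1, -1))
}

#' Gaussian blur with replicate borders
#'
#' Separable Gaussian convolution, truncated at `truncate` standard
#' deviations, with out-of-image samples replicated from the nearest edge
#' pixel (consistent with the replicate padding used for the Laplacian
#' stencil). `sigma = 0` returns the input unchanged.
#'
#' @param slice numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @param truncate kernel half-width in sigmas (default 4).
#' @return Blurred matrix of the same shape.
#' @export
blur_gaussian <- function(slice, sigma, truncate = 4) {
  stopifnot(is.matrix(slice), sigma >= 0)
  if (sigma == 0) return(slice)
  h <- max(1L, ceiling(truncate * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_mat <- function(n) {
    # row u of the operator holds the kernel centered at u, edges replicated
    A <- matrix(0, n, n)
    for (u in seq_len(n)) {
      pos <- pmin(pmax(u + seq(-h, h), 1L), n)
      for (t in seq_along(pos)) A[u, pos[t]] <- A[u, pos[t]] + k[t]
    }
    A
  }
  conv_mat(nrow(slice)) %*% slice %*% t(conv_mat(ncol(slice)))
}

# population variance (1/n denominator), NA if empty
pop_var <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

# histogram counts of values in [0,1] over `bins` equal bins; top edge closed
hist_counts01 <- function(x, bins) {
  idx <- pmin(floor(x * bins) + 1L, bins)
  tabulate(idx, nbins = bins)
}

as_mask <- function(mask, slice) {
  if (is.null(mask)) mask <- full_mask(slice)
  stopifnot(is.logical(mask), identical(dim(mask), dim(slice)))
  mask
}
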