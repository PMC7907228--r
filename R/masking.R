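#' Stack-maximum intensity normalization
#'
#' Fluorescence intensity depends on staining and acquisition settings, so
#' before any metric is evaluated every pixel of the stack is divided by the
#' maximum intensity of the whole 3-D stack. Per-slice intensity ratios are
#' preserved and the global maximum maps to exactly 1.
#'
#' @param stack a [zstack].
#' @return A float-valued [zstack] with intensities in \[0, 1\].
#' @export
normalize_stack <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  gmax <- max(vapply(stack$slices, max, numeric(1)))
  if (!is.finite(gmax) || gmax <= 0) {
    stop("all-zero stack: normalization undefined", call. = FALSE)
  }
  out <- stack
  out$slices <- lapply(stack$slices, function(s) s / gmax)
  out$bit_depth <- NA_integer_
  out
}

#' Otsu foreground threshold and mask
#'
#' The spheroid is very well separated from the dark background in the slice
#' histogram, so the foreground mask is obtained by Otsu's method: the
#' threshold maximizing the between-class variance
#' \eqn{\omega_0\omega_1(\mu_0-\mu_1)^2} over all histogram cut points.
#' The histogram uses `bins` equal-width bins on \[0, 1\] (the slice must be
#' stack-normalized first); the threshold returned is the upper edge of the
#' last background bin, and the mask keeps pixels strictly above it.
#'
#' A constant slice has a degenerate one-bin histogram: the mask comes back
#' empty with `degenerate = TRUE`, and downstream metrics propagate `NA`
#' rather than a silent zero.
#'
#' @param slice numeric matrix with values in \[0, 1\].
#' @param bins histogram bin count (default 256, the 8-bit convention).
#' @return For `otsu_threshold`, the scalar threshold (`NA` if degenerate).
#'   For `otsu_mask`, a logical matrix with attributes `kind`, `threshold`,
#'   `pixel_count` and `degenerate`.
#' @export
otsu_threshold <- function(slice, bins = 256L) {
  stopifnot(is.matrix(slice))
  if (any(slice < 0 | slice > 1, na.rm = TRUE)) {
    stop("Otsu expects a normalized slice in [0, 1]", call. = FALSE)
  }
  # bin i covers [(i-1)/bins, i/bins); top edge closed
  idx <- pmin(floor(slice * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  if (sum(counts > 0L) < 2L) return(NA_real_)
  n <- sum(counts)
  centers <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(counts) / n              # background weight for cut after bin k
  m0 <- cumsum(counts * centers) / n    # unnormalized background mean
  mt <- m0[bins]
  k <- seq_len(bins - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  bcv <- rep(-Inf, bins - 1L)
  bcv[valid] <- (mt * w0[k][valid] - m0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  kstar <- which.max(bcv)               # first maximizer on ties
  kstar / bins                          # upper edge of last background bin
}

#' @rdname otsu_threshold
#' @export
otsu_mask <- function(slice, bins = 256L) {
  thr <- otsu_threshold(slice, bins = bins)
  if (is.na(thr)) {
    m <- matrix(FALSE, nrow(slice), ncol(slice))
    return(structure(m, kind = "otsu_foreground", threshold = NA_real_,
                     pixel_count = 0L, degenerate = TRUE))
  }
  m <- slice > thr
  structure(m, kind = "otsu_foreground", threshold = thr,
            pixel_count = sum(m), degenerate = FALSE)
}

#' Full-slice mask
#' @param slice numeric matrix the mask should match in shape.
#' @return Logical matrix of `TRUE` with mask attributes.
#' @export
full_mask <- function(slice) {
  m <- matrix(TRUE, nrow(slice), ncol(slice))
  structure(m, kind = "full", threshold = NA_real_,
            pixel_count = length(m), degenerate = FALSE)
}

#' Intensity-weighted centroid from image moments
#'
#' The spheroid's center of mass in a slice is located from the raw image
#' moments \eqn{M_{pq} = \sum_x \sum_y x^p y^q I(x,y)} computed over the
#' masked pixels (background excluded), with x the 0-based column index and
#' y the 0-based row index: `centerx = M10/M00`, `centery = M01/M00`.
#'
#' @param slice numeric intensity matrix.
#' @param mask logical matrix restricting the moments; defaults to the
#'   whole slice.
#' @return A list with `centerx`, `centery`, `m00`, `m10`, `m01` and
#'   `degenerate` (`TRUE` when the masked intensity sum is zero, in which
#'   case the center is `NA`).
#' @export
centroid <- function(slice, mask = NULL) {
  stopifnot(is.matrix(slice))
  if (is.null(mask)) mask <- full_mask(slice)
  stopifnot(identical(dim(mask), dim(slice)))
  w <- slice * mask
  m00 <- sum(w)
  if (!is.finite(m00) || m00 <= 0) {
    return(list(centerx = NA_real_, centery = NA_real_,
                m00 = m00, m10 = NA_real_, m01 = NA_real_, degenerate = TRUE))
  }
  xs <- matrix(rep(seq_len(ncol(slice)) - 1, each = nrow(slice)), nrow(slice))
  ys <- matrix(rep(seq_len(nrow(slice)) - 1, ncol(slice)), nrow(slice))
  m10 <- sum(xs * w)
  m01 <- sum(ys * w)
  list(centerx = m10 / m00, centery = m01 / m00,
       m00 = m00, m10 = m10, m01 = m01, degenerate = FALSE)
}

#' Internal-circle mask
#'
#' Certain clearing agents sharpen the rim of a spheroid while its core stays
#' blurred; restricting pixel-statistics metrics to a fixed-radius circle
#' around the slice centroid scores the interior only. Membership is strict:
#' a pixel (row i, col j, 0-based) is inside iff
#' \eqn{(j-\mathrm{center}_x)^2 + (i-\mathrm{center}_y)^2 < r^2}.
#' The circle may be clipped at the image border.
#'
#' @param shape integer vector `c(M, N)` (rows, cols) or a matrix to take the
#'   shape from.
#' @param center a centroid list from [centroid()] or `c(centerx, centery)`.
#' @param r radius in pixels (> 0); the reference analysis used r = 200 px.
#' @return Logical matrix with mask attributes.
#' @export
internal_circle_mask <- function(shape, center, r) {
  if (is.matrix(shape)) shape <- dim(shape)
  stopifnot(length(shape) == 2L, r > 0)
  if (is.list(center)) center <- c(center$centerx, center$centery)
  if (any(is.na(center))) {
    m <- matrix(FALSE, shape[1], shape[2])
    return(structure(m, kind = "internal_circle", threshold = NA_real_,
                     pixel_count = 0L, degenerate = TRUE, radius = r))
  }
  i <- matrix(rep(seq_len(shape[1]) - 1, shape[2]), shape[1])
  j <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1])
  m <- (j - center[1])^2 + (i - center[2])^2 < r^2
  structure(m, kind = "internal_circle", threshold = NA_real_,
            pixel_count = sum(m), degenerate = !any(m), radius = r)
}
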