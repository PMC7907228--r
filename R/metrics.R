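#' Image derivative fields
#'
#' `gradient_field()` returns the partial derivatives of a slice by central
#' differences in the interior and one-sided differences at the borders
#' (x = column direction, y = row direction), together with the gradient
#' magnitude \eqn{|\nabla I| = \sqrt{(\partial I/\partial x)^2 +
#' (\partial I/\partial y)^2}}. `laplacian_field()` applies the 4-neighbor
#' stencil `[[0,1,0],[1,-4,1],[0,1,0]]` with replicate border padding.
#'
#' @param slice numeric matrix, at least 2 x 2.
#' @return For `gradient_field`, a list with `dx`, `dy`, `magnitude`,
#'   `mean_magnitude`; for `laplacian_field`, the Laplacian matrix.
#' @export
gradient_field <- function(slice) {
  stopifnot(is.matrix(slice), nrow(slice) >= 2L, ncol(slice) >= 2L)
  M <- nrow(slice); N <- ncol(slice)
  dx <- matrix(0, M, N)
  dx[, 1] <- slice[, 2] - slice[, 1]
  dx[, N] <- slice[, N] - slice[, N - 1]
  if (N > 2L) dx[, 2:(N - 1)] <- (slice[, 3:N] - slice[, 1:(N - 2)]) / 2
  dy <- matrix(0, M, N)
  dy[1, ] <- slice[2, ] - slice[1, ]
  dy[M, ] <- slice[M, ] - slice[M - 1, ]
  if (M > 2L) dy[2:(M - 1), ] <- (slice[3:M, ] - slice[1:(M - 2), ]) / 2
  mag <- sqrt(dx^2 + dy^2)
  list(dx = dx, dy = dy, magnitude = mag, mean_magnitude = mean(mag))
}

#' @rdname gradient_field
#' @export
laplacian_field <- function(slice) {
  stopifnot(is.matrix(slice), nrow(slice) >= 2L, ncol(slice) >= 2L)
  M <- nrow(slice); N <- ncol(slice)
  up    <- slice[c(1, 1:(M - 1)), ]
  down  <- slice[c(2:M, M), ]
  left  <- slice[, c(1, 1:(N - 1))]
  right <- slice[, c(2:N, N)]
  up + down + left + right - 4 * slice
}

#' Slice-wise sharpness metrics
#'
#' Seven no-reference focus measures evaluated on one optical section.
#' The pixel-statistics metrics (`intensity_variance`,
#' `gradient_magnitude_variance`, `laplacian_variance`,
#' `histogram_threshold`, `histogram_entropy`) accept a logical `mask`
#' restricting which pixels enter the statistic; derivatives are always
#' computed on the full slice first so the mask boundary injects no
#' artificial edges. The frequency-domain metrics (`frequency_threshold`,
#' `periodogram_kurtosis`) are defined on the whole slice and take no mask.
#' All variances are population variances (denominator = pixel count). An
#' empty or degenerate mask yields `NA`.
#'
#' * `intensity_variance`: variance of the (normalized) intensities; many
#'   intensities far apart in brightness score high, a flat slice scores 0.
#' * `gradient_magnitude_variance`: variance of \eqn{|\nabla I|}.
#' * `laplacian_variance`: variance of the discrete Laplacian.
#' * `histogram_threshold`: with T the mean masked intensity and f the
#'   histogram over `bins` bins on \[0, 1\],
#'   \eqn{\sum_{x_i > T} x_i f(x_i)} over bin centers \eqn{x_i}. The strict
#'   inequality acts on the histogram domain: only bins strictly above the
#'   bin containing T contribute, so a constant slice scores 0.
#' * `histogram_entropy`:
#'   \eqn{-\sum_i (f(x_i)/H_{max}) \log_2(f(x_i)/H_{max})} where
#'   \eqn{H_{max}} is the tallest bin; empty bins contribute 0. With
#'   `normalization = "sum"` an ordinary Shannon entropy of the histogram
#'   (f normalized by the pixel count) is computed instead — a deliberate
#'   departure from the Hmax form, available for comparison.
#' * `frequency_threshold`: sum of the DFT magnitudes \eqn{|F(u,v)|}
#'   strictly outside the centered circle \eqn{u^2+v^2 \le r_{freq}^2}
#'   (a high-pass filter; forward DFT is the plain unnormalized sum). A
#'   radius of 0 is an empty exclusion circle: every component, DC
#'   included, is summed.
#' * `periodogram_kurtosis`: bivariate kurtosis \eqn{\beta_{2,2}} of the
#'   periodogram \eqn{A = |F \cdot \bar F| = |F|^2} normalized to a
#'   probability distribution over centered frequencies. Lower values
#'   indicate a better-focused image, the opposite direction of the other
#'   six metrics.
#'
#' @param slice numeric matrix (stack-normalized to \[0, 1\] for the
#'   histogram metrics).
#' @param mask logical matrix or `NULL` for the full slice.
#' @param bins histogram bin count (default 256).
#' @param normalization `"hmax"` (default) or `"sum"`; see above.
#' @param r_freq high-pass radius in frequency-index units; defaults to
#'   `min(dim(slice)) / 4`.
#' @return A single numeric value (`NA` for degenerate input).
#' @name sharpness-metrics
NULL

#' @rdname sharpness-metrics
#' @export
intensity_variance <- function(slice, mask = NULL) {
  mask <- as_mask(mask, slice)
  if (!any(mask)) return(NA_real_)
  pop_var(slice[mask])
}

#' @rdname sharpness-metrics
#' @export
gradient_magnitude_variance <- function(slice, mask = NULL) {
  mask <- as_mask(mask, slice)
  if (!any(mask)) return(NA_real_)
  g <- gradient_field(slice)
  pop_var(g$magnitude[mask])
}

#' @rdname sharpness-metrics
#' @export
laplacian_variance <- function(slice, mask = NULL) {
  mask <- as_mask(mask, slice)
  if (!any(mask)) return(NA_real_)
  pop_var(laplacian_field(slice)[mask])
}

#' @rdname sharpness-metrics
#' @export
histogram_threshold <- function(slice, mask = NULL, bins = 256L) {
  mask <- as_mask(mask, slice)
  if (!any(mask)) return(NA_real_)
  x <- slice[mask]
  if (any(x < 0 | x > 1)) {
    stop("histogram metrics expect a normalized slice in [0, 1]", call. = FALSE)
  }
  thr <- mean(x)
  f <- hist_counts01(x, bins)
  centers <- (seq_len(bins) - 0.5) / bins
  # strict inequality applied on the histogram domain: only bins strictly
  # above the bin holding T count, so a constant slice scores 0
  thr_bin <- min(floor(thr * bins) + 1L, bins)
  keep <- seq_len(bins) > thr_bin
  sum(centers[keep] * f[keep])
}

#' @rdname sharpness-metrics
#' @export
histogram_entropy <- function(slice, mask = NULL, bins = 256L,
                              normalization = c("hmax", "sum")) {
  normalization <- match.arg(normalization)
  mask <- as_mask(mask, slice)
  if (!any(mask)) return(NA_real_)
  x <- slice[mask]
  if (any(x < 0 | x > 1)) {
    stop("histogram metrics expect a normalized slice in [0, 1]", call. = FALSE)
  }
  f <- hist_counts01(x, bins)
  f <- f[f > 0]
  p <- switch(normalization, hmax = f / max(f), sum = f / sum(f))
  -sum(p * log2(p))
}

#' @rdname sharpness-metrics
#' @export
frequency_threshold <- function(slice, r_freq = NULL) {
  stopifnot(is.matrix(slice), nrow(slice) >= 2L, ncol(slice) >= 2L)
  if (is.null(r_freq)) r_freq <- min(dim(slice)) / 4
  stopifnot(r_freq >= 0)
  Fm <- Mod(stats::fft(slice))
  if (r_freq == 0) return(sum(Fm))   # radius-0 circle excludes nothing
  u <- freq_index(nrow(slice))
  v <- freq_index(ncol(slice))
  outside <- outer(u^2, v^2, `+`) > r_freq^2
  sum(Fm[outside])
}

#' @rdname sharpness-metrics
#' @export
periodogram_kurtosis <- function(slice) {
  stopifnot(is.matrix(slice), nrow(slice) >= 2L, ncol(slice) >= 2L)
  Fc <- stats::fft(slice)
  A <- Mod(Fc)^2                       # |F * conj(F)|
  tot <- sum(A)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  h <- A / tot
  u <- freq_index(nrow(slice))
  v <- freq_index(ncol(slice))
  hu <- rowSums(h)                     # marginal over v
  hv <- colSums(h)
  mu_u <- sum(u * hu)
  mu_v <- sum(v * hv)
  du <- u - mu_u
  dv <- v - mu_v
  s2u <- sum(du^2 * hu)
  s2v <- sum(dv^2 * hv)
  if (s2u <= 0 || s2v <= 0) return(NA_real_)   # delta at DC: constant slice
  su <- sqrt(s2u); sv <- sqrt(s2v)
  gam <- function(k, l) sum(h * outer(du^k, dv^l)) / (su^k * sv^l)
  rho <- sum(h * outer(du, dv)) / (su * sv)
  denom <- (1 - rho^2)^2
  if (denom <= .Machine$double.eps) return(NA_real_)
  (gam(4, 0) + gam(0, 4) + 2 * gam(2, 2) +
      4 * rho * (rho * gam(2, 2) - gam(1, 3) - gam(3, 1))) / denom
}

#' Metric registry
#'
#' Names under which the seven metrics are addressable from configuration
#' or the command line.
#' @return Character vector of metric names.
#' @export
sqm_metrics <- function() {
  c("intensity_variance", "gradient_variance", "laplacian_variance",
    "histogram_threshold", "histogram_entropy", "frequency_threshold",
    "kurtosis")
}

metric_uses_mask <- function(metric) {
  !metric %in% c("frequency_threshold", "kurtosis")
}

eval_metric_slice <- function(metric, slice, mask, bins, r_freq) {
  switch(metric,
    intensity_variance  = intensity_variance(slice, mask),
    gradient_variance   = gradient_magnitude_variance(slice, mask),
    laplacian_variance  = laplacian_variance(slice, mask),
    histogram_threshold = histogram_threshold(slice, mask, bins = bins),
    histogram_entropy   = histogram_entropy(slice, mask, bins = bins),
    frequency_threshold = frequency_threshold(slice, r_freq = r_freq),
    kurtosis            = periodogram_kurtosis(slice),
    stop("unknown metric '", metric, "'; see sqm_metrics()", call. = FALSE)
  )
}

#' Evaluate a metric slice-by-slice over a z-stack
#'
#' Applies one sharpness metric independently to every optical section of a
#' stack, producing the per-slice metric plot \eqn{g(j)}, `j = 1..n`. The
#' stack is first normalized by its global maximum (see [normalize_stack()]).
#' Masking modes for the pixel-statistics metrics:
#'
#' * `"otsu"` (alias `"whole_thresholded"`): per-slice Otsu foreground.
#' * `"internal_circle"`: circle of radius `r` around the intensity-weighted
#'   centroid of the Otsu foreground, recomputed per slice.
#' * `"none"` (alias `"unmasked"`): whole slice.
#'
#' Frequency-domain metrics are always evaluated on the whole slice; asking
#' for a mask with them raises a warning and the mask is ignored. Slices on
#' which the requested mask is degenerate (e.g. constant background-only
#' slices) yield `NA`.
#'
#' @param stack a [zstack].
#' @param metric one of [sqm_metrics()].
#' @param masking masking mode, see above. Defaults to `"otsu"` for pixel
#'   metrics and `"none"` for frequency metrics.
#' @param r internal-circle radius, pixels (default 200).
#' @param bins histogram bin count for Otsu and the histogram metrics.
#' @param r_freq high-pass radius for `frequency_threshold`
#'   (default `min(M, N)/4`).
#' @param normalize divide by the stack-wide maximum first (default `TRUE`;
#'   a no-op when the maximum is already 1).
#' @return A tibble with columns `stack_id`, `metric`, `masking`, `slice`,
#'   `value`.
#' @export
evaluate_stack <- function(stack, metric, masking = NULL, r = 200,
                           bins = 256L, r_freq = NULL, normalize = TRUE) {
  stopifnot(inherits(stack, "zstack"))
  metric <- match.arg(metric, sqm_metrics())
  if (is.null(masking)) {
    masking <- if (metric_uses_mask(metric)) "otsu" else "none"
  }
  masking <- c(whole_thresholded = "otsu", unmasked = "none")[masking] %|na|% masking
  masking <- match.arg(masking, c("otsu", "internal_circle", "none"))
  if (!metric_uses_mask(metric) && masking != "none") {
    warning("metric '", metric, "' is evaluated on the whole slice; ",
            "masking mode '", masking, "' ignored", call. = FALSE)
    masking <- "none"
  }
  if (normalize) stack <- normalize_stack(stack)
  vals <- vapply(stack$slices, function(s) {
    mask <- switch(masking,
      none = NULL,
      otsu = otsu_mask(s, bins = bins),
      internal_circle = {
        fg <- otsu_mask(s, bins = bins)
        if (attr(fg, "degenerate")) fg else
          internal_circle_mask(dim(s), centroid(s, fg), r = r)
      })
    if (!is.null(mask) && attr(mask, "degenerate")) return(NA_real_)
    eval_metric_slice(metric, s, mask, bins = bins, r_freq = r_freq)
  }, numeric(1))
  tibble::tibble(stack_id = stack$stack_id, metric = metric,
                 masking = masking, slice = seq_along(vals), value = vals)
}

`%|na|%` <- function(a, b) if (length(a) == 1L && is.na(a)) b else unname(a)
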