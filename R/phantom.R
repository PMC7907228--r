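#' Synthetic spheroid phantom specification
#'
#' Parameters of the phantom generator (see [generate_phantom()]). The
#' phantom emulates a nuclei-dense spherical object imaged as a z-stack on
#' a single-side-illuminated light-sheet system: slice sharpness and
#' brightness degrade with axial depth and, optionally, with lateral
#' distance from the illuminated (left) edge. One `clearing_quality`
#' parameter `q` in \[0, 1\] controls the degradation rate: at `q = 1`
#' degradation is minimal (blur stays at `sigma0`, no attenuation), at
#' `q = 0` it is strongest.
#'
#' Defaults give a 256 x 256 x 60 stack with a 100 px spheroid holding 300
#' nuclei of radius 2-4 px — small enough that a full pipeline run takes
#' seconds.
#'
#' @param width,height slice size N x M, pixels.
#' @param n_slices number of optical sections.
#' @param spheroid_radius radius of the cell-bearing sphere, pixels.
#' @param n_nuclei number of nuclei.
#' @param nucleus_radius range (min, max) of nucleus radius, pixels.
#' @param nucleus_intensity range of nucleus peak intensity in \[0, 1\].
#' @param clearing_quality q in \[0, 1\].
#' @param sigma0 baseline Gaussian blur sigma applied to every slice, px.
#' @param axial_blur_slope added blur sigma per slice of depth at q = 0.
#' @param axial_attenuation per-slice log-intensity decay at q = 0.
#' @param lateral_blur_slope added blur sigma per pixel of distance from the
#'   illuminated left edge at q = 0 (0 disables lateral degradation).
#' @param noise_sd additive Gaussian read-noise standard deviation.
#' @param seed integer RNG seed; the phantom is fully reproducible from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width = 256L, height = 256L, n_slices = 60L,
                         spheroid_radius = 100, n_nuclei = 300L,
                         nucleus_radius = c(2, 4),
                         nucleus_intensity = c(0.5, 1),
                         clearing_quality = 0.5, sigma0 = 0.6,
                         axial_blur_slope = 0.05, axial_attenuation = 0.02,
                         lateral_blur_slope = 0.002, noise_sd = 0.01,
                         seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_slices = as.integer(n_slices),
               spheroid_radius = spheroid_radius, n_nuclei = as.integer(n_nuclei),
               nucleus_radius = nucleus_radius,
               nucleus_intensity = nucleus_intensity,
               clearing_quality = clearing_quality, sigma0 = sigma0,
               axial_blur_slope = axial_blur_slope,
               axial_attenuation = axial_attenuation,
               lateral_blur_slope = lateral_blur_slope,
               noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(spec$clearing_quality >= 0, spec$clearing_quality <= 1,
            spec$noise_sd >= 0, spec$sigma0 >= 0, spec$n_slices >= 1,
            2 * spec$spheroid_radius <= min(spec$width, spec$height),
            max(spec$nucleus_radius) < spec$spheroid_radius)
  structure(spec, class = "phantom_spec")
}

#' Generate a synthetic spheroid z-stack
#'
#' Nuclei are isotropic 3-D Gaussian blobs (sigma = radius / 2) placed
#' uniformly inside a sphere centered in the volume; slice `j` of the ideal
#' stack is the sum of the blob cross-sections at that depth. Optical
#' degradation is depth-linear in blur and in log-attenuation — the
#' simplest model reproducing the characteristic decay of slice sharpness
#' towards deeper layers (fastest in the outer third for poorly cleared
#' samples):
#' \deqn{\sigma(j) = \sigma_0 + s_{ax} (j-1)(1-q), \qquad
#'       a(j) = e^{-\mu_{ax} (j-1)(1-q)}}
#' Lateral degradation (light-sheet illumination from the left) blends in
#' extra blur growing linearly with the distance from the left edge at rate
#' `lateral_blur_slope * (1-q)`. Gaussian read noise is added and
#' intensities clipped to \[0, 1\]. Slice 1 is the top (illumination-near)
#' face. This is a test harness emulating plot shapes, not a physical
#' light-sheet PSF model.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `stack` (a [zstack] of float slices in \[0, 1\]) and
#'   `truth` (list with `per_slice` tibble of `slice`, `sigma`,
#'   `attenuation`; `nuclei` tibble of centers; the `spec`; and `q`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  M <- spec$height; N <- spec$width; n <- spec$n_slices
  q <- spec$clearing_quality
  R <- spec$spheroid_radius
  cx <- (N - 1) / 2; cy <- (M - 1) / 2
  dz <- 2 * R / n                       # axial pixel extent of one slice
  z_center <- (n + 1) / 2
  # uniform positions inside the sphere by rejection
  nuc <- matrix(numeric(0), 0, 3)
  while (nrow(nuc) < spec$n_nuclei) {
    m <- spec$n_nuclei - nrow(nuc)
    p <- matrix(stats::runif(3 * m, -1, 1), m, 3)
    nuc <- rbind(nuc, p[rowSums(p^2) < 1, , drop = FALSE])
  }
  nuc <- nuc[seq_len(spec$n_nuclei), , drop = FALSE] * R
  nuclei <- tibble::tibble(
    x = cx + nuc[, 1], y = cy + nuc[, 2],
    z_slice = z_center + nuc[, 3] / dz,
    radius = stats::runif(spec$n_nuclei, spec$nucleus_radius[1],
                          spec$nucleus_radius[2]),
    peak = stats::runif(spec$n_nuclei, spec$nucleus_intensity[1],
                        spec$nucleus_intensity[2]))

  ideal <- replicate(n, matrix(0, M, N), simplify = FALSE)
  for (k in seq_len(spec$n_nuclei)) {
    s <- nuclei$radius[k] / 2
    w <- ceiling(3 * s)
    xi <- round(nuclei$x[k]); yi <- round(nuclei$y[k])
    cols <- max(0, xi - w):min(N - 1, xi + w)
    rows <- max(0, yi - w):min(M - 1, yi + w)
    if (!length(cols) || !length(rows)) next
    gx <- exp(-(cols - nuclei$x[k])^2 / (2 * s^2))
    gy <- exp(-(rows - nuclei$y[k])^2 / (2 * s^2))
    blob <- nuclei$peak[k] * outer(gy, gx)
    js <- seq_len(n)
    dzk <- abs(js - nuclei$z_slice[k]) * dz
    js <- js[dzk < 3 * s]
    for (j in js) {
      az <- exp(-((j - nuclei$z_slice[k]) * dz)^2 / (2 * s^2))
      ideal[[j]][rows + 1, cols + 1] <- ideal[[j]][rows + 1, cols + 1] + az * blob
    }
  }
  ideal <- lapply(ideal, function(s) pmin(s, 1))

  sigma_j <- spec$sigma0 + spec$axial_blur_slope * (seq_len(n) - 1) * (1 - q)
  atten_j <- exp(-spec$axial_attenuation * (seq_len(n) - 1) * (1 - q))
  sig_lat_max <- spec$lateral_blur_slope * (N - 1) * (1 - q)
  wx <- matrix(rep((seq_len(N) - 1) / max(1, N - 1), each = M), M)
  slices <- vector("list", n)
  for (j in seq_len(n)) {
    base <- blur_gaussian(ideal[[j]], sigma_j[j])
    out <- if (sig_lat_max > 0) {
      far <- blur_gaussian(ideal[[j]], sigma_j[j] + sig_lat_max)
      (1 - wx) * base + wx * far
    } else base
    out <- out * atten_j[j]
    if (spec$noise_sd > 0) out <- out + matrix(stats::rnorm(M * N, 0, spec$noise_sd), M)
    slices[[j]] <- pmin(pmax(out, 0), 1)
  }
  stack <- zstack(slices, stack_id = sprintf("phantom_q%.2f_s%d", q, spec$seed))
  truth <- list(
    per_slice = tibble::tibble(slice = seq_len(n), sigma = sigma_j,
                               attenuation = atten_j),
    nuclei = nuclei, q = q, spec = spec,
    lateral_sigma_max = sig_lat_max)
  list(stack = stack, truth = truth)
}

#' Simulate expert scores for phantom stacks
#'
#' Emulates the human 1-5 scoring of stack regions: the ground-truth region
#' quality of each phantom (mean over the region's slices of
#' `attenuation / (1 + (sigma - sigma0))`, i.e. brightness retained and
#' blur incurred) is min-max mapped to \[1, 5\] across the whole set, a
#' truncated Gaussian rater error is added, and each rater's score is
#' rounded to the integer anchors 1-5; the table holds the mean over
#' `raters` raters. With `noise_sd = 0` the scores are the deterministic
#' quality map.
#'
#' @param truths list of phantom `truth` objects from [generate_phantom()].
#' @param noise_sd rater error standard deviation on the 1-5 scale.
#' @param seed RNG seed.
#' @param raters number of simulated raters averaged per cell (default 1).
#' @param parts number of stack regions (default 3).
#' @return An expert-score tibble (`stack_id`, `region`, `score`) passing
#'   [validate_expert_scores()].
#' @export
generate_expert_scores <- function(truths, noise_sd = 0.3, seed = 1L,
                                   raters = 1L, parts = 3L) {
  stopifnot(noise_sd >= 0, raters >= 1L)
  set.seed(seed)
  labels <- if (parts == 3L) region_levels() else paste0("region_", seq_len(parts))
  quality <- purrr::map(truths, function(tr) {
    ps <- tr$per_slice
    n <- nrow(ps)
    reg <- region_of(ps$slice, n, parts, labels)
    tibble::tibble(stack_id = tr$spec_id %||% sprintf("phantom_q%.2f_s%d",
                                                      tr$q, tr$spec$seed),
                   region = reg,
                   quality = ps$attenuation / (1 + (ps$sigma - tr$spec$sigma0))) |>
      dplyr::group_by(.data$stack_id, .data$region) |>
      dplyr::summarise(quality = mean(.data$quality), .groups = "drop")
  }) |> purrr::list_rbind()
  lo <- min(quality$quality); hi <- max(quality$quality)
  q15 <- if (hi > lo) 1 + 4 * (quality$quality - lo) / (hi - lo) else
    rep(3, nrow(quality))
  score <- vapply(q15, function(mu) {
    mean(vapply(seq_len(raters), function(r) {
      raw <- mu + stats::rnorm(1, 0, noise_sd)
      round(min(5, max(1, raw)))
    }, numeric(1)))
  }, numeric(1))
  validate_expert_scores(tibble::tibble(stack_id = quality$stack_id,
                                        region = as.character(quality$region),
                                        score = score))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
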