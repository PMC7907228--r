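#' Z-stack container
#'
#' A `zstack` is an ordered list of single-channel 2-D intensity matrices, all
#' of identical size, together with minimal acquisition metadata. Slice 1 is
#' the top of the spheroid (first TIFF page) unless the stack was read with
#' `reverse = TRUE`.
#'
#' @param slices list of numeric matrices, all the same dimension, values >= 0.
#' @param stack_id opaque identifier (defaults to `"stack"`).
#' @param bit_depth integer source bit depth (8 or 16), or `NA` for float data.
#' @param pixel_size micrometres per pixel, or `NA` if unknown.
#'
#' @return An object of class `zstack` with elements `slices`, `stack_id`,
#'   `bit_depth`, `pixel_size`.
#' @export
zstack <- function(slices, stack_id = "stack", bit_depth = NA_integer_,
                   pixel_size = NA_real_) {
  if (!is.list(slices) || length(slices) < 1L) {
    stop("`slices` must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- vapply(slices, function(s) {
    if (!is.matrix(s) || !is.numeric(s)) {
      stop("every slice must be a numeric matrix", call. = FALSE)
    }
    dim(s)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all slices must share the same dimensions", call. = FALSE)
  }
  if (any(vapply(slices, function(s) any(s < 0, na.rm = TRUE), logical(1)))) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(
    list(slices = slices, stack_id = as.character(stack_id),
         bit_depth = bit_depth, pixel_size = pixel_size),
    class = "zstack"
  )
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<zstack '%s'> %d slices of %d x %d px", x$stack_id,
              length(x$slices), d[1], d[2]))
  if (!is.na(x$bit_depth)) cat(sprintf(", %d-bit", x$bit_depth))
  if (!is.na(x$pixel_size)) cat(sprintf(", %.3g um/px", x$pixel_size))
  cat("\n")
  invisible(x)
}

#' @export
length.zstack <- function(x) length(x$slices)

#' @export
dim.zstack <- function(x) c(dim(x$slices[[1]]), length(x$slices))

#' Read a grayscale TIFF z-stack
#'
#' Reads a single- or multi-page grayscale TIFF. Page order is taken as
#' top-to-bottom of the spheroid; pass `reverse = TRUE` for stacks acquired
#' bottom-first. Integer pixel data are retained losslessly; multichannel
#' (RGB) input is rejected rather than silently converted, because the
#' analysis is defined on single-channel nuclei images.
#'
#' @param path path to a readable TIFF file.
#' @param stack_id identifier stored on the stack; defaults to the file name.
#' @param reverse reverse slice order after reading.
#' @param pixel_size optional micrometres per pixel to attach as metadata.
#'
#' @return A [zstack].
#' @export
read_stack <- function(path, stack_id = NULL, reverse = FALSE,
                       pixel_size = NA_real_) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stop("cannot read '", path, "' as TIFF: ",
                                             conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  depth <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(depth) && depth %in% c(8L, 16L)) {
    # integer data: re-read undivided so intensities round-trip losslessly
    pages2 <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages2)) pages2 <- list(pages2)
    pages <- pages2
  } else {
    depth <- NA_integer_   # float samples stay on their native scale
  }
  slices <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) p <- p[, , 1] else
        stop("page ", i, " has ", dim(p)[3],
             " channels; only single-channel grayscale TIFFs are supported",
             call. = FALSE)
    }
    storage.mode(p) <- "double"
    p
  })
  if (reverse) slices <- rev(slices)
  zstack(slices,
         stack_id = if (is.null(stack_id)) sub("\\.[^.]*$", "", basename(path)) else stack_id,
         bit_depth = depth, pixel_size = pixel_size)
}

#' Write a z-stack as a multi-page grayscale TIFF
#'
#' Integer-valued stacks are written at their source bit depth (8 or 16) so
#' that [read_stack()] recovers them bit-identically; float stacks must lie in
#' \[0, 1\] and are written as 32-bit float.
#'
#' @param stack a [zstack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  depth <- stack$bit_depth
  if (!is.na(depth)) {
    scale <- 2^depth - 1
    pages <- lapply(stack$slices, function(s) s / scale)
    ok <- tiff::writeTIFF(pages, path, bits.per.sample = depth)
  } else {
    if (any(vapply(stack$slices, function(s) any(s > 1), logical(1)))) {
      stop("float stacks must be normalized to [0, 1] before writing", call. = FALSE)
    }
    ok <- tiff::writeTIFF(stack$slices, path, bits.per.sample = 32L)
  }
  if (!all(ok > 0)) stop("failed to write '", path, "'", call. = FALSE)
  invisible(path)
}

#' Read an expert-score table
#'
#' Experts score each spheroid region on an integer-anchored 1-5 scale
#' (1 worst, 5 sharpest); the table holds the mean score per
#' (stack, region). Validation rejects scores outside \[1, 5\], unknown
#' region labels and duplicated (stack_id, region) rows.
#'
#' @param path CSV file with columns `stack_id`, `region`, `score`.
#' @return A tibble with columns `stack_id` (character), `region`
#'   (factor top/middle/bottom) and `score` (numeric in \[1, 5\]).
#' @export
read_expert_scores <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          stack_id = readr::col_character(),
                          region = readr::col_character(),
                          score = readr::col_double()))
  validate_expert_scores(tb)
}

#' @rdname read_expert_scores
#' @param scores a data frame to validate in place of a file.
#' @export
validate_expert_scores <- function(scores) {
  need <- c("stack_id", "region", "score")
  if (!all(need %in% names(scores))) {
    stop("expert scores need columns stack_id, region, score", call. = FALSE)
  }
  bad_region <- setdiff(unique(scores$region), region_levels())
  if (length(bad_region)) {
    stop("unknown region label(s): ", paste(bad_region, collapse = ", "),
         "; expected top/middle/bottom", call. = FALSE)
  }
  if (any(!is.finite(scores$score)) || any(scores$score < 1 | scores$score > 5)) {
    stop("expert scores must lie in [1, 5]", call. = FALSE)
  }
  dup <- duplicated(scores[, c("stack_id", "region")])
  if (any(dup)) {
    stop("duplicated (stack_id, region) rows: ",
         paste(unique(scores$stack_id[dup]), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(scores) |>
    dplyr::mutate(stack_id = as.character(.data$stack_id),
                  region = factor(.data$region, levels = region_levels()))
}

#' Region labels, top of the stack first
#' @return `c("top", "middle", "bottom")`
#' @export
region_levels <- function() c("top", "middle", "bottom")

#' Write / read per-slice metric values as CSV
#'
#' One row per slice with columns `slice` and `value` plus identifying
#' columns (`stack_id`, `metric`, `masking`) when present. Undefined slice
#' values (degenerate masks) are `NA` in R and serialized as empty cells.
#'
#' @param plot a metric-plot tibble from [evaluate_stack()].
#' @param path output CSV path.
#' @return `path` invisibly; for the reader, a tibble.
#' @export
write_metric_csv <- function(plot, path) {
  if (nrow(plot) == 0L) stop("refusing to write an empty metric plot", call. = FALSE)
  readr::write_csv(plot, path, na = "")
  invisible(path)
}

#' @rdname write_metric_csv
#' @export
read_metric_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = "")
}
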