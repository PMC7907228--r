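#' Broom-style tidiers for sqm result objects
#'
#' `tidy()` returns the per-unit table of a result (per-plot scores, per-
#' stratum correlations, pairwise Dunn comparisons); `glance()` returns the
#' one-row summary.
#'
#' @param x an `sqm_scoreset`, `sqm_correlation` or `sqm_group_comparison`.
#' @param ... unused.
#' @return A tibble.
#' @name sqm-tidiers
NULL

#' @rdname sqm-tidiers
#' @method tidy sqm_scoreset
#' @export
tidy.sqm_scoreset <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname sqm-tidiers
#' @method glance sqm_scoreset
#' @export
glance.sqm_scoreset <- function(x, ...) {
  tibble::tibble(alpha = attr(x, "alpha"), beta = attr(x, "beta"),
                 degenerate = attr(x, "degenerate"), n_plots = nrow(x))
}

#' @rdname sqm-tidiers
#' @method tidy sqm_correlation
#' @export
tidy.sqm_correlation <- function(x, ...) x$strata

#' @rdname sqm-tidiers
#' @method glance sqm_correlation
#' @export
glance.sqm_correlation <- function(x, ...) {
  ov <- x$strata[x$strata$stratum == "overall", ]
  tibble::tibble(r = ov$r, slope = ov$slope, intercept = ov$intercept,
                 p_value = ov$p_value, n_pairs = ov$n,
                 n_unmatched = nrow(x$unmatched))
}

#' @rdname sqm-tidiers
#' @method tidy sqm_group_comparison
#' @export
tidy.sqm_group_comparison <- function(x, ...) x$dunn

#' @rdname sqm-tidiers
#' @method glance sqm_group_comparison
#' @export
glance.sqm_group_comparison <- function(x, ...) {
  tibble::tibble(kw_statistic = x$kw_statistic, kw_df = x$kw_df,
                 kw_p = x$kw_p, n_groups = length(x$group_sizes),
                 n_values = sum(x$group_sizes))
}
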