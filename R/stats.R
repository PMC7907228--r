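#' Correlate region scores with expert evaluations
#'
#' Matches metric region scores to a table of expert scores on
#' (stack_id, region), then quantifies agreement with Pearson's correlation
#' and an ordinary least-squares fit (expert score on metric score), both
#' overall and within each region. Stacks or regions present on one side
#' only are reported in `unmatched`, never silently dropped.
#'
#' @param region_scores tibble from [score_regions()] (needs `stack_id`,
#'   `region` and the score column).
#' @param experts expert-score tibble as from [read_expert_scores()].
#' @param score_col which metric score to correlate, `"score15"` (default)
#'   or `"score01"`; Pearson's r is invariant to this linear rescale, the
#'   regression coefficients are not.
#' @return An object of class `sqm_correlation`: list with `strata` (tibble
#'   of stratum, n, r, slope, intercept, p_value), `pairs` (the matched
#'   data), and `unmatched` (tibble of unmatched stack_id/region with the
#'   side they were missing from).
#' @export
correlate_with_experts <- function(region_scores, experts,
                                   score_col = c("score15", "score01")) {
  score_col <- match.arg(score_col)
  experts <- validate_expert_scores(experts)
  ms <- region_scores |>
    dplyr::mutate(stack_id = as.character(.data$stack_id),
                  region = as.character(.data$region)) |>
    dplyr::select("stack_id", "region", metric_score = dplyr::all_of(score_col))
  ex <- experts |>
    dplyr::mutate(region = as.character(.data$region)) |>
    dplyr::select("stack_id", "region", expert_score = "score")
  pairs <- dplyr::inner_join(ms, ex, by = c("stack_id", "region"))
  unmatched <- dplyr::bind_rows(
    dplyr::anti_join(ms, ex, by = c("stack_id", "region")) |>
      dplyr::transmute(.data$stack_id, .data$region, missing_from = "experts"),
    dplyr::anti_join(ex, ms, by = c("stack_id", "region")) |>
      dplyr::transmute(.data$stack_id, .data$region, missing_from = "metric_scores"))
  if (nrow(pairs) < 3L) {
    stop("need at least 3 matched (stack_id, region) pairs; got ",
         nrow(pairs), call. = FALSE)
  }
  fit_stratum <- function(d, label) {
    if (nrow(d) < 3L || stats::sd(d$metric_score) == 0 ||
        stats::sd(d$expert_score) == 0) {
      return(tibble::tibble(stratum = label, n = nrow(d), r = NA_real_,
                            slope = NA_real_, intercept = NA_real_,
                            p_value = NA_real_))
    }
    fit <- stats::lm(expert_score ~ metric_score, data = d)
    ct <- stats::cor.test(d$metric_score, d$expert_score)
    tibble::tibble(stratum = label, n = nrow(d), r = unname(ct$estimate),
                   slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   p_value = ct$p.value)
  }
  strata <- dplyr::bind_rows(
    fit_stratum(pairs, "overall"),
    purrr::map(region_levels(),
               \(rg) fit_stratum(dplyr::filter(pairs, .data$region == rg), rg)) |>
      purrr::list_rbind())
  structure(list(strata = strata, pairs = tibble::as_tibble(pairs),
                 unmatched = unmatched, score_col = score_col),
            class = "sqm_correlation")
}

#' @export
print.sqm_correlation <- function(x, ...) {
  cat("<sqm_correlation> metric vs. expert scores (", x$score_col, ")\n", sep = "")
  print(x$strata)
  if (nrow(x$unmatched)) {
    cat("unmatched rows:", nrow(x$unmatched), "(see $unmatched)\n")
  }
  invisible(x)
}

#' Significance stars
#'
#' `*` for p <= 0.05, `**` for p <= 0.01, `***` for p <= 0.001, `ns`
#' otherwise.
#' @param p vector of p-values.
#' @return Character vector.
#' @export
signif_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_,
                   p <= 0.001 ~ "***",
                   p <= 0.01 ~ "**",
                   p <= 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' Compare score groups: Kruskal-Wallis with Dunn's post-hoc test
#'
#' Region scores of different clearing protocols (or cell lines) are
#' compared non-parametrically: a Kolmogorov-Smirnov check against a fitted
#' normal distribution per group motivates the non-parametric choice, the
#' Kruskal-Wallis rank test assesses any overall group difference, and
#' Dunn's z-test on the pooled mean ranks (with tie correction) resolves
#' which pairs differ, with p-values adjusted for multiple comparisons
#' (Holm by default). Significance stars follow the 0.05 / 0.01 / 0.001
#' convention.
#'
#' @param data data frame of scores with a grouping column.
#' @param group,value column names (tidy-eval) of the group label and the
#'   score.
#' @param reference optional group label: restrict Dunn pairs to
#'   comparisons against this group (e.g. the uncleared control).
#' @param p_adjust adjustment method for Dunn p-values, any of
#'   [stats::p.adjust.methods] (default `"holm"`).
#' @return An object of class `sqm_group_comparison`: list with
#'   `kw_statistic`, `kw_df`, `kw_p`, `normality` (per-group KS p-values),
#'   `dunn` (tibble: group1, group2, z, p_unadjusted, p_adjusted, stars)
#'   and `group_sizes`.
#' @export
compare_groups <- function(data, group, value, reference = NULL,
                           p_adjust = "holm") {
  g <- factor(dplyr::pull(data, {{ group }}))
  x <- dplyr::pull(data, {{ value }})
  keep <- !is.na(x) & !is.na(g)
  g <- droplevels(g[keep]); x <- x[keep]
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 values; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  normality <- tibble::tibble(
    group = names(sizes),
    n = as.integer(sizes),
    ks_p = vapply(names(sizes), function(lv) {
      xi <- x[g == lv]
      if (stats::sd(xi) == 0) return(NA_real_)
      suppressWarnings(stats::ks.test(xi, "pnorm", mean(xi), stats::sd(xi))$p.value)
    }, numeric(1)))
  kw <- stats::kruskal.test(x, g)
  dunn <- dunn_test(x, g, p_adjust = p_adjust)
  if (!is.null(reference)) {
    if (!reference %in% levels(g)) {
      stop("reference group '", reference, "' not present", call. = FALSE)
    }
    dunn <- dunn[dunn$group1 == reference | dunn$group2 == reference, ]
    dunn$p_adjusted <- stats::p.adjust(dunn$p_unadjusted, method = p_adjust)
    dunn$stars <- signif_stars(dunn$p_adjusted)
  }
  structure(list(kw_statistic = unname(kw$statistic),
                 kw_df = unname(kw$parameter), kw_p = kw$p.value,
                 normality = normality, dunn = dunn,
                 group_sizes = sizes, p_adjust = p_adjust),
            class = "sqm_group_comparison")
}

#' Dunn's test of pairwise mean-rank differences
#'
#' For groups i, j with pooled ranks over N observations, the statistic is
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' with the tie-correction sum over tie groups of size t; two-sided normal
#' p-values are then adjusted for the number of pairs.
#'
#' @param x numeric values.
#' @param g group factor.
#' @param p_adjust adjustment method (default Holm).
#' @return Tibble with `group1`, `group2`, `z`, `p_unadjusted`,
#'   `p_adjusted`, `stars` (symmetric in the pair order).
#' @export
dunn_test <- function(x, g, p_adjust = "holm") {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_term
  rb <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  combos <- utils::combn(levels(g), 2)
  z <- vapply(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    (rb[[a]] - rb[[b]]) / sqrt(v * (1 / n[[a]] + 1 / n[[b]]))
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(p, method = p_adjust)
  tibble::tibble(group1 = combos[1, ], group2 = combos[2, ], z = z,
                 p_unadjusted = p, p_adjusted = pmin(padj, 1),
                 stars = signif_stars(pmin(padj, 1)))
}

#' @export
print.sqm_group_comparison <- function(x, ...) {
  cat(sprintf(
    "<sqm_group_comparison> Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.4g\n",
    x$kw_statistic, x$kw_df, x$kw_p))
  cat("groups:", paste(sprintf("%s (n=%d)", names(x$group_sizes),
                               as.integer(x$group_sizes)), collapse = ", "), "\n")
  cat("Dunn pairwise comparisons (", x$p_adjust, "-adjusted):\n", sep = "")
  print(x$dunn)
  invisible(x)
}
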