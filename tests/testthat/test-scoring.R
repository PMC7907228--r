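mk_plot <- function(id, values) {
  tibble::tibble(stack_id = id, slice = seq_along(values), value = values)
}

test_that("region split uses rounded thirds and covers every slice", {
  p9 <- split_regions(mk_plot("a", rep(0, 9)))
  expect_equal(as.character(p9$region), rep(c("top", "middle", "bottom"), each = 3))

  p10 <- split_regions(mk_plot("a", rep(0, 10)))
  expect_equal(table(p10$region)[["top"]], 3)     # round(10/3) = 3
  expect_equal(table(p10$region)[["middle"]], 4)  # up to round(20/3) = 7
  expect_equal(table(p10$region)[["bottom"]], 3)

  p3 <- split_regions(mk_plot("a", rep(0, 3)))
  expect_equal(as.integer(table(p3$region)), c(1, 1, 1))

  expect_error(split_regions(mk_plot("a", rep(0, 2))), "cannot split")

  # stacks of different lengths are split on their own n
  two <- dplyr::bind_rows(mk_plot("a", rep(0, 9)), mk_plot("b", rep(0, 12)))
  sp <- split_regions(two)
  expect_equal(sum(sp$region == "top" & sp$stack_id == "b"), 4)
})

test_that("joint min-max score matches hand evaluations and its bounds", {
  # two plots (0,0) and (1,1): scores 0 and 1
  s <- score_plots(dplyr::bind_rows(mk_plot("a", c(0, 0)), mk_plot("b", c(1, 1))))
  expect_equal(s$score01[s$stack_id == "a"], 0)
  expect_equal(s$score01[s$stack_id == "b"], 1)

  # adding g3 = (0, 1) leaves alpha/beta and scores, g3 itself gets 0.5
  s3 <- score_plots(dplyr::bind_rows(mk_plot("a", c(0, 0)), mk_plot("b", c(1, 1)),
                                     mk_plot("c", c(0, 1))))
  expect_equal(s3$score01[s3$stack_id == "a"], 0)
  expect_equal(s3$score01[s3$stack_id == "b"], 1)
  expect_equal(s3$score01[s3$stack_id == "c"], 0.5)

  # plot pinned at the set extremes scores exactly 1 / exactly 0
  set.seed(41)
  plots <- purrr::map(1:4, \(i) mk_plot(paste0("p", i), runif(10, 0.2, 0.8)))
  plots <- c(plots, list(mk_plot("hi", rep(0.9, 10)), mk_plot("lo", rep(0.1, 10))))
  sc <- score_plots(purrr::list_rbind(plots))
  expect_identical(sc$score01[sc$stack_id == "hi"], 1)
  expect_identical(sc$score01[sc$stack_id == "lo"], 0)
  expect_true(all(sc$score01 >= 0 & sc$score01 <= 1))
  expect_equal(attr(sc, "alpha"), 0.9)
  expect_equal(attr(sc, "beta"), 0.1)

  # degenerate set: all plots constant at the same value
  expect_true(attr(score_plots(mk_plot("a", rep(2, 5))), "degenerate"))
  expect_equal(score_plots(mk_plot("a", rep(2, 5)))$score01, 0)
})

test_that("NA slices drop out of the alpha/beta pool and the plot mean", {
  a <- mk_plot("a", c(0.5, NA, 0.5))
  b <- mk_plot("b", c(0.2, 0.8, NA))
  s <- score_plots(dplyr::bind_rows(a, b))
  expect_equal(attr(s, "alpha"), 0.8)
  expect_equal(attr(s, "beta"), 0.2)
  expect_equal(s$n_slices, c(2L, 2L))
  expect_equal(s$score01[s$stack_id == "a"], 0.5)  # mean of (0.5,0.5) rescaled
  expect_equal(s$score01[s$stack_id == "b"], 0.5)
})

test_that("score is invariant under joint affine maps of the plots", {
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    plots <- purrr::list_rbind(
      purrr::map(1:k, \(i) mk_plot(paste0("p", i), runif(sample(5:15, 1)))))
    base <- score_plots(plots)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    mapped <- dplyr::mutate(plots, value = a * value + b)
    expect_equal(score_plots(mapped)$score01, base$score01, tolerance = 1e-12)
  }
})

test_that("region scores of a constant plot are equal across regions", {
  flat <- mk_plot("flat", rep(0.4, 12))
  other <- mk_plot("o", seq(0, 1, length.out = 12))
  rs <- score_regions(dplyr::bind_rows(flat, other), pool = "global")
  flat_scores <- rs$score01[rs$stack_id == "flat"]
  expect_equal(max(flat_scores) - min(flat_scores), 0, tolerance = 1e-12)
})

test_that("1-5 rescale is the linear min-max map and preserves order", {
  s <- score_plots(dplyr::bind_rows(mk_plot("a", c(0, 0)), mk_plot("b", c(1, 1)),
                                    mk_plot("c", c(0, 1))))
  r <- rescale_1_5(s)
  expect_equal(sort(r$score15), c(1, 3, 5))

  set.seed(43)
  s$score01 <- runif(3)
  r <- rescale_1_5(s)
  expect_equal(cor(r$score01, r$score15, method = "spearman"), 1)
  expect_equal(range(r$score15), c(1, 5))

  s$score01 <- rep(0.7, 3)
  expect_warning(r <- rescale_1_5(s), "midpoint")
  expect_equal(r$score15, rep(3, 3))
})

test_that("pearson matches the textbook formula and guards degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  set.seed(44)
  a <- runif(20); b <- runif(20)
  expect_equal(pearson(a, b), naive_pearson(a, b), tolerance = 1e-12)
  expect_error(pearson(a, rep(1, 20)), "zero variance")
  expect_error(pearson(1:2, 2:1), "at least 3")
})

test_that("expert correlation is exact for identical scores and lists unmatched", {
  rs <- tidyr::expand_grid(stack_id = paste0("s", 1:6),
                           region = region_levels()) |>
    dplyr::mutate(score01 = seq(0, 1, length.out = 18),
                  score15 = 1 + 4 * score01)
  experts <- dplyr::transmute(rs, stack_id, region, score = score15)
  cr <- correlate_with_experts(rs, experts)
  expect_equal(tidy(cr)$r, rep(1, 4), tolerance = 1e-12)
  expect_equal(nrow(cr$unmatched), 0)
  expect_equal(glance(cr)$n_pairs, 18)

  # one stack missing on the expert side is reported, not dropped silently
  cr2 <- correlate_with_experts(rs, experts[experts$stack_id != "s6", ])
  expect_equal(nrow(cr2$unmatched), 3)
  expect_true(all(cr2$unmatched$stack_id == "s6"))
  expect_equal(tidy(cr2)$n[1], 15)
})

test_that("simulated noisy experts still correlate strongly at 18 pairs", {
  set.seed(45)
  truth15 <- seq(1, 5, length.out = 18)
  rs <- tidyr::expand_grid(stack_id = paste0("s", 1:6),
                           region = region_levels()) |>
    dplyr::mutate(score15 = truth15, score01 = (truth15 - 1) / 4)
  experts <- rs |>
    dplyr::transmute(stack_id, region,
                     score = pmin(5, pmax(1, score15 + rnorm(18, 0, 0.3))))
  cr <- correlate_with_experts(rs, experts)
  expect_gt(glance(cr)$r, 0.8)
})

test_that("rank tests flag separated groups and clear duplicated groups", {
  d <- tibble::tibble(group = rep(c("g1", "g2"), times = c(5, 6)),
                      value = c(1:5, 10:15))
  gc <- compare_groups(d, group, value)
  expect_lt(gc$kw_p, 0.01)
  expect_equal(tidy(gc)$stars, "**")
  expect_true(all(tidy(gc)$p_adjusted <= 1))

  # the same sample under two labels: Dunn p for the pair ~ 1
  d2 <- tibble::tibble(group = rep(c("a", "b", "c"), each = 6),
                       value = c(1:6, 1:6, 7:12 + 0.5))
  gc2 <- compare_groups(d2, group, value)
  ab <- tidy(gc2) |> dplyr::filter(group1 == "a", group2 == "b")
  expect_gt(ab$p_adjusted, 0.95)
  expect_equal(ab$z, 0)

  expect_error(compare_groups(d[1:5, ], group, value), "at least 2 groups")
  expect_error(
    compare_groups(tibble::tibble(group = c("a", "a", "b"), value = 1:3),
                   group, value), "at least 2 values")
})

test_that("Kruskal-Wallis and Dunn agree with base-R ranking on hand data", {
  # KW on untied data cross-checked against kruskal.test already; check the
  # Dunn z against a direct mean-rank computation
  d <- tibble::tibble(group = rep(c("a", "b"), each = 4), value = c(1, 3, 5, 7, 2, 4, 6, 8))
  dn <- dunn_test(d$value, d$group)
  r <- rank(d$value)
  z_hand <- (mean(r[1:4]) - mean(r[5:8])) /
    sqrt((8 * 9 / 12) * (1 / 4 + 1 / 4))
  expect_equal(dn$z, z_hand, tolerance = 1e-12)

  # reference-restricted comparisons re-adjust over the smaller family
  d3 <- tibble::tibble(group = rep(c("ctrl", "t1", "t2"), each = 5),
                       value = c(rnorm(5), rnorm(5, 3), rnorm(5, 6)))
  gcr <- compare_groups(d3, group, value, reference = "ctrl")
  expect_equal(nrow(tidy(gcr)), 2)
  expect_true(all(tidy(gcr)$group1 == "ctrl" | tidy(gcr)$group2 == "ctrl"))
})
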