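#' Assess a batch of stacks with one metric
#'
#' Maps [evaluate_stack()] over a list of z-stacks and binds the per-slice
#' metric plots into one tibble, ready for [score_regions()].
#'
#' @param stacks a list of [zstack] objects (or a single one).
#' @inheritParams evaluate_stack
#' @param ... passed on to [evaluate_stack()].
#' @return Tibble of per-slice metric values for all stacks.
#' @export
sqm_assess <- function(stacks, metric, ...) {
  if (inherits(stacks, "zstack")) stacks <- list(stacks)
  purrr::map(stacks, \(s) evaluate_stack(s, metric = metric, ...)) |>
    purrr::list_rbind()
}

#' Write region scores as CSV
#'
#' Columns `stack_id`, `region`, `score01`, `score15` (plus any identifying
#' columns present); `NA` scores become empty cells.
#'
#' @param scores tibble from [score_regions()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_scores <- function(scores, path) {
  readr::write_csv(tibble::as_tibble(unclass(scores)), path, na = "")
  invisible(path)
}
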