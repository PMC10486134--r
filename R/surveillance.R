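#' Species composition of a pooled mosquito collection
#'
#' Percentage composition of a field-collection tally, printed the way
#' surveillance reports state them: `100 * count / total`, rounded half-up to
#' one decimal. The denominator defaults to the sum of the supplied counts but
#' can be fixed to the full collection total when the tally covers only a
#' subset of taxa (e.g. a single dominant species against the whole catch).
#'
#' @param tally Data frame with columns `label` (species or genus) and
#'   `count` (nonnegative integers).
#' @param total Denominator; defaults to `sum(tally$count)`.
#' @return A tibble with columns `label`, `count`, `percentage` sorted by
#'   decreasing count.
#' @examples
#' composition(tibble::tibble(
#'   label = c("Culex", "Armigeres", "Anopheles", "Aedes"),
#'   count = c(17201, 10962, 3750, 264)
#' ))
#' @export
composition <- function(tally, total = NULL) {
  stopifnot(is.data.frame(tally), all(c("label", "count") %in% names(tally)))
  if (any(tally$count < 0)) stop("counts must be nonnegative")
  if (is.null(total)) total <- sum(tally$count)
  if (total <= 0) stop("total must be positive")
  tally |>
    tibble::as_tibble() |>
    dplyr::mutate(percentage = round_half_up(100 * .data$count / total, 1)) |>
    dplyr::arrange(dplyr::desc(.data$count))
}

#' Pool positivity rate
#'
#' Fraction of mosquito pools that yielded a virus-positive culture, as a
#' percentage rounded half-up to one decimal. This is the plain pool
#' positivity (isolation) rate; minimum-infection-rate estimators are out of
#' scope.
#'
#' @param n_positive Number of positive pools.
#' @param n_pools Total number of pools tested.
#' @return A single percentage.
#' @examples
#' positivity_rate(3, 200)  # 1.5
#' @export
positivity_rate <- function(n_positive, n_pools) {
  if (n_pools <= 0) stop("n_pools must be positive")
  if (n_positive < 0 || n_positive > n_pools) {
    stop("need 0 <= n_positive <= n_pools")
  }
  round_half_up(100 * n_positive / n_pools, 1)
}

#' Summarize a pool-level surveillance table
#'
#' Groups a per-pool record table and computes pools tested, pools positive
#' and the positivity percentage per group.
#'
#' @param pools Data frame with one row per pool; must contain a logical or
#'   0/1 column `positive`.
#' @param ... Grouping columns (tidy-select), e.g. `species`, `site`.
#' @return A tibble with `n_pools`, `n_positive` and `positivity` per group.
#' @export
summarize_pools <- function(pools, ...) {
  stopifnot(is.data.frame(pools), "positive" %in% names(pools))
  pools |>
    tibble::as_tibble() |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n_pools = dplyr::n(),
      n_positive = sum(as.logical(.data$positive)),
      .groups = "drop"
    ) |>
    dplyr::mutate(positivity = round_half_up(100 * .data$n_positive / .data$n_pools, 1))
}
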