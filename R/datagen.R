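#' Simulate a synthetic expert panel
#'
#' Generates per-expert Z-number risk assessments with the structure the
#' pipeline assumes: for every failure mode, objective, risk factor and
#' expert, a restriction TFN on the rating scale and a reliability TFN drawn
#' from the linguistic reliability vocabulary. The modal rating is uniform on
#' the scale; the left and right spreads are uniform on `spread_range` and
#' clipped to the scale bounds, matching the half-widths of the published
#' panel. Fully reproducible from `seed`.
#'
#' @param n_modes Number of failure modes (codes `M01`, `M02`, ...).
#' @param objectives Character vector of objective labels.
#' @param n_experts Number of experts on the panel.
#' @param scale Rating-scale bounds, default `c(1, 10)`.
#' @param spread_range Min and max half-width of the restriction TFNs.
#' @param reliability_vocabulary A linguistic scale tibble (`term`, `l`, `m`,
#'   `u`); defaults to the published five-term vocabulary.
#' @param seed Optional integer seed.
#' @return A tibble with one row per (mode, objective, factor, expert).
#' @examples
#' panel <- simulate_panel(n_modes = 3, n_experts = 2, seed = 1)
#' aggregate_experts(panel)
#' @export
simulate_panel <- function(n_modes = 21,
                           objectives = c("Delivery to Client", "Freight Cost"),
                           n_experts = 5, scale = c(1, 10),
                           spread_range = c(0.5, 2.5),
                           reliability_vocabulary = linguistic_scale_reliability(),
                           seed = NULL) {
  stopifnot(n_modes >= 1, n_experts >= 1, length(objectives) >= 1,
            scale[1] < scale[2], spread_range[1] >= 0,
            spread_range[1] <= spread_range[2])
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  grid <- tidyr::expand_grid(
    mode_code = sprintf("M%02d", seq_len(n_modes)),
    objective = objectives,
    factor = c("S", "O", "D"),
    expert = seq_len(n_experts))
  n <- nrow(grid)
  m <- stats::runif(n, scale[1], scale[2])
  dl <- stats::runif(n, spread_range[1], spread_range[2])
  du <- stats::runif(n, spread_range[1], spread_range[2])
  rel_idx <- sample.int(nrow(reliability_vocabulary), n, replace = TRUE)
  dplyr::bind_cols(grid, tibble::tibble(
    rl = pmax(m - dl, scale[1]), rm = m, ru = pmin(m + du, scale[2]),
    bl = reliability_vocabulary$l[rel_idx],
    bm = reliability_vocabulary$m[rel_idx],
    bu = reliability_vocabulary$u[rel_idx]))
}

#' Aggregate an expert panel into a consensus assessment
#'
#' Averages the restriction and reliability TFNs component-wise across
#' experts for every (mode, objective, factor) cell — the aggregation the
#' published panel reports. The mean of valid TFNs is a valid TFN, so no
#' re-sorting is needed. Every expert must cover every cell.
#'
#' @param panel A per-expert panel from [simulate_panel()] (or the same
#'   layout with an `expert` column).
#' @return A consensus assessment tibble, one row per (mode, objective,
#'   factor), validated by [as_assessments()].
#' @export
aggregate_experts <- function(panel) {
  p <- tibble::as_tibble(panel)
  cover <- p |>
    dplyr::count(.data$mode_code, .data$objective, .data$factor)
  if (length(unique(cover$n)) != 1 || any(cover$n != length(unique(p$expert)))) {
    bad <- cover[cover$n != max(cover$n), ]
    stop("incomplete expert coverage for cell ",
         paste(bad$mode_code[1], bad$objective[1], bad$factor[1]), call. = FALSE)
  }
  p |>
    dplyr::group_by(.data$mode_code, .data$objective, .data$factor) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("rl", "rm", "ru", "bl", "bm", "bu")),
                                   mean), .groups = "drop") |>
    as_assessments(scale_max = max(p$ru))
}
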