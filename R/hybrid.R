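#' Hybrid per-objective and combined risk scores
#'
#' The final prioritization blends the three views of each failure mode with
#' equal weight:
#'
#' * `norm_rpn` — the RPN middle value divided by the objective's maximum
#'   (the riskiest mode scores 1);
#' * `norm_k` — the combined WASPAS utility middle, min-max inverted within
#'   the objective (the lowest-K, i.e. riskiest, mode scores 1);
#' * `theta_norm` — the cap-normalized DEA super-efficiency.
#'
#' The per-objective hybrid score is `Q = (norm_rpn + norm_k + theta_norm)/3`
#' and the study-level score averages the two objectives with equal weight.
#' Normalization pools are per objective throughout; ties in any ranking
#' break lexicographically on the mode code.
#'
#' @param rpn A tibble `mode_code`, `objective`, `rpn_m` (or `rpn_middle`).
#' @param k A tibble `mode_code`, `objective`, `k_m`.
#' @param dea A tibble `mode_code`, `objective`, `theta_norm`.
#' @return `hybrid_scores()`: one row per mode and objective with the three
#'   normalized components, `q` and the per-objective `rank`.
#'   `combine_objectives()`: one row per mode with `q_total` and the overall
#'   `rank`.
#' @examples
#' h <- hybrid_scores(
#'   rpn = study_hybrid_rpn(), k = study_waspas(), dea = study_dea()
#' )
#' combine_objectives(h) |> head(3)
#' @export
hybrid_scores <- function(rpn, k, dea) {
  r <- tibble::as_tibble(rpn)
  if (!"rpn_m" %in% names(r) && "rpn_middle" %in% names(r)) {
    r$rpn_m <- r$rpn_middle
  }
  r <- dplyr::select(r, "mode_code", "objective", "rpn_m")
  kk <- dplyr::select(tibble::as_tibble(k), "mode_code", "objective", "k_m")
  dd <- dplyr::select(tibble::as_tibble(dea), "mode_code", "objective", "theta_norm")
  out <- r |>
    dplyr::inner_join(kk, by = c("mode_code", "objective")) |>
    dplyr::inner_join(dd, by = c("mode_code", "objective"))
  if (nrow(out) < nrow(r)) {
    stop("RPN, utility and efficiency tables do not cover the same (mode, objective) cells",
         call. = FALSE)
  }
  out <- out |>
    dplyr::group_by(.data$objective) |>
    dplyr::mutate(norm_rpn = normalize_rpn(.data$rpn_m),
                  norm_k = normalize_k(.data$k_m)) |>
    dplyr::ungroup() |>
    dplyr::mutate(q = (.data$norm_rpn + .data$norm_k + .data$theta_norm) / 3)
  out |>
    dplyr::group_by(.data$objective) |>
    dplyr::arrange(dplyr::desc(.data$q), .data$mode_code, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$objective, .data$mode_code) |>
    dplyr::select("mode_code", "objective", "norm_rpn", "norm_k", "theta_norm",
                  "q", "rank")
}

#' @rdname hybrid_scores
#' @param rpn_middles Numeric vector of RPN middle values for one
#'   normalization pool.
#' @export
normalize_rpn <- function(rpn_middles) {
  if (length(rpn_middles) == 0) stop("empty RPN pool", call. = FALSE)
  if (any(rpn_middles <= 0)) stop("RPN middles must be positive", call. = FALSE)
  rpn_middles / max(rpn_middles)
}

#' @rdname hybrid_scores
#' @param k_middles Numeric vector of combined-utility middle values for one
#'   normalization pool.
#' @export
normalize_k <- function(k_middles) {
  rng <- range(k_middles)
  if (rng[1] == rng[2]) {
    stop("all K middles are equal; the min-max inversion is undefined for a ",
         "degenerate spread", call. = FALSE)
  }
  1 - (k_middles - rng[1]) / (rng[2] - rng[1])
}

#' @rdname hybrid_scores
#' @param hybrid Output of `hybrid_scores()` covering every mode under every
#'   objective.
#' @param objective_weights Named or ordered numeric weights over the
#'   objectives (default equal; must sum to 1).
#' @export
combine_objectives <- function(hybrid, objective_weights = NULL) {
  h <- tibble::as_tibble(hybrid)
  objectives <- sort(unique(h$objective))
  if (is.null(objective_weights)) {
    objective_weights <- stats::setNames(rep(1 / length(objectives), length(objectives)),
                                         objectives)
  } else if (is.null(names(objective_weights))) {
    names(objective_weights) <- objectives
  }
  if (!setequal(names(objective_weights), objectives)) {
    stop("objective_weights must name every objective", call. = FALSE)
  }
  if (abs(sum(objective_weights) - 1) > 1e-8) {
    stop("objective_weights must sum to 1", call. = FALSE)
  }
  counts <- table(h$mode_code)
  if (any(counts != length(objectives))) {
    stop("mode ", names(counts)[counts != length(objectives)][1],
         " is not scored under every objective", call. = FALSE)
  }
  h |>
    dplyr::mutate(.w = objective_weights[.data$objective]) |>
    dplyr::group_by(.data$mode_code) |>
    dplyr::summarise(q_total = sum(.data$.w * .data$q), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$q_total), .data$mode_code) |>
    dplyr::mutate(rank = dplyr::row_number())
}
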