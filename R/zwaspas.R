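#' Weighted aggregated sum-product ranking (Z-WASPAS)
#'
#' Ranks failure modes per objective by blending a weighted sum model (WSM)
#' and a weighted product model (WPM) over the reliability-weighted S/O/D
#' decision matrix. All three criteria are non-beneficial (higher severity,
#' occurrence or detection-difficulty means more risk), so the matrix is
#' normalized criterion-wise against the per-component minimum; the least
#' risky mode then sits at (1, 1, 1) and riskier modes score below it. Lower
#' combined utility `K` therefore flags *higher* risk, and rank 1 is the mode
#' with the lowest `K` middle value.
#'
#' `waspas_normalize()`, `waspas_wsm()`, `waspas_wpm()` and
#' `waspas_combine()` expose the individual steps; `zwaspas()` chains them
#' from a raw assessment panel.
#'
#' @param matrix A tibble `mode_code`, `objective`, `criterion`, `l`, `m`,
#'   `u` of strictly positive decision values.
#' @param division Fuzzy division style for the normalization,
#'   `"componentwise"` (default; gives the exact (1,1,1) anchor) or
#'   `"inverted"`.
#' @return `waspas_normalize()` the matrix with normalized `l`, `m`, `u`;
#'   `waspas_wsm()`/`waspas_wpm()` one TFN row per mode and objective;
#'   `waspas_combine()` and `zwaspas()` the full result table with WSM, WPM
#'   and combined TFNs, their defuzzified means `q_bar`/`p_bar`, the crisp
#'   utility `k` and the risk rank.
#' @examples
#' zwaspas(study_assessments(), study_weights()) |> head()
#' @export
waspas_normalize <- function(matrix, division = c("componentwise", "inverted")) {
  division <- match.arg(division)
  if (any(matrix$l <= 0)) {
    stop("decision matrix entries must be strictly positive", call. = FALSE)
  }
  matrix |>
    dplyr::group_by(.data$objective, .data$criterion) |>
    dplyr::mutate(
      .h = tfn_divide(tfn(min(.data$l), min(.data$m), min(.data$u)),
                      tfn(.data$l, .data$m, .data$u), style = division)) |>
    dplyr::ungroup() |>
    dplyr::mutate(l = tfn_l(.data$.h), m = tfn_m(.data$.h), u = tfn_u(.data$.h)) |>
    dplyr::select(-".h")
}

join_weights <- function(matrix, weights) {
  w <- tibble::as_tibble(weights)
  if (!"objective" %in% names(w)) {
    w <- tidyr::crossing(objective = unique(matrix$objective), w)
  }
  out <- dplyr::inner_join(matrix, w, by = c("objective", "criterion"))
  if (nrow(out) != nrow(matrix)) {
    stop("weights do not cover every (objective, criterion) in the matrix",
         call. = FALSE)
  }
  out
}

#' @rdname waspas_normalize
#' @param weights A weight set: columns `criterion`, `w_l`, `w_m`, `w_u` and
#'   optionally `objective` (from [zswara()] or [study_weights()]).
#' @export
waspas_wsm <- function(matrix, weights) {
  join_weights(matrix, weights) |>
    dplyr::mutate(.t = tfn_product(tfn(.data$l, .data$m, .data$u),
                                   tfn(.data$w_l, .data$w_m, .data$w_u))) |>
    dplyr::group_by(.data$mode_code, .data$objective) |>
    dplyr::summarise(wsm_l = sum(tfn_l(.data$.t)), wsm_m = sum(tfn_m(.data$.t)),
                     wsm_u = sum(tfn_u(.data$.t)), .groups = "drop")
}

#' @rdname waspas_normalize
#' @export
waspas_wpm <- function(matrix, weights) {
  join_weights(matrix, weights) |>
    dplyr::mutate(.t = tfn_power(tfn(.data$l, .data$m, .data$u),
                                 tfn(.data$w_l, .data$w_m, .data$w_u))) |>
    dplyr::group_by(.data$mode_code, .data$objective) |>
    dplyr::summarise(wpm_l = prod(tfn_l(.data$.t)), wpm_m = prod(tfn_m(.data$.t)),
                     wpm_u = prod(tfn_u(.data$.t)), .groups = "drop")
}

#' @rdname waspas_normalize
#' @param scores A tibble with WSM and WPM TFN columns (`wsm_l` ... `wpm_u`),
#'   e.g. the output of the two model steps or a published stage table.
#' @param lambda Mixing weight on the WSM in \[0, 1\] (default 0.5).
#' @export
waspas_combine <- function(scores, lambda = 0.5) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    stop("lambda must be a single number in [0, 1]", call. = FALSE)
  }
  wsm <- tfn(scores$wsm_l, scores$wsm_m, scores$wsm_u)
  wpm <- tfn(scores$wpm_l, scores$wpm_m, scores$wpm_u)
  comb <- tfn_add(tfn_scale(wsm, lambda), tfn_scale(wpm, 1 - lambda))
  scores <- tibble::as_tibble(scores)
  scores <- scores[setdiff(names(scores),
                           c("k_l", "k_m", "k_u", "q_bar", "p_bar", "k", "rank"))]
  out <- dplyr::bind_cols(
    scores,
    tibble::tibble(k_l = tfn_l(comb), k_m = tfn_m(comb), k_u = tfn_u(comb),
                   q_bar = defuzzify(wsm), p_bar = defuzzify(wpm))
  )
  out$k <- lambda * out$q_bar + (1 - lambda) * out$p_bar
  out |>
    dplyr::group_by(.data$objective) |>
    dplyr::arrange(.data$k_m, .data$mode_code, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$objective, .data$mode_code)
}

#' @rdname waspas_normalize
#' @inheritParams z_convert
#' @param conversion Z-number conversion mode for building the decision
#'   matrix (default `"alpha"`).
#' @export
zwaspas <- function(assessments, weights, lambda = 0.5,
                    conversion = c("alpha", "sqrt_alpha"),
                    division = c("componentwise", "inverted")) {
  conversion <- match.arg(conversion)
  division <- match.arg(division)
  matrix <- z_convert(assessments, mode = conversion) |>
    dplyr::rename(criterion = "factor", l = "xl", m = "xm", u = "xu")
  norm <- waspas_normalize(matrix, division = division)
  scores <- dplyr::inner_join(waspas_wsm(norm, weights), waspas_wpm(norm, weights),
                              by = c("mode_code", "objective"))
  waspas_combine(scores, lambda = lambda)
}
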