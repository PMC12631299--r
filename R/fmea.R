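#' Validate an assessment panel
#'
#' An assessment panel is the long-format table of expert Z-number judgments:
#' one row per failure mode x objective x risk factor, with the restriction
#' TFN in `rl`, `rm`, `ru` (rating-scale units) and the reliability TFN in
#' `bl`, `bm`, `bu` (confined to \[0, 1\]). `as_assessments()` checks the
#' schema, the TFN orderings, the rating-scale bounds and the completeness of
#' the S/O/D triplets, and returns the validated tibble.
#'
#' @param x A data frame with columns `mode_code`, `objective`, `factor`
#'   (values `"S"`, `"O"`, `"D"`), `rl`, `rm`, `ru`, `bl`, `bm`, `bu`;
#'   `mode_name` is optional.
#' @param scale_max Upper bound of the rating scale (default 10).
#' @return A validated tibble.
#' @export
as_assessments <- function(x, scale_max = 10) {
  x <- tibble::as_tibble(x)
  needed <- c("mode_code", "objective", "factor", "rl", "rm", "ru", "bl", "bm", "bu")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("assessment table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0) stop("assessment table is empty", call. = FALSE)
  if (!all(x$factor %in% c("S", "O", "D"))) {
    stop("factor must be one of S, O, D", call. = FALSE)
  }
  key <- paste(x$mode_code, x$objective, x$factor)
  if (anyDuplicated(key)) {
    stop("duplicate row for ", key[anyDuplicated(key)], call. = FALSE)
  }
  check_order <- function(l, m, u, what) {
    bad <- which(!(l <= m & m <= u))
    if (length(bad)) {
      stop(sprintf("row %d (%s): %s TFN violates l <= m <= u", bad[1], key[bad[1]], what),
           call. = FALSE)
    }
  }
  check_order(x$rl, x$rm, x$ru, "restriction")
  check_order(x$bl, x$bm, x$bu, "reliability")
  if (any(x$rl < 0 | x$ru > scale_max)) {
    stop("restriction TFNs must lie within the rating scale [0, ", scale_max, "]",
         call. = FALSE)
  }
  if (any(x$bl < 0 | x$bu > 1)) {
    stop("reliability TFNs must lie within [0, 1]", call. = FALSE)
  }
  counts <- table(paste(x$mode_code, x$objective))
  if (any(counts != 3)) {
    stop("every (mode, objective) cell needs exactly the three factors S, O, D; ",
         "offending cell: ", names(counts)[counts != 3][1], call. = FALSE)
  }
  x
}

#' Convert a panel's Z-numbers to weighted TFNs
#'
#' Applies [z_to_tfn()] row-wise, yielding the reliability-weighted decision
#' matrix used by the weighting, ranking and efficiency stages.
#'
#' @param assessments An assessment panel (see [as_assessments()]).
#' @param mode Z-number conversion mode (see [z_to_tfn()]).
#' @return A tibble `mode_code`, `objective`, `factor`, `xl`, `xm`, `xu`.
#' @export
z_convert <- function(assessments, mode = c("alpha", "sqrt_alpha")) {
  mode <- match.arg(mode)
  a <- as_assessments(assessments)
  zz <- assessment_tfns(a)
  x <- z_to_tfn(zz$restriction, zz$reliability, mode = mode)
  tibble::tibble(mode_code = a$mode_code, objective = a$objective, factor = a$factor,
                 xl = tfn_l(x), xm = tfn_m(x), xu = tfn_u(x))
}

#' Fuzzy risk priority numbers
#'
#' The classical FMEA risk priority number, fuzzified: for each failure mode
#' and objective the severity, occurrence and detection TFNs are multiplied
#' component-wise, giving an RPN TFN in rating-cubed units. Following the
#' published tables, the product is taken over the *restriction* TFNs alone —
#' reliability is not folded in; set `use_reliability = TRUE` to apply the
#' Z-number conversion first.
#'
#' Modes are ranked within each objective in descending order of the RPN
#' ranking key (the middle component by default, the defuzzified mean as an
#' alternative); ties break lexicographically on the mode code.
#'
#' @inheritParams z_convert
#' @param use_reliability Apply [z_to_tfn()] before multiplying (default
#'   `FALSE`).
#' @param mode Conversion mode when `use_reliability = TRUE`.
#' @param key Ranking key: `"middle"` or `"mean"`.
#' @return A tibble `mode_code`, `objective`, `rpn_l`, `rpn_m`, `rpn_u`,
#'   `rank`.
#' @examples
#' compute_rpn(study_assessments()) |> dplyr::filter(rank == 1)
#' @export
compute_rpn <- function(assessments, use_reliability = FALSE,
                        mode = c("alpha", "sqrt_alpha"), key = c("middle", "mean")) {
  mode <- match.arg(mode)
  key <- match.arg(key)
  a <- as_assessments(assessments)
  if (use_reliability) {
    conv <- z_convert(a, mode = mode)
  } else {
    conv <- tibble::tibble(mode_code = a$mode_code, objective = a$objective,
                           factor = a$factor, xl = a$rl, xm = a$rm, xu = a$ru)
  }
  wide <- tidyr::pivot_wider(conv, names_from = "factor",
                             values_from = c("xl", "xm", "xu"))
  rpn <- tfn_product(tfn_product(tfn(wide$xl_S, wide$xm_S, wide$xu_S),
                                 tfn(wide$xl_O, wide$xm_O, wide$xu_O)),
                     tfn(wide$xl_D, wide$xm_D, wide$xu_D))
  out <- tibble::tibble(mode_code = wide$mode_code, objective = wide$objective,
                        rpn_l = tfn_l(rpn), rpn_m = tfn_m(rpn), rpn_u = tfn_u(rpn))
  rank_by_rpn(out, key = key)
}

#' @rdname compute_rpn
#' @param rpn A tibble with `mode_code`, `objective`, `rpn_l`, `rpn_m`,
#'   `rpn_u` columns, e.g. from `compute_rpn()`.
#' @export
rank_by_rpn <- function(rpn, key = c("middle", "mean")) {
  key <- match.arg(key)
  if (nrow(rpn) == 0) stop("no RPN rows to rank", call. = FALSE)
  rpn |>
    dplyr::group_by(.data$objective) |>
    dplyr::arrange(
      dplyr::desc(if (key == "middle") .data$rpn_m
                  else (.data$rpn_l + .data$rpn_m + .data$rpn_u) / 3),
      .data$mode_code, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$objective, .data$mode_code)
}
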