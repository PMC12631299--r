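#' Z-number handling
#'
#' A Z-number is an ordered pair of fuzzy numbers: a *restriction* TFN on the
#' rating scale (the judged value) and a *reliability* TFN confined to
#' \[0, 1\] (the expert's confidence in that value). The pipeline stores
#' Z-numbers as two `tfn` columns; these helpers collapse the reliability into
#' a crisp weight and fold it into the restriction.
#'
#' `reliability_alpha()` is the centroid of a triangular reliability
#' component, which simplifies to the component mean `(l + m + u) / 3`.
#'
#' `z_to_tfn()` converts a Z-number to a single weighted TFN. Two scalings are
#' in use in the literature and both occur in the study this package
#' reproduces:
#'
#' * `mode = "alpha"` multiplies the restriction by the centroid weight
#'   `alpha` itself — the convention the numeric risk pipeline (input
#'   averages, decision matrices) follows;
#' * `mode = "sqrt_alpha"` multiplies by `sqrt(alpha)` — the Kang-style
#'   conversion the linguistic weighting table follows.
#'
#' Every stage that converts Z-numbers takes the mode as configuration.
#'
#' @param restriction A `tfn` vector of judged values.
#' @param reliability A `tfn` vector with all components in \[0, 1\].
#' @param mode Scaling convention, `"alpha"` or `"sqrt_alpha"`.
#' @return `reliability_alpha()` a numeric vector in (0, 1\];
#'   `z_to_tfn()` a `tfn` vector.
#' @examples
#' reliability_alpha(tfn(0.35, 0.5, 0.75)) # 0.5333
#' z_to_tfn(tfn(2, 3.8, 5.5), tfn(0.5, 0.7, 0.9), mode = "alpha")
#' @export
reliability_alpha <- function(reliability) {
  stopifnot(is_tfn(reliability))
  if (any(tfn_l(reliability) < 0) || any(tfn_u(reliability) > 1)) {
    stop("reliability TFN components must lie in [0, 1]", call. = FALSE)
  }
  alpha <- defuzzify(reliability)
  if (any(alpha == 0)) {
    stop("all-zero reliability gives alpha = 0, which would annihilate the restriction",
         call. = FALSE)
  }
  alpha
}

#' @rdname reliability_alpha
#' @export
z_to_tfn <- function(restriction, reliability, mode = c("alpha", "sqrt_alpha")) {
  mode <- match.arg(mode)
  v <- vctrs::vec_recycle_common(restriction = restriction, reliability = reliability)
  alpha <- reliability_alpha(v$reliability)
  if (mode == "sqrt_alpha") alpha <- sqrt(alpha)
  tfn_scale(v$restriction, alpha)
}

#' @rdname parse_tfn
#' @export
format_znumber <- function(restriction, reliability, digits = 3) {
  sprintf("[%s, %s]", format_tfn(restriction, digits), format_tfn(reliability, digits))
}

# Z-number columns (rl, rm, ru, bl, bm, bu) of an assessment tibble -> tfn pair
assessment_tfns <- function(df) {
  list(restriction = tfn(df$rl, df$rm, df$ru), reliability = tfn(df$bl, df$bm, df$bu))
}
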