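#' Linguistic scales for criterion weighting
#'
#' The stepwise weighting stage elicits, for each criterion after the most
#' important one, a linguistic judgment of how much *less* important it is
#' than its predecessor, together with a linguistic reliability grade. Three
#' published vocabularies are bundled:
#'
#' * `linguistic_scale_importance()` — the five comparative-importance terms
#'   (EI equality, MOL modestly less, LI least, VLI very low, MUL much less
#'   important) with their TFNs;
#' * `linguistic_scale_reliability()` — the five reliability grades (VW, W, M,
#'   H, VH) as TFNs on \[0, 1\];
#' * `linguistic_scale_comparison()` — the increasing importance ladder (EI,
#'   WI, FI, VI, AI) used when judgments are expressed as direct comparative
#'   strength rather than step-down ratios.
#'
#' @return A tibble with columns `term`, `l`, `m`, `u`.
#' @examples
#' linguistic_scale_importance()
#' @export
linguistic_scale_importance <- function() {
  tibble::tribble(
    ~term, ~l, ~m, ~u,
    "EI", 1, 1, 1,
    "MOL", 2 / 3, 1, 3 / 2,
    "LI", 2 / 5, 1 / 2, 2 / 3,
    "VLI", 2 / 7, 1 / 3, 2 / 5,
    "MUL", 2 / 9, 1 / 4, 2 / 7
  )
}

#' @rdname linguistic_scale_importance
#' @export
linguistic_scale_reliability <- function() {
  tibble::tribble(
    ~term, ~l, ~m, ~u,
    "VW", 0, 0, 0.25,
    "W", 0.2, 0.35, 0.5,
    "M", 0.35, 0.5, 0.75,
    "H", 0.5, 0.75, 0.9,
    "VH", 0.75, 1, 1
  )
}

#' @rdname linguistic_scale_importance
#' @export
linguistic_scale_comparison <- function() {
  tibble::tribble(
    ~term, ~l, ~m, ~u,
    "EI", 1, 1, 1,
    "WI", 2 / 3, 1, 3 / 2,
    "FI", 3 / 2, 2, 5 / 2,
    "VI", 5 / 2, 3, 7 / 2,
    "AI", 7 / 2, 4, 9 / 2
  )
}

scale_lookup <- function(terms, scale, what) {
  idx <- match(terms, scale$term)
  if (anyNA(idx)) {
    stop(sprintf("unknown %s term '%s'; valid terms: %s",
                 what, terms[which(is.na(idx))[1]],
                 paste(scale$term, collapse = ", ")), call. = FALSE)
  }
  tfn(scale$l[idx], scale$m[idx], scale$u[idx])
}

#' Convert a linguistic Z-number judgment to a weighted TFN
#'
#' Looks up the importance and reliability terms in their scales and applies
#' the `sqrt_alpha` Z-number conversion (the convention under which the
#' published linguistic conversion table reproduces). The equal-importance
#' anchor — any importance term whose TFN is (1, 1, 1) — is returned
#' unchanged, matching the published table where every (EI, *) pair maps to
#' (1, 1, 1) regardless of reliability.
#'
#' @param importance,reliability Character vectors of scale terms.
#' @param importance_scale,reliability_scale Scale tibbles
#'   (`term`, `l`, `m`, `u`); defaults are the published vocabularies.
#' @return A `tfn` vector.
#' @examples
#' linguistic_to_tfn("VLI", "M") # ~ (0.21, 0.24, 0.29)
#' @export
linguistic_to_tfn <- function(importance, reliability,
                              importance_scale = linguistic_scale_importance(),
                              reliability_scale = linguistic_scale_reliability()) {
  imp <- scale_lookup(importance, importance_scale, "importance")
  rel <- scale_lookup(reliability, reliability_scale, "reliability")
  out <- z_to_tfn(imp, rel, mode = "sqrt_alpha")
  anchor <- tfn_l(imp) == 1 & tfn_m(imp) == 1 & tfn_u(imp) == 1
  if (any(anchor)) out[anchor] <- imp[anchor]
  out
}

#' Stepwise criterion weights (Z-SWARA)
#'
#' Given criteria ranked from most to least important, with a comparative
#' step-down TFN `s_j` for each criterion after the first,
#' `swara_coefficients()` runs the stepwise recursion
#' `q_1 = (1,1,1)`, `q_j = q_{j-1} / (s_j + 1)`, and `swara_weights()`
#' normalizes the coefficients into final weights `w_j = q_j / sum(q_j)`.
#' Because `s_j + 1 >= 1` component-wise, coefficients — and hence weights —
#' are non-increasing down the ranked order.
#'
#' The published recursion formula reads literally as
#' `q_j = s_j / s_{j-1} + 1`, which would make coefficients grow down the
#' ranking, contradicting both the method's semantics and the published
#' decreasing weights; it is available for audit via
#' `recursion = "as_printed"` (with `s_1 = (1,1,1)`).
#'
#' @param judgments A data frame with columns `criterion`, `position`
#'   (1 = most important, contiguous) and the comparison TFN columns `sl`,
#'   `sm`, `su` (`NA` for position 1). An optional `objective` column groups
#'   independent weightings.
#' @param division Fuzzy division style for the recursion and normalization.
#' @param recursion `"standard"` (default) or `"as_printed"`.
#' @return A tibble with one row per criterion: the stepwise coefficient
#'   (`q_l`, `q_m`, `q_u`) and, for `swara_weights()` / `zswara()`, the final
#'   weight (`w_l`, `w_m`, `w_u`).
#' @examples
#' j <- tibble::tibble(
#'   criterion = c("S", "O", "D"), position = 1:3,
#'   sl = c(NA, 0.4, 0.3), sm = c(NA, 0.4, 0.3), su = c(NA, 0.4, 0.3)
#' )
#' zswara(j)
#' @export
swara_coefficients <- function(judgments, division = c("inverted", "componentwise"),
                               recursion = c("standard", "as_printed")) {
  division <- match.arg(division)
  recursion <- match.arg(recursion)
  j <- dplyr::arrange(tibble::as_tibble(judgments), .data$position)
  if (!identical(j$position, seq_len(nrow(j)))) {
    stop("judgment positions must be contiguous from 1", call. = FALSE)
  }
  if (nrow(j) > 1 && anyNA(c(j$sl[-1], j$sm[-1], j$su[-1]))) {
    stop("every criterion after position 1 needs a comparison TFN", call. = FALSE)
  }
  one <- tfn(1, 1, 1)
  q <- vctrs::vec_init(one, nrow(j))
  q[1] <- one
  if (nrow(j) > 1) {
    s <- tfn(c(1, j$sl[-1]), c(1, j$sm[-1]), c(1, j$su[-1])) # s_1 unused anchor
    for (i in seq(2, nrow(j))) {
      if (recursion == "standard") {
        k <- tfn_add(s[i], one)
        q[i] <- tfn_divide(q[i - 1], k, style = division)
      } else {
        q[i] <- tfn_add(tfn_divide(s[i], s[i - 1], style = division), one)
      }
    }
  }
  dplyr::bind_cols(j[setdiff(names(j), c("sl", "sm", "su"))],
                   tibble::tibble(q_l = tfn_l(q), q_m = tfn_m(q), q_u = tfn_u(q)))
}

#' @rdname swara_coefficients
#' @param coefficients Output of `swara_coefficients()`.
#' @export
swara_weights <- function(coefficients, division = c("inverted", "componentwise")) {
  division <- match.arg(division)
  q <- tfn(coefficients$q_l, coefficients$q_m, coefficients$q_u)
  total <- tfn(sum(tfn_l(q)), sum(tfn_m(q)), sum(tfn_u(q)))
  w <- tfn_divide(q, total, style = division)
  dplyr::bind_cols(tibble::as_tibble(coefficients),
                   tibble::tibble(w_l = tfn_l(w), w_m = tfn_m(w), w_u = tfn_u(w)))
}

#' @rdname swara_coefficients
#' @details
#' `zswara()` is the user-facing wrapper: it accepts either numeric
#' comparison TFNs (`sl`, `sm`, `su`) or linguistic columns
#' (`importance_term`, `reliability_term`, converted through
#' [linguistic_to_tfn()]), runs the recursion per objective, and returns the
#' weight set.
#' @export
zswara <- function(judgments, division = c("inverted", "componentwise"),
                   recursion = c("standard", "as_printed")) {
  division <- match.arg(division)
  recursion <- match.arg(recursion)
  j <- tibble::as_tibble(judgments)
  if (!all(c("sl", "sm", "su") %in% names(j))) {
    if (!all(c("importance_term", "reliability_term") %in% names(j))) {
      stop("judgments need either sl/sm/su or importance_term/reliability_term columns",
           call. = FALSE)
    }
    first <- j$position == 1
    j$sl <- NA_real_
    j$sm <- NA_real_
    j$su <- NA_real_
    if (any(!first)) {
      s <- linguistic_to_tfn(j$importance_term[!first], j$reliability_term[!first])
      j$sl[!first] <- tfn_l(s)
      j$sm[!first] <- tfn_m(s)
      j$su[!first] <- tfn_u(s)
    }
  }
  if (!"objective" %in% names(j)) j$objective <- "overall"
  out <- j |>
    dplyr::group_by(.data$objective) |>
    dplyr::group_modify(function(g, key) {
      swara_weights(swara_coefficients(g, division = division, recursion = recursion),
                    division = division)
    }) |>
    dplyr::ungroup()
  out
}
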