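#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) is the triple (l, m, u) with
#' `l <= m <= u`: membership rises linearly from the lower support `l` to the
#' mode `m` and falls to the upper support `u`. TFNs are the basic quantity of
#' every stage of the risk-prioritization pipeline; they are implemented as a
#' vctrs record class so a TFN column travels inside an ordinary tibble.
#'
#' @param l,m,u Numeric vectors (recycled to common length) holding the lower,
#'   modal and upper support values. All must be finite and satisfy
#'   `l <= m <= u` element-wise.
#' @return A `tfn` vector.
#' @examples
#' tfn(2, 3.8, 5.5)
#' defuzzify(tfn(2, 3.8, 5.5))
#' @export
tfn <- function(l, m, u) {
  args <- vctrs::vec_recycle_common(l = as.double(l), m = as.double(m), u = as.double(u))
  bad <- !is.finite(args$l) | !is.finite(args$m) | !is.finite(args$u)
  if (any(bad)) {
    stop("TFN components must be finite numbers (offending element ",
         which(bad)[1], ")", call. = FALSE)
  }
  viol <- args$l > args$m | args$m > args$u
  if (any(viol)) {
    i <- which(viol)[1]
    stop(sprintf("TFN ordering l <= m <= u violated at element %d: (%g, %g, %g)",
                 i, args$l[i], args$m[i], args$u[i]), call. = FALSE)
  }
  new_tfn(args$l, args$m, args$u)
}

new_tfn <- function(l = double(), m = double(), u = double()) {
  vctrs::new_rcrd(list(l = l, m = m, u = u), class = "zfmea_tfn")
}

#' @export
format.zfmea_tfn <- function(x, ..., digits = 4) {
  sprintf("(%s, %s, %s)",
          formatC(tfn_l(x), digits = digits, format = "fg"),
          formatC(tfn_m(x), digits = digits, format = "fg"),
          formatC(tfn_u(x), digits = digits, format = "fg"))
}

#' @export
vec_ptype_abbr.zfmea_tfn <- function(x, ...) "tfn"

#' @export
vec_ptype2.zfmea_tfn.zfmea_tfn <- function(x, y, ...) new_tfn()

#' @export
vec_cast.zfmea_tfn.zfmea_tfn <- function(x, to, ...) x

#' Test for and access TFN components
#'
#' @param x A `tfn` vector.
#' @return `tfn_l()`, `tfn_m()` and `tfn_u()` return the numeric component
#'   vectors; `is_tfn()` returns a logical scalar.
#' @export
is_tfn <- function(x) inherits(x, "zfmea_tfn")

#' @rdname is_tfn
#' @export
tfn_l <- function(x) vctrs::field(x, "l")

#' @rdname is_tfn
#' @export
tfn_m <- function(x) vctrs::field(x, "m")

#' @rdname is_tfn
#' @export
tfn_u <- function(x) vctrs::field(x, "u")

#' Defuzzify a TFN by the simple average
#'
#' Collapses each TFN to the arithmetic mean of its three components,
#' `(l + m + u) / 3`. This is the single defuzzification rule used throughout
#' the pipeline (input averages, utility means, reliability centroids).
#'
#' @param x A `tfn` vector.
#' @return A numeric vector.
#' @examples
#' defuzzify(tfn(0.209, 0.293, 0.507)) # 0.3363...
#' @export
defuzzify <- function(x) {
  stopifnot(is_tfn(x))
  (tfn_l(x) + tfn_m(x) + tfn_u(x)) / 3
}

#' TFN interval arithmetic
#'
#' Component-wise operations on triangular fuzzy numbers. Addition and
#' positive scaling are exact interval arithmetic; multiplication is the usual
#' component-wise approximation valid for non-negative operands. Division and
#' exponentiation are not uniquely defined for TFNs, so both expose the
#' conventions used by the pipeline:
#'
#' * `tfn_divide(style = "inverted")` returns `(l1/u2, m1/m2, u1/l2)`, the
#'   standard fuzzy division, which always preserves ordering.
#' * `tfn_divide(style = "componentwise")` divides matching components and
#'   re-sorts ascending to restore a valid TFN.
#' * `tfn_power()` raises matching components (`l^wl`, `m^wm`, `u^wu`) and
#'   re-sorts; re-sorting matters for bases below 1, where a larger exponent
#'   shrinks the value.
#'
#' @param a,b,w `tfn` vectors (recycled to a common length).
#' @param c A non-negative numeric scaling factor.
#' @param style Fuzzy division convention, `"inverted"` or `"componentwise"`.
#' @return A `tfn` vector.
#' @examples
#' tfn_product(tfn(2, 3.8, 5.5), tfn(3, 4.8, 6))
#' tfn_divide(tfn(1, 2, 3), tfn(2, 4, 6), style = "inverted")
#' @export
tfn_add <- function(a, b) {
  v <- vctrs::vec_recycle_common(a = a, b = b)
  tfn(tfn_l(v$a) + tfn_l(v$b), tfn_m(v$a) + tfn_m(v$b), tfn_u(v$a) + tfn_u(v$b))
}

#' @rdname tfn_add
#' @export
tfn_scale <- function(a, c) {
  stopifnot(is_tfn(a))
  c <- vctrs::vec_recycle(as.double(c), length(a))
  if (any(c < 0)) stop("tfn_scale() requires a non-negative scalar", call. = FALSE)
  tfn(tfn_l(a) * c, tfn_m(a) * c, tfn_u(a) * c)
}

#' @rdname tfn_add
#' @export
tfn_product <- function(a, b) {
  v <- vctrs::vec_recycle_common(a = a, b = b)
  if (any(tfn_l(v$a) < 0) || any(tfn_l(v$b) < 0)) {
    stop("tfn_product() requires non-negative operands", call. = FALSE)
  }
  tfn(tfn_l(v$a) * tfn_l(v$b), tfn_m(v$a) * tfn_m(v$b), tfn_u(v$a) * tfn_u(v$b))
}

#' @rdname tfn_add
#' @export
tfn_divide <- function(a, b, style = c("inverted", "componentwise")) {
  style <- match.arg(style)
  v <- vctrs::vec_recycle_common(a = a, b = b)
  if (any(tfn_l(v$b) <= 0)) {
    stop("tfn_divide() requires a strictly positive divisor", call. = FALSE)
  }
  if (style == "inverted") {
    tfn(tfn_l(v$a) / tfn_u(v$b), tfn_m(v$a) / tfn_m(v$b), tfn_u(v$a) / tfn_l(v$b))
  } else {
    tfn_sorted(tfn_l(v$a) / tfn_l(v$b), tfn_m(v$a) / tfn_m(v$b), tfn_u(v$a) / tfn_u(v$b))
  }
}

#' @rdname tfn_add
#' @export
tfn_power <- function(a, w) {
  v <- vctrs::vec_recycle_common(a = a, w = w)
  if (any(tfn_l(v$a) <= 0)) {
    stop("tfn_power() requires a strictly positive base", call. = FALSE)
  }
  tfn_sorted(tfn_l(v$a)^tfn_l(v$w), tfn_m(v$a)^tfn_m(v$w), tfn_u(v$a)^tfn_u(v$w))
}

# build a tfn from three candidate component vectors, sorting each triple
tfn_sorted <- function(x, y, z) {
  mat <- cbind(x, y, z)
  srt <- t(apply(mat, 1, sort))
  tfn(srt[, 1], srt[, 2], srt[, 3])
}

#' Parse and format paper-style TFN strings
#'
#' The study tables print TFNs as the literal string `"(l, m, u)"` with a
#' period decimal separator. `parse_tfn()` reads that dialect; `format_tfn()`
#' writes it at a chosen precision.
#'
#' @param x For `parse_tfn()`, a character vector of `"(l, m, u)"` strings;
#'   for `format_tfn()`, a `tfn` vector.
#' @param digits Number of decimal places for formatting.
#' @return `parse_tfn()` a `tfn` vector; `format_tfn()` a character vector.
#' @examples
#' parse_tfn("(24.00, 109.44, 264.00)")
#' format_tfn(tfn(1 / 3, 0.5, 2 / 3), digits = 2)
#' @export
parse_tfn <- function(x) {
  m <- regmatches(x, gregexpr("-?[0-9.]+", x))
  bad <- lengths(m) != 3
  if (any(bad)) {
    stop("cannot parse TFN string: ", x[which(bad)[1]], call. = FALSE)
  }
  num <- vapply(m, as.numeric, numeric(3))
  tfn(num[1, ], num[2, ], num[3, ])
}

#' @rdname parse_tfn
#' @export
format_tfn <- function(x, digits = 3) {
  fmt <- paste0("%.", digits, "f")
  sprintf("(%s, %s, %s)", sprintf(fmt, tfn_l(x)), sprintf(fmt, tfn_m(x)),
          sprintf(fmt, tfn_u(x)))
}
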