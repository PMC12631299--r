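# Independent oracles used across the suite.

# random valid TFN vector
rand_tfn <- function(n, lo = 0.1, hi = 10) {
  a <- matrix(runif(3 * n, lo, hi), ncol = 3)
  s <- t(apply(a, 1, sort))
  tfn(s[, 1], s[, 2], s[, 3])
}

expect_max_abs_diff <- function(actual, expected, tol) {
  expect_lte(max(abs(actual - expected)), tol)
}

expect_tfn_ordered <- function(x) {
  expect_true(all(tfn_l(x) <= tfn_m(x) + 1e-12 & tfn_m(x) <= tfn_u(x) + 1e-12))
}

# crisp SWARA recursion (plain scalar arithmetic)
crisp_swara <- function(s) { # s: step-down ratios for criteria 2..n
  q <- cumprod(c(1, 1 / (s + 1)))
  list(q = q, w = q / sum(q))
}

# brute-force VRS input-oriented efficiency: enumerate basic solutions of the
# standard-form system (theta, lambda, 3 slacks; 4 rows)
dea_input_bruteforce <- function(x_ref, y_ref, xt, yt) {
  n <- length(y_ref)
  M <- rbind(c(0, rep(1, n), 0, 0, 0),
             c(0, y_ref, -1, 0, 0),
             c(xt[1], -x_ref[, 1], 0, -1, 0),
             c(xt[2], -x_ref[, 2], 0, 0, -1))
  rhs <- c(1, yt, 0, 0)
  best <- Inf
  for (cols in utils::combn(ncol(M), 4, simplify = FALSE)) {
    B <- M[, cols, drop = FALSE]
    if (abs(det(B)) < 1e-12) next
    z <- rep(0, ncol(M))
    z[cols] <- solve(B, rhs)
    if (all(z >= -1e-9)) best <- min(best, z[1])
  }
  best
}

# tiny valid assessment panel (2 modes x 1 objective), crisp-friendly
toy_assessments <- function() {
  tibble::tibble(
    mode_code = rep(c("M01", "M02"), each = 3),
    objective = "obj",
    factor = rep(c("S", "O", "D"), 2),
    rl = c(2, 3, 4, 4, 5, 6), rm = c(2, 3, 4, 4, 5, 6), ru = c(2, 3, 4, 4, 5, 6),
    bl = 1, bm = 1, bu = 1)
}
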