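test_that("linguistic Z-numbers convert per the published weighting table", {
  expect_equal(round(unlist(vctrs::vec_data(linguistic_to_tfn("VLI", "M"))), 2),
               c(l = 0.21, m = 0.24, u = 0.29))
  expect_equal(round(unlist(vctrs::vec_data(linguistic_to_tfn("MOL", "W"))), 2),
               c(l = 0.39, m = 0.59, u = 0.89))
  # the equal-importance anchor ignores reliability
  for (r in c("VW", "W", "M", "H", "VH")) {
    expect_equal(linguistic_to_tfn("EI", r), tfn(1, 1, 1))
  }
  expect_error(linguistic_to_tfn("XX", "M"), "EI, MOL, LI, VLI, MUL")
})

test_that("stepwise coefficients follow the standard recursion", {
  j <- tibble::tibble(criterion = "S", position = 1L,
                      sl = NA_real_, sm = NA_real_, su = NA_real_)
  expect_equal(swara_coefficients(j)[, c("q_l", "q_m", "q_u")],
               tibble::tibble(q_l = 1, q_m = 1, q_u = 1))
  j3 <- tibble::tibble(
    criterion = c("S", "O", "D"), position = 1:3,
    sl = c(NA, 0.4, 0.3), sm = c(NA, 0.4, 0.3), su = c(NA, 0.4, 0.3))
  q <- swara_coefficients(j3)
  expect_equal(q$q_m, c(1, 1 / 1.4, 1 / 1.4 / 1.3), tolerance = 1e-12)
  expect_error(swara_coefficients(dplyr::mutate(j3, position = c(1L, 3L, 4L))),
               "contiguous")
  expect_error(swara_coefficients(dplyr::mutate(j3, sl = NA_real_)), "comparison TFN")
})

test_that("crisp degenerate weighting matches the scalar oracle exactly", {
  set.seed(11)
  for (i in 1:10) {
    s <- runif(sample(1:4, 1), 0.1, 1)
    j <- tibble::tibble(
      criterion = paste0("c", seq_len(length(s) + 1)),
      position = seq_len(length(s) + 1),
      sl = c(NA, s), sm = c(NA, s), su = c(NA, s))
    got <- zswara(j)
    oracle <- crisp_swara(s)
    expect_equal(got$q_m, oracle$q, tolerance = 1e-12)
    expect_equal(got$w_m, oracle$w, tolerance = 1e-12)
    expect_equal(sum(got$w_m), 1, tolerance = 1e-12)
  }
})

test_that("weights are positive and non-increasing down the ranked order", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(2:5, 1)
    s <- rand_tfn(n - 1, 0.2, 1.2)
    j <- tibble::tibble(
      criterion = paste0("c", 1:n), position = 1:n,
      sl = c(NA, tfn_l(s)), sm = c(NA, tfn_m(s)), su = c(NA, tfn_u(s)))
    w <- zswara(j)
    expect_true(all(w$w_l > 0))
    expect_true(all(diff(w$w_m[order(w$position)]) <= 1e-12))
  }
})

test_that("linguistic judgments flow through the wrapper per objective", {
  j <- tibble::tibble(
    objective = rep(c("a", "b"), each = 3),
    criterion = rep(c("S", "O", "D"), 2), position = rep(1:3, 2),
    importance_term = c(NA, "LI", "VLI", NA, "MOL", "LI"),
    reliability_term = c(NA, "H", "M", NA, "VH", "W"))
  w <- zswara(j)
  expect_equal(nrow(w), 6)
  expect_true(all(c("q_l", "w_m") %in% names(w)))
  # position-1 criterion carries the largest middle weight in each objective
  top <- w |> dplyr::group_by(objective) |> dplyr::slice_max(w_m, n = 1)
  expect_equal(sort(unique(top$position)), 1L)
})

test_that("the printed recursion variant grows rather than shrinks", {
  j3 <- tibble::tibble(
    criterion = c("S", "O", "D"), position = 1:3,
    sl = c(NA, 0.4, 0.3), sm = c(NA, 0.4, 0.3), su = c(NA, 0.4, 0.3))
  q <- swara_coefficients(j3, recursion = "as_printed")
  expect_true(all(q$q_m[-1] > 1)) # s_j/s_{j-1} + 1 > 1: not a step-down weighting
})
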