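make_matrix <- function(df) {
  tibble::as_tibble(df)
}

test_that("normalization anchors the least risky mode at (1,1,1)", {
  m <- tibble::tibble(
    mode_code = c("A", "B"), objective = "o", criterion = "S",
    l = c(1, 2), m = c(2, 4), u = c(3, 6))
  cw <- waspas_normalize(m, division = "componentwise")
  expect_equal(unlist(cw[cw$mode_code == "A", c("l", "m", "u")], use.names = FALSE),
               c(1, 1, 1))
  expect_equal(unlist(cw[cw$mode_code == "B", c("l", "m", "u")], use.names = FALSE),
               c(0.5, 0.5, 0.5))
  inv <- waspas_normalize(m, division = "inverted")
  expect_equal(unlist(inv[inv$mode_code == "B", c("l", "m", "u")], use.names = FALSE),
               c(1 / 6, 1 / 2, 3 / 2))
  # identical rows all map to the anchor
  same <- dplyr::mutate(m, l = 2, m = 3, u = 4)
  ncw <- waspas_normalize(same)
  expect_true(all(ncw$l == 1 & ncw$m == 1 & ncw$u == 1))
  expect_error(waspas_normalize(dplyr::mutate(m, l = 0)), "positive")
})

test_that("normalization leaves a matrix with a unit anchor row fixed at that row", {
  # normalizing a matrix whose component-wise minima form the anchor (1,1,1)
  # maps the anchor to itself; general idempotence does not hold for min/h
  m <- tibble::tibble(
    mode_code = c("A", "B", "C"), objective = "o", criterion = "S",
    l = c(1, 2, 4), m = c(1, 3, 5), u = c(1, 4, 6))
  n1 <- waspas_normalize(m, "componentwise")
  expect_equal(unlist(n1[n1$mode_code == "A", c("l", "m", "u")], use.names = FALSE),
               c(1, 1, 1))
})

test_that("WSM and WPM match crisp scalar oracles on degenerate inputs", {
  w <- tibble::tibble(criterion = c("S", "O", "D"),
                      w_l = c(0.5, 0.3, 0.2), w_m = c(0.5, 0.3, 0.2),
                      w_u = c(0.5, 0.3, 0.2))
  set.seed(41)
  vals <- matrix(runif(6, 0.2, 1), nrow = 2)
  m <- tibble::tibble(
    mode_code = rep(c("A", "B"), each = 3), objective = "o",
    criterion = rep(c("S", "O", "D"), 2),
    l = as.vector(t(vals)), m = as.vector(t(vals)), u = as.vector(t(vals)))
  wsm <- waspas_wsm(m, w)
  wpm <- waspas_wpm(m, w)
  for (i in 1:2) {
    expect_equal(wsm$wsm_m[i], sum(vals[i, ] * c(0.5, 0.3, 0.2)), tolerance = 1e-12)
    expect_equal(wpm$wpm_m[i], prod(vals[i, ]^c(0.5, 0.3, 0.2)), tolerance = 1e-12)
  }
  # weighted AM-GM: WSM >= WPM when crisp weights sum to 1
  expect_true(all(wsm$wsm_m >= wpm$wpm_m))
})

test_that("the weight sum bounds the WSM of the all-anchor matrix", {
  w <- study_weights()
  m <- tidyr::crossing(mode_code = "A", objective = unique(w$objective),
                       criterion = c("S", "O", "D")) |>
    dplyr::mutate(l = 1, m = 1, u = 1)
  wsm <- waspas_wsm(m, w)
  del <- wsm[wsm$objective == "Delivery to Client", ]
  expect_equal(c(del$wsm_l, del$wsm_m, del$wsm_u), c(0.94, 1.07, 1.22))
  wpm <- waspas_wpm(m, w)
  expect_equal(c(wpm$wpm_l[1], wpm$wpm_m[1], wpm$wpm_u[1]), c(1, 1, 1))
})

test_that("combination mixes WSM and WPM linearly in lambda", {
  s <- tibble::tibble(
    mode_code = "F01", objective = "Delivery to Client",
    wsm_l = 0.264, wsm_m = 0.311, wsm_u = 0.472,
    wpm_l = 0.153, wpm_m = 0.276, wpm_u = 0.541)
  half <- waspas_combine(s, lambda = 0.5)
  expect_equal(c(half$k_l, half$k_m, half$k_u), c(0.2085, 0.2935, 0.5065))
  expect_equal(half$k, 0.5 * half$q_bar + 0.5 * half$p_bar)
  one <- waspas_combine(s, lambda = 1)
  expect_equal(c(one$k_l, one$k_m, one$k_u), c(s$wsm_l, s$wsm_m, s$wsm_u))
  # midpoint property
  zero <- waspas_combine(s, lambda = 0)
  expect_equal(half$k, (one$k + zero$k) / 2, tolerance = 1e-12)
  expect_error(waspas_combine(s, lambda = 1.2), "lambda")
})

test_that("risk rank 1 goes to the lowest combined middle utility", {
  res <- waspas_combine(study_waspas(), lambda = 0.5)
  del <- res[res$objective == "Delivery to Client", ]
  expect_equal(del$mode_code[del$rank == 1], "F14")
  frt <- res[res$objective == "Freight Cost", ]
  expect_equal(frt$mode_code[frt$rank == 1], "F16")
  expect_equal(frt$mode_code[frt$rank == 2], "F14")
})

test_that("the full chain runs from a raw panel and degenerates sanely", {
  w <- tibble::tibble(criterion = c("S", "O", "D"),
                      w_l = c(0.5, 0.3, 0.2), w_m = c(0.5, 0.3, 0.2),
                      w_u = c(0.5, 0.3, 0.2))
  res <- zwaspas(toy_assessments(), w)
  expect_equal(nrow(res), 2)
  # M01 dominates (smaller S/O/D everywhere) -> anchor -> higher K -> rank 2
  expect_equal(res$rank[res$mode_code == "M01"], 2L)
  expect_true(all(res$k_l <= res$k_m & res$k_m <= res$k_u))
})
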