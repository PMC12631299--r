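toy_dmus <- function() {
  tibble::tibble(
    mode_code = c("A", "B", "C"), objective = "o",
    s_avg = c(1, 2, 2), o_avg = c(1, 2, 2), y = c(1, 2, 1))
}

test_that("DMU construction defuzzifies inputs and inverts the utility", {
  dmus <- build_dmus(study_assessments(), study_waspas())
  f01 <- dmus[dmus$mode_code == "F01" & dmus$objective == "Delivery to Client", ]
  expect_equal(c(f01$s_avg, f01$o_avg, f01$y), c(2.637, 3.68, 2.973), tolerance = 5e-4)
  f14 <- dmus[dmus$mode_code == "F14" & dmus$objective == "Delivery to Client", ]
  expect_equal(c(f14$s_avg, f14$o_avg, f14$y), c(8.097, 7.067, 6.696), tolerance = 5e-4)
  # unit utility TFN -> unit output
  k1 <- tibble::tibble(mode_code = "M01", objective = "obj", k_l = 1, k_m = 1, k_u = 1)
  a1 <- dplyr::filter(toy_assessments(), mode_code == "M01")
  expect_equal(build_dmus(a1, k1)$y, 1)
  expect_error(build_dmus(toy_assessments(), k1), "no combined utility")
})

test_that("the solver reproduces the hand-computed toy VRS results", {
  d <- toy_dmus()
  std <- dea_superefficiency(d, exclude_self = FALSE)
  expect_equal(std$raw_theta[std$mode_code == "C"], 0.5, tolerance = 1e-9)
  expect_true(all(std$raw_theta <= 1 + 1e-9))
  sup <- dea_superefficiency(d)
  expect_equal(sup$raw_theta[sup$mode_code == "A"], 2, tolerance = 1e-9)
  # A exceeds the cap: capped to 1.5, normalized to 1
  expect_equal(sup$theta_norm[sup$mode_code == "A"], 1)
})

test_that("solver output matches brute-force enumeration on small pools", {
  set.seed(73)
  for (rep in 1:40) {
    n <- sample(3:4, 1)
    d <- tibble::tibble(
      mode_code = paste0("M", 1:n), objective = "o",
      s_avg = runif(n, 1, 9), o_avg = runif(n, 1, 9), y = runif(n, 1, 7))
    sup <- dea_superefficiency(d)
    for (i in 1:n) {
      bf <- dea_input_bruteforce(as.matrix(d[-i, c("s_avg", "o_avg")]), d$y[-i],
                                 as.numeric(d[i, c("s_avg", "o_avg")]), d$y[i])
      if (is.infinite(bf)) {
        expect_false(sup$feasible[i])
      } else {
        expect_equal(sup$raw_theta[i], bf, tolerance = 1e-9)
      }
    }
  }
})

test_that("super-efficiency dominates standard efficiency and shrinks with the pool", {
  set.seed(79)
  n <- 6
  d <- tibble::tibble(
    mode_code = paste0("M", 1:n), objective = "o",
    s_avg = runif(n, 1, 9), o_avg = runif(n, 1, 9), y = runif(n, 1, 7))
  std <- dea_superefficiency(d, exclude_self = FALSE)
  sup <- dea_superefficiency(d)
  expect_true(all(std$raw_theta <= 1 + 1e-9))
  expect_true(all(pmin(sup$raw_theta, 99) >= std$raw_theta - 1e-7))
  # enlarging the reference pool cannot raise a target's super-efficiency
  bigger <- dplyr::bind_rows(d, dplyr::mutate(d, mode_code = paste0("X", 1:n),
                                              s_avg = s_avg * 0.9, y = y * 1.05))
  sup2 <- dea_superefficiency(bigger)
  expect_true(all(sup2$raw_theta[1:n] <= sup$raw_theta[1:n] + 1e-7))
})

test_that("efficiencies are invariant to rescaling all inputs", {
  set.seed(83)
  n <- 5
  d <- tibble::tibble(
    mode_code = paste0("M", 1:n), objective = "o",
    s_avg = runif(n, 1, 9), o_avg = runif(n, 1, 9), y = runif(n, 1, 7))
  a <- dea_superefficiency(d)
  b <- dea_superefficiency(dplyr::mutate(d, s_avg = s_avg * 3, o_avg = o_avg * 3))
  expect_equal(a$raw_theta, b$raw_theta, tolerance = 1e-7)
})

test_that("frontier-extreme study modes are infeasible and cap to exactly 1", {
  dmus <- build_dmus(study_assessments(), study_waspas())
  dea <- dea_superefficiency(dmus)
  inf <- dea[!dea$feasible, ]
  expect_setequal(paste(inf$mode_code, inf$objective),
                  c("F14 Delivery to Client", "F16 Freight Cost"))
  expect_equal(inf$theta_norm, c(1, 1))
})

test_that("fresh scores agree with the published normalized efficiencies", {
  dmus <- build_dmus(study_assessments(), study_waspas())
  dea <- dea_superefficiency(dmus)
  cmp <- dplyr::inner_join(dea, study_dea(), by = c("mode_code", "objective"),
                           suffix = c("", "_pub"))
  expect_equal(nrow(cmp), 42)
  expect_max_abs_diff(cmp$theta_norm, cmp$theta_norm_pub, 5e-4)
})

test_that("capping maps infeasible and above-cap scores onto the cap", {
  got <- cap_normalize(c(Inf, 2.7, 0.75), cap = 1.5)
  expect_equal(got$capped_theta, c(1.5, 1.5, 0.75))
  expect_equal(got$theta_norm, c(1, 1, 0.5))
  expect_error(cap_normalize(1, cap = 0), "positive")
})

test_that("the output orientation runs and flags its own infeasibilities", {
  d <- toy_dmus()
  out <- dea_superefficiency(d, orientation = "output")
  # A holds the unique minimum input: no reference fits within it -> infeasible
  expect_false(out$feasible[out$mode_code == "A"])
  expect_true(all(out$raw_theta[out$feasible] > 0))
})
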