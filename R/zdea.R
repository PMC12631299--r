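#' Build DEA decision-making units from risk scores
#'
#' The efficiency stage treats every failure mode under every objective as a
#' decision-making unit (DMU) converting risk inputs into criticality output:
#' inputs are the defuzzified, reliability-weighted severity and occurrence
#' averages; the output is the reciprocal of the defuzzified combined WASPAS
#' utility, `1 / K_avg`, so that riskier modes (low `K`) produce more output.
#'
#' @inheritParams z_convert
#' @param k A tibble with `mode_code`, `objective` and the combined utility
#'   TFN columns `k_l`, `k_m`, `k_u` (from [zwaspas()] or a stage fixture).
#' @param mode Z-number conversion mode for the input averages.
#' @return A tibble `mode_code`, `objective`, `s_avg`, `o_avg`, `y`.
#' @examples
#' dmus <- build_dmus(study_assessments(), study_waspas())
#' @export
build_dmus <- function(assessments, k, mode = c("alpha", "sqrt_alpha")) {
  mode <- match.arg(mode)
  conv <- z_convert(assessments, mode = mode) |>
    dplyr::filter(.data$factor %in% c("S", "O")) |>
    dplyr::mutate(avg = defuzzify(tfn(.data$xl, .data$xm, .data$xu))) |>
    dplyr::select("mode_code", "objective", "factor", "avg") |>
    tidyr::pivot_wider(names_from = "factor", values_from = "avg") |>
    dplyr::rename(s_avg = "S", o_avg = "O")
  kk <- tibble::as_tibble(k)
  out <- dplyr::inner_join(
    conv,
    dplyr::transmute(kk, mode_code = .data$mode_code, objective = .data$objective,
                     y = 1 / defuzzify(tfn(.data$k_l, .data$k_m, .data$k_u))),
    by = c("mode_code", "objective"))
  missing <- dplyr::anti_join(conv, kk, by = c("mode_code", "objective"))
  if (nrow(missing)) {
    stop("no combined utility for mode ", missing$mode_code[1], " (",
         missing$objective[1], ")", call. = FALSE)
  }
  out
}

# Feasibility tolerance for the efficiency programs (documented constant).
DEA_TOL <- 1e-9

# Linear program min c'x subject to t(A) %*% x >= b (first meq rows as
# equalities), solved as a ridge-regularized quadratic program
# (Goldfarb-Idnani, quadprog). The ridge is escalated if the QP is rejected
# numerically; the solution is then polished by solving the active-constraint
# system exactly, which recovers the LP optimum to machine precision on these
# small, non-degenerate programs. Returns the optimal objective value.
lp_min <- function(cvec, A, b, meq) {
  N <- length(cvec)
  sol <- NULL
  for (ridge in c(1e-8, 1e-6, 1e-4, 1e-2)) {
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = diag(ridge, N), dvec = -cvec, Amat = A,
                         bvec = b, meq = meq),
      error = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol)) {
    stop("efficiency program could not be solved at any regularization level",
         call. = FALSE)
  }
  x <- sol$solution
  resid <- drop(crossprod(A, x)) - b
  act <- unique(c(seq_len(meq), which(abs(resid) < 1e-6 & seq_along(b) > meq)))
  Aact <- t(A[, act, drop = FALSE])
  # minimum-norm solution of the (possibly rank-deficient) active system
  sv <- svd(Aact)
  pos <- sv$d > max(sv$d[1], 1) * 1e-12
  xp <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], b[act])) / sv$d[pos])
  xp <- drop(xp)
  if (!is.null(xp) &&
      max(abs(drop(Aact %*% xp) - b[act])) < 1e-8 &&
      all(drop(crossprod(A, xp)) - b > -1e-8) &&
      sum(cvec * xp) <= sum(cvec * x) + 1e-6) {
    x <- xp
  }
  sum(cvec * x)
}

# One VRS efficiency program. x: inputs matrix of the reference set
# (units x inputs); y: reference outputs; xt, yt: the evaluated unit.
# Input orientation: min theta s.t. sum(l*y) >= yt, sum(l*x_i) <= theta*xt_i,
# sum(l) = 1, l >= 0. Output orientation: max phi with the roles of the
# constraints swapped. Returns the optimum, or Inf when the program is
# infeasible (the super-efficiency case for frontier-extreme units).
dea_solve <- function(x, y, xt, yt, orientation) {
  n <- length(y)
  if (n < 1) stop("empty DEA reference set", call. = FALSE)
  p <- ncol(x)
  if (orientation == "input") {
    # infeasible iff no convex combination reaches the target output
    if (max(y) < yt - DEA_TOL) return(Inf)
    A <- cbind(c(0, rep(1, n)),       # sum lambda = 1
               c(0, y),               # sum lambda y >= yt
               rbind(xt, -x),         # theta*xt_i - sum lambda x_i >= 0
               rbind(0, diag(n)))     # lambda >= 0
    lp_min(c(1, rep(0, n)), A, c(1, yt, rep(0, p), rep(0, n)), meq = 1)
  } else {
    # infeasible iff no convex combination fits within the target inputs:
    # minimize the worst input excess t over the simplex
    Af <- cbind(c(0, rep(1, n)),      # sum lambda = 1
                rbind(1, -x),         # t + x_t,i - sum lambda x_i >= 0
                c(1, rep(0, n)),      # t >= -1 (bounds the free slack; only
                                      # the sign of the optimum matters)
                rbind(0, diag(n)))    # lambda >= 0
    excess <- lp_min(c(1, rep(0, n)), Af, c(1, -xt, -1, rep(0, n)), meq = 1)
    if (excess > DEA_TOL) return(Inf)
    A <- cbind(c(0, rep(1, n)),       # sum lambda = 1
               c(-yt, y),             # sum lambda y - phi*yt >= 0
               rbind(0, -x),          # sum lambda x_i <= x_t,i (slackened by
                                      # DEA_TOL: boundary-feasible programs
                                      # would otherwise be rejected by roundoff)
               rbind(0, diag(n)))     # lambda >= 0
    xt_rel <- xt * (1 + DEA_TOL) + DEA_TOL
    -lp_min(c(-1, rep(0, n)), A, c(1, 0, -xt_rel, rep(0, n)), meq = 1)
  }
}

#' Super-efficiency DEA under variable returns to scale
#'
#' Scores every DMU by an input-oriented (default) VRS efficiency program;
#' with `exclude_self = TRUE` the evaluated DMU is removed from its own
#' reference set (super-efficiency), so frontier units can score above 1 or
#' — when their output exceeds every peer's under the VRS convexity
#' constraint — become infeasible. Infeasible or above-cap scores are capped
#' (default 1.5) and all scores are normalized by the cap, following the
#' published post-processing.
#'
#' @param dmus A tibble from [build_dmus()] (`mode_code`, `objective`,
#'   `s_avg`, `o_avg`, `y`, all strictly positive).
#' @param orientation `"input"` (default) or `"output"`.
#' @param pool `"per_objective"` (default): each objective forms its own
#'   frontier; `"joint"`: all DMUs compete on one frontier.
#' @param exclude_self Super-efficiency (default `TRUE`); `FALSE` gives the
#'   standard VRS efficiency, which is at most 1 for input orientation.
#' @param cap Cap applied to raw scores before normalization (default 1.5).
#' @return A tibble with `raw_theta` (`Inf` marks an infeasible
#'   super-efficiency program), `feasible`, `capped_theta` and
#'   `theta_norm = capped_theta / cap`.
#' @examples
#' dmus <- build_dmus(study_assessments(), study_waspas())
#' dea_superefficiency(dmus) |> dplyr::filter(!feasible)
#' @export
dea_superefficiency <- function(dmus, orientation = c("input", "output"),
                                pool = c("per_objective", "joint"),
                                exclude_self = TRUE, cap = 1.5) {
  orientation <- match.arg(orientation)
  pool <- match.arg(pool)
  if (!is.numeric(cap) || cap <= 0) stop("cap must be positive", call. = FALSE)
  d <- tibble::as_tibble(dmus)
  if (any(d$s_avg <= 0 | d$o_avg <= 0 | d$y <= 0)) {
    stop("DMU inputs and output must be strictly positive", call. = FALSE)
  }
  d$.pool <- if (pool == "per_objective") d$objective else "all"
  raw <- vapply(seq_len(nrow(d)), function(i) {
    ref <- which(d$.pool == d$.pool[i] & (!exclude_self | seq_len(nrow(d)) != i))
    if (length(ref) < 1) {
      stop("DMU ", d$mode_code[i], " has no reference peers", call. = FALSE)
    }
    dea_solve(x = as.matrix(d[ref, c("s_avg", "o_avg")]), y = d$y[ref],
              xt = c(d$s_avg[i], d$o_avg[i]), yt = d$y[i],
              orientation = orientation)
  }, numeric(1))
  d$.pool <- NULL
  cn <- cap_normalize(raw, cap = cap)
  dplyr::bind_cols(d, tibble::tibble(raw_theta = raw, feasible = is.finite(raw),
                                     capped_theta = cn$capped_theta,
                                     theta_norm = cn$theta_norm))
}

#' @rdname dea_superefficiency
#' @param raw_theta Numeric vector of raw efficiency scores; `Inf` marks an
#'   infeasible super-efficiency program.
#' @export
cap_normalize <- function(raw_theta, cap = 1.5) {
  if (!is.numeric(cap) || cap <= 0) stop("cap must be positive", call. = FALSE)
  capped <- pmin(raw_theta, cap)
  tibble::tibble(capped_theta = capped, theta_norm = capped / cap)
}
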