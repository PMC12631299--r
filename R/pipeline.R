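#' Run the full risk-prioritization pipeline
#'
#' Chains the five stages — fuzzy RPN, criterion weighting, weighted
#' sum-product ranking, super-efficiency DEA and hybrid aggregation — over an
#' assessment panel, returning a fitted object holding every stage table.
#'
#' Any stage after the RPN can be replaced by a published intermediate via
#' `fixtures`: a named list with any of `waspas` (a table with `wsm_*`,
#' `wpm_*` columns, combined by [waspas_combine()]), `dea` (a table with
#' `theta_norm`) and `rpn_middles` (a table with `rpn_middle`, overriding the
#' RPN middles fed to the hybrid stage). This is how the packaged study is
#' reproduced stage-wise despite upstream intermediates that are not
#' bit-derivable from the raw panel.
#'
#' @inheritParams z_convert
#' @param weights A weight set (`objective`, `criterion`, `w_l`, `w_m`,
#'   `w_u`).
#' @param lambda WASPAS mixing weight in \[0, 1\].
#' @param conversion Z-number conversion mode for the numeric stages.
#' @param division Fuzzy division style for the WASPAS normalization.
#' @param dea_orientation,dea_pool,dea_cap Efficiency-stage configuration
#'   (see [dea_superefficiency()]).
#' @param objective_weights Weights over objectives for the combined score
#'   (default equal).
#' @param fixtures Optional named list of stage substitutions (see Details).
#' @return An object of class `zfmea_fit`: a list with elements
#'   `assessments`, `weights`, `rpn`, `waspas`, `dmus`, `dea`, `hybrid`,
#'   `combined` and `config`. Supports [tidy()], [glance()],
#'   [ggplot2::autoplot()] and `print()`.
#' @examples
#' fit <- zfmea(study_assessments(), study_weights(),
#'              fixtures = list(waspas = study_waspas(), dea = study_dea(),
#'                              rpn_middles = study_hybrid_rpn()))
#' tidy(fit)
#' @export
zfmea <- function(assessments, weights, lambda = 0.5,
                  conversion = c("alpha", "sqrt_alpha"),
                  division = c("componentwise", "inverted"),
                  dea_orientation = c("input", "output"),
                  dea_pool = c("per_objective", "joint"),
                  dea_cap = 1.5, objective_weights = NULL, fixtures = list()) {
  conversion <- match.arg(conversion)
  division <- match.arg(division)
  dea_orientation <- match.arg(dea_orientation)
  dea_pool <- match.arg(dea_pool)
  stopifnot(is.list(fixtures))
  unknown <- setdiff(names(fixtures), c("waspas", "dea", "rpn_middles"))
  if (length(unknown)) {
    stop("unknown fixture stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  a <- as_assessments(assessments)

  rpn <- compute_rpn(a)

  waspas <- if (!is.null(fixtures$waspas)) {
    waspas_combine(tibble::as_tibble(fixtures$waspas)[
      c("mode_code", "objective", "wsm_l", "wsm_m", "wsm_u",
        "wpm_l", "wpm_m", "wpm_u")], lambda = lambda)
  } else {
    zwaspas(a, weights, lambda = lambda, conversion = conversion,
            division = division)
  }

  dmus <- build_dmus(a, waspas, mode = conversion)
  dea <- if (!is.null(fixtures$dea)) {
    tibble::as_tibble(fixtures$dea)[c("mode_code", "objective", "theta_norm")]
  } else {
    dea_superefficiency(dmus, orientation = dea_orientation, pool = dea_pool,
                        cap = dea_cap)
  }

  rpn_for_hybrid <- if (!is.null(fixtures$rpn_middles)) {
    tibble::as_tibble(fixtures$rpn_middles)
  } else {
    rpn
  }
  hybrid <- hybrid_scores(rpn = rpn_for_hybrid, k = waspas, dea = dea)
  combined <- combine_objectives(hybrid, objective_weights = objective_weights)

  structure(
    list(assessments = a, weights = tibble::as_tibble(weights), rpn = rpn,
         waspas = waspas, dmus = dmus, dea = dea, hybrid = hybrid,
         combined = combined,
         config = list(lambda = lambda, conversion = conversion,
                       division = division, dea_orientation = dea_orientation,
                       dea_pool = dea_pool, dea_cap = dea_cap,
                       fixtures = names(fixtures))),
    class = "zfmea_fit")
}

#' @export
print.zfmea_fit <- function(x, n = 5, ...) {
  cat("Z-number hybrid risk prioritization\n")
  cat(sprintf("  %d failure modes x %d objectives; lambda = %g, DEA %s/%s, cap %g\n",
              length(unique(x$combined$mode_code)),
              length(unique(x$hybrid$objective)),
              x$config$lambda, x$config$dea_orientation, x$config$dea_pool,
              x$config$dea_cap))
  if (length(x$config$fixtures)) {
    cat("  stage fixtures:", paste(x$config$fixtures, collapse = ", "), "\n")
  }
  cat("Top of the combined ranking:\n")
  print(utils::head(x$combined, n))
  invisible(x)
}

#' Tidy the combined ranking of a fitted prioritization
#'
#' `tidy()` returns the per-mode combined scores joined with the
#' per-objective hybrid scores in wide form; `glance()` returns a one-row
#' summary of the fit.
#'
#' @param x A `zfmea_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.zfmea_fit <- function(x, ...) {
  wide <- x$hybrid |>
    dplyr::select("mode_code", "objective", "q") |>
    tidyr::pivot_wider(names_from = "objective", values_from = "q",
                       names_prefix = "q_")
  dplyr::left_join(x$combined, wide, by = "mode_code")
}

#' @rdname tidy.zfmea_fit
#' @export
glance.zfmea_fit <- function(x, ...) {
  tibble::tibble(
    n_modes = length(unique(x$combined$mode_code)),
    n_objectives = length(unique(x$hybrid$objective)),
    lambda = x$config$lambda,
    dea_cap = x$config$dea_cap,
    top_mode = x$combined$mode_code[1],
    top_q_total = x$combined$q_total[1])
}

#' Plot the combined hybrid ranking
#'
#' A horizontal bar chart of the combined hybrid scores, highest risk on
#' top; `plot_hybrid_scores()` shows the per-objective scores side by side.
#'
#' @param object,fit A `zfmea_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zfmea_fit <- function(object, ...) {
  d <- dplyr::mutate(object$combined,
                     mode_code = stats::reorder(.data$mode_code, .data$q_total))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q_total, y = .data$mode_code)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "combined hybrid score Q_total", y = NULL,
                  title = "Failure modes by combined hybrid risk score") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.zfmea_fit
#' @export
plot_hybrid_scores <- function(fit) {
  stopifnot(inherits(fit, "zfmea_fit"))
  d <- dplyr::mutate(fit$hybrid,
                     mode_code = stats::reorder(.data$mode_code, .data$q))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$mode_code)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::facet_wrap(ggplot2::vars(.data$objective)) +
    ggplot2::labs(x = "hybrid score Q", y = NULL,
                  title = "Per-objective hybrid risk scores") +
    ggplot2::theme_minimal()
}

#' Run the pipeline from files
#'
#' A thin orchestration layer over [zfmea()] for shell use: reads the
#' assessment panel (and optionally a weight file), runs every stage, and —
#' when `outdir` is given — writes one CSV per stage (`rpn.csv`,
#' `weights.csv`, `waspas.csv`, `dmus.csv`, `dea.csv`, `hybrid.csv`,
#' `combined.csv`) plus a human-readable `summary.txt`. Output is
#' deterministic for identical inputs and configuration.
#'
#' @param assessments_path Path to the assessment CSV.
#' @param weights_path Optional path to a weight CSV; defaults to the
#'   packaged study weights.
#' @param outdir Optional output directory (created if needed).
#' @param ... Passed to [zfmea()].
#' @return The `zfmea_fit`, invisibly when writing files.
#' @export
run_pipeline <- function(assessments_path, weights_path = NULL, outdir = NULL, ...) {
  a <- read_assessments(assessments_path)
  w <- if (is.null(weights_path)) study_weights() else read_weights(weights_path)
  fit <- zfmea(a, w, ...)
  if (is.null(outdir)) return(fit)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(outdir, name)
  readr::write_csv(fit$rpn, out("rpn.csv"))
  readr::write_csv(fit$weights, out("weights.csv"))
  readr::write_csv(fit$waspas, out("waspas.csv"))
  readr::write_csv(fit$dmus, out("dmus.csv"))
  dea_out <- fit$dea
  if ("raw_theta" %in% names(dea_out)) {
    dea_out$raw_theta <- ifelse(is.finite(dea_out$raw_theta),
                                as.character(dea_out$raw_theta), "INF")
  }
  readr::write_csv(dea_out, out("dea.csv"))
  readr::write_csv(fit$hybrid, out("hybrid.csv"))
  readr::write_csv(fit$combined, out("combined.csv"))
  writeLines(c(
    "Z-number hybrid risk prioritization",
    sprintf("lambda = %g; conversion = %s; division = %s; DEA %s/%s cap %g",
            fit$config$lambda, fit$config$conversion, fit$config$division,
            fit$config$dea_orientation, fit$config$dea_pool, fit$config$dea_cap),
    if (length(fit$config$fixtures))
      paste("stage fixtures:", paste(fit$config$fixtures, collapse = ", "))
    else "stage fixtures: none",
    "",
    "Combined ranking (highest risk first):",
    sprintf("  %2d. %s  Q_total = %.6f", fit$combined$rank,
            fit$combined$mode_code, fit$combined$q_total)
  ), out("summary.txt"))
  invisible(fit)
}
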