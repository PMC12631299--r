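#' Read and write assessment panels
#'
#' `read_assessments()` loads the standard long-format CSV dialect
#' (`mode_code`, optional `mode_name`, `objective`, `factor`, `rl`, `rm`,
#' `ru`, `bl`, `bm`, `bu` — one row per Z-number) and validates it with
#' [as_assessments()]. `write_assessments()` writes the same dialect.
#'
#' @param path Path to a CSV file.
#' @param scale_max Upper bound of the rating scale.
#' @return `read_assessments()` a validated tibble.
#' @export
read_assessments <- function(path, scale_max = 10) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  as_assessments(x, scale_max = scale_max)
}

#' @rdname read_assessments
#' @param assessments A validated assessment panel.
#' @export
write_assessments <- function(assessments, path) {
  readr::write_csv(as_assessments(assessments), path)
  invisible(path)
}

#' Read a criterion weight set
#'
#' Loads a CSV with columns `objective`, `criterion`, `wl`/`w_l`, `wm`/`w_m`,
#' `wu`/`w_u` (both spellings accepted) into the weight-set layout the
#' ranking stages expect.
#'
#' @param path Path to a CSV file.
#' @return A tibble `objective`, `criterion`, `w_l`, `w_m`, `w_u`.
#' @export
read_weights <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE)
  ren <- c(w_l = "wl", w_m = "wm", w_u = "wu")
  for (nm in names(ren)) {
    if (!nm %in% names(w) && ren[[nm]] %in% names(w)) names(w)[names(w) == ren[[nm]]] <- nm
  }
  needed <- c("objective", "criterion", "w_l", "w_m", "w_u")
  if (!all(needed %in% names(w))) {
    stop("weight file needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  tfn(w$w_l, w$w_m, w$w_u) # validates ordering
  if (any(w$w_l <= 0)) stop("weights must be positive", call. = FALSE)
  tibble::as_tibble(w[needed])
}

study_file <- function(name) {
  system.file("extdata", name, package = "zfmea", mustWork = TRUE)
}

#' The packaged antiretroviral supply-chain case study
#'
#' The package ships the published risk study of 21 failure modes in an
#' antiretroviral (HIV) drug supply chain, assessed under two objectives —
#' delivery-to-client date and freight cost — as plain-text fixtures:
#'
#' * `study_assessments()` — the expert Z-number panel (21 modes x 2
#'   objectives x 3 factors);
#' * `study_weights()` — the stepwise criterion weights for S, O, D per
#'   objective;
#' * `study_waspas()` — the published WSM/WPM stage values with their
#'   combined utility TFNs (this stage table cannot be re-derived bit-exactly
#'   from the raw panel; it is consumed as the published intermediate);
#' * `study_dea()` — the published normalized super-efficiency scores;
#' * `study_hybrid_rpn()` — the RPN middle values the published hybrid stage
#'   used (they deviate from the RPN table for a handful of cells);
#' * `study_failure_modes()` — code-to-name lookup for the 21 modes.
#'
#' @return A tibble (layout per accessor above).
#' @examples
#' study_assessments() |> head(3)
#' @export
study_assessments <- function() {
  read_assessments(study_file("assessments.csv"))
}

#' @rdname study_assessments
#' @export
study_weights <- function() {
  read_weights(study_file("weights.csv"))
}

#' @rdname study_assessments
#' @export
study_waspas <- function() {
  dplyr::inner_join(
    readr::read_csv(study_file("waspas_wsm_wpm.csv"), show_col_types = FALSE),
    readr::read_csv(study_file("waspas_combined_k.csv"), show_col_types = FALSE),
    by = c("mode_code", "objective"))
}

#' @rdname study_assessments
#' @export
study_dea <- function() {
  readr::read_csv(study_file("dea_scores.csv"), show_col_types = FALSE)
}

#' @rdname study_assessments
#' @export
study_hybrid_rpn <- function() {
  readr::read_csv(study_file("hybrid_rpn_middles.csv"), show_col_types = FALSE)
}

#' @rdname study_assessments
#' @export
study_failure_modes <- function() {
  readr::read_csv(study_file("failure_modes.csv"), show_col_types = FALSE)
}
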