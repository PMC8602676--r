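#' Load a hydrophobicity-index coefficient set
#'
#' The default set (`v1`, shipped with the package) implements a
#' first-generation additive retention-coefficient model for reversed-phase
#' C18 / formic-acid separation: a per-residue retention coefficient `rc`, a
#' per-residue N-terminal correction `rc_nt` applied with decreasing weight
#' to the first three residues, and a peptide-length correction. Alternative
#' coefficient sets for other column chemistries can be dropped in as TSV
#' files with the same columns.
#'
#' @param path TSV with columns `residue`, `rc`, `rc_nt`; default the
#'   bundled v1 set.
#' @return A list of class `rt_coefficients` with `rc`, `rc_nt` (named
#'   numeric, all 20 residues), `nt_weights` and `version`.
#' @export
hi_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hi_coefficients_v1.tsv",
                        package = "tsafinder")
  }
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("residue", "rc", "rc_nt") %in% names(tb)))
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!setequal(tb$residue, aa20)) {
    stop("coefficient set must cover exactly the 20 standard residues",
         call. = FALSE)
  }
  structure(list(
    rc = stats::setNames(tb$rc, tb$residue),
    rc_nt = stats::setNames(tb$rc_nt, tb$residue),
    nt_weights = c(0.42, 0.22, 0.05),
    version = sub("\\.tsv$", "", basename(path))
  ), class = "rt_coefficients")
}

#' Predict a peptide's hydrophobicity index
#'
#' Additive model: the sum of per-residue retention coefficients, plus
#' N-terminal corrections for the first three residues (weights 0.42, 0.22,
#' 0.05), scaled by a length correction (short and long peptides retain
#' less than the plain sum predicts). Deterministic, and
#' permutation-invariant beyond the three N-terminal positions. The HI is
#' dimensionless and proportional to the organic-solvent fraction at
#' elution, hence to retention time on a fixed gradient.
#'
#' @param peptide Amino-acid sequence (length >= 4, standard residues only;
#'   `X` is rejected).
#' @param coeffs An [hi_coefficients()] set.
#' @return Numeric HI value.
#' @export
predict_hi <- function(peptide, coeffs = hi_coefficients()) {
  if (nchar(peptide) < 4L) {
    stop("peptide too short for HI prediction (need >= 4 aa): ", peptide,
         call. = FALSE)
  }
  aa <- strsplit(toupper(peptide), "")[[1]]
  unknown <- setdiff(aa, names(coeffs$rc))
  if (length(unknown) > 0L) {
    stop("non-standard residue(s) in '", peptide, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- length(aa)
  kl <- if (n < 10) 1 - 0.027 * (10 - n) else
    if (n > 20) 1 - 0.014 * (n - 20) else 1
  base <- sum(coeffs$rc[aa]) +
    sum(coeffs$nt_weights * coeffs$rc_nt[aa[1:3]])
  unname(kl * base)
}

#' Vectorized HI prediction
#' @param peptides Character vector of sequences.
#' @inheritParams predict_hi
#' @return Numeric vector.
#' @export
predict_hi_all <- function(peptides, coeffs = hi_coefficients()) {
  vapply(peptides, predict_hi, numeric(1), coeffs = coeffs, USE.NAMES = FALSE)
}

#' Fit observed retention time against predicted hydrophobicity index
#'
#' Ordinary least squares of retention time (minutes) on HI, reporting the
#' slope, intercept, coefficient of determination and the F-test p-value for
#' a nonzero slope.
#'
#' @param observations Tibble (or data frame) with columns `hi` and `rt`.
#' @return An `rt_fit` object wrapping the `lm` fit; supports [tidy()],
#'   [glance()] and `autoplot()`.
#' @export
fit_rt_vs_hi <- function(observations) {
  stopifnot(all(c("hi", "rt") %in% names(observations)))
  n <- nrow(observations)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(observations$hi)) == 1L) {
    stop("degenerate design: all HI values identical", call. = FALSE)
  }
  fit <- stats::lm(rt ~ hi, data = observations)
  sm <- suppressWarnings(summary(fit))
  p <- if (is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  # R^2 from the definition; a zero-variance response has R^2 = 0 by
  # convention rather than the 0/0 artifact summary.lm can produce
  sst <- sum((observations$rt - mean(observations$rt))^2)
  r2 <- if (sst <= .Machine$double.eps * n) 0 else
    1 - sum(stats::residuals(fit)^2) / sst
  structure(list(
    lm = fit, data = tibble::as_tibble(observations),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    p_value = unname(p),
    n = n
  ), class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf(
    "<rt_fit> RT = %.3f + %.3f * HI  (n = %d, R^2 = %.4f, p = %.3g)\n",
    x$intercept, x$slope, x$n, x$r_squared, x$p_value))
  invisible(x)
}

#' Tidy an RT-vs-HI fit
#' @param x An `rt_fit`.
#' @param ... Unused.
#' @return Tibble with one row per model term (`term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`).
#' @export
tidy.rt_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$lm))$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std_error = co[, 2], statistic = co[, 3],
                 p_value = co[, 4])
}

#' One-row model summary of an RT-vs-HI fit
#' @param x An `rt_fit`.
#' @param ... Unused.
#' @return Tibble with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
glance.rt_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, p_value = x$p_value, n = x$n)
}

#' @export
autoplot.rt_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$hi, y = .data$rt)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "firebrick") +
    ggplot2::labs(x = "predicted hydrophobicity index",
                  y = "observed retention time (min)",
                  subtitle = sprintf("R^2 = %.3f, p = %.2g",
                                     object$r_squared, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Validate candidate peptides by retention-time regression
#'
#' Predicts an HI for every candidate, regresses observed mean retention
#' time on HI, and flags peptides whose studentized residual exceeds a
#' threshold. Flagging is advisory: retention-time agreement supports a
#' peptide's sequence assignment, and outliers are reported, never removed.
#' When a reference-matched peptide table is supplied, it is fitted as well
#' so the two regressions can be compared.
#'
#' @param candidates Tibble with columns `peptide` and `mean_rt` (minutes).
#' @param coeffs An [hi_coefficients()] set.
#' @param reference Optional tibble with `peptide`, `mean_rt` of
#'   reference-matched peptides fitted alongside.
#' @param residual_flag Studentized-residual threshold (default 3).
#' @return List of class `rt_validation`: `table` (peptide, hi, mean_rt,
#'   studentized residual, `flagged`), `fit` (an `rt_fit`) and
#'   `reference_fit` (or `NULL`).
#' @export
validate_candidates <- function(candidates, coeffs = hi_coefficients(),
                                reference = NULL, residual_flag = 3) {
  if (nrow(candidates) < 3L) {
    stop("need at least 3 candidates with retention times", call. = FALSE)
  }
  obs <- tibble::tibble(
    peptide = candidates$peptide,
    hi = predict_hi_all(candidates$peptide, coeffs),
    rt = candidates$mean_rt
  )
  fit <- fit_rt_vs_hi(obs)
  stud <- stats::rstudent(fit$lm)
  table <- obs |>
    dplyr::rename(mean_rt = "rt") |>
    dplyr::mutate(studentized = unname(stud),
                  flagged = abs(.data$studentized) > residual_flag)
  ref_fit <- NULL
  if (!is.null(reference) && nrow(reference) >= 3L) {
    ref_fit <- fit_rt_vs_hi(tibble::tibble(
      hi = predict_hi_all(reference$peptide, coeffs),
      rt = reference$mean_rt))
  }
  structure(list(table = table, fit = fit, reference_fit = ref_fit,
                 residual_flag = residual_flag, coeffs_version = coeffs$version),
            class = "rt_validation")
}

#' @export
print.rt_validation <- function(x, ...) {
  cat("<rt_validation> ", nrow(x$table), " peptide(s), ",
      sum(x$table$flagged), " flagged (|studentized| > ", x$residual_flag,
      ")\n", sep = "")
  print(x$fit)
  invisible(x)
}

#' Write an RT validation report as TSV and JSON
#'
#' @param validation An `rt_validation`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return The validation object, invisibly.
#' @export
write_rt_report <- function(validation, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(validation$table, tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(fit = as.list(glance.rt_fit(validation$fit)),
           coefficients_version = validation$coeffs_version,
           n_flagged = sum(validation$table$flagged)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(validation)
}

#' @export
autoplot.rt_validation <- function(object, ...) {
  autoplot.rt_fit(object$fit) +
    ggplot2::geom_point(
      data = object$table[object$table$flagged, ],
      ggplot2::aes(x = .data$hi, y = .data$mean_rt),
      color = "orange", size = 3, shape = 1)
}
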