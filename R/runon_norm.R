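#' Fit the run-on calibration standard curve
#'
#' Ordinary least squares of scintillation counts (CPM) on DNA input (ng)
#' over the serial-dilution standards: `cpm = m * dna_ng + b`.
#'
#' @param standards A data.frame with columns `dna_ng` and `cpm`, or a
#'   two-column matrix/list of `(dna_ng, cpm)` pairs.
#' @return An object of class `standard_curve`: `m` (slope, CPM/ng),
#'   `b` (intercept, CPM), `r2`, `n`.
#' @export
fit_standard_curve <- function(standards) {
  if (is.matrix(standards)) {
    standards <- data.frame(dna_ng = standards[, 1], cpm = standards[, 2])
  }
  x <- standards$dna_ng; y <- standards$cpm
  if (length(x) < 2 || length(unique(x)) < 2) {
    stop_input("calibration requires >= 2 standards with distinct DNA inputs")
  }
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) > 0) {
    suppressWarnings(summary(fit)$r.squared)   # exact fits are fine here
  } else 1
  structure(list(m = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]),
                 r2 = r2, n = length(x)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: cpm = %.6g * dna_ng + %.6g (r2 = %.4f, n = %d)\n",
              x$m, x$b, x$r2, x$n))
  invisible(x)
}

#' Expected CPM for a sample from the standard curve
#'
#' @param curve A [fit_standard_curve()] result.
#' @param dna_ng DNA input of the sample(s), ng (> 0).
#' @return Predicted CPM, `m * dna_ng + b`. A non-positive prediction
#'   means the sample cannot be calibrated and is an error.
#' @export
expected_cpm <- function(curve, dna_ng) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(dna_ng <= 0)) stop_input("dna_ng must be positive")
  e <- curve$m * dna_ng + curve$b
  if (any(e <= 0)) {
    stop_input("uncalibratable sample: expected CPM <= 0 at dna_ng = ",
               paste(dna_ng[e <= 0], collapse = ", "))
  }
  e
}

.composition_matrix <- function(samples) {
  cols <- c("frac_LZ", "frac_P", "frac_D")
  if (!all(cols %in% names(samples))) {
    stop_input("samples need composition columns ",
               paste(cols, collapse = ", "))
  }
  A <- as.matrix(samples[, cols])
  colnames(A) <- c("LZ", "P", "D")
  if (any(A < -1e-12) || any(A > 1 + 1e-12)) {
    stop_input("composition fractions must be in [0,1]")
  }
  A
}

#' Deconvolve per-stage relative transcriptional activity
#'
#' Solves the calibrated mixture model: for each sample,
#' `observed CPM / expected CPM = frac_LZ * LZ + frac_P * P + frac_D * D`,
#' where `LZ`, `P`, `D` are the stage activities. The (usually
#' overdetermined) system is solved by unconstrained ordinary least
#' squares without intercept; it is exact when square and consistent.
#' Negative solutions are reported with a warning; `nonneg = TRUE`
#' switches to a non-negativity-constrained fit.
#'
#' @param samples A data.frame of run-on samples with columns `dna_ng`,
#'   `cpm`, `frac_LZ`, `frac_P`, `frac_D`.
#' @param curve A [fit_standard_curve()] result.
#' @param nonneg Constrain activities to be non-negative (uses
#'   `pracma::lsqnonneg`).
#' @return An object of class `stage_activities`: `activity` (named
#'   vector LZ, P, D), `residual_norm`, `covariance` (scaled by residual
#'   variance when there are more samples than stages, else `NA`).
#' @export
deconvolve_activities <- function(samples, curve, nonneg = FALSE) {
  A <- .composition_matrix(samples)
  if (nrow(A) < 3) {
    stop_input("underdetermined system: need >= 3 samples for 3 stages")
  }
  qa <- qr(A)
  if (qa$rank < 3) {
    ## columns not reached by the pivoted R factor are unidentifiable
    bad <- colnames(A)[qa$pivot[(qa$rank + 1):3]]
    stop_input("composition matrix is rank-deficient; unidentifiable ",
               "stage(s): ", paste(bad, collapse = ", "))
  }
  r <- samples$cpm / expected_cpm(curve, samples$dna_ng)
  if (nonneg) {
    if (!requireNamespace("pracma", quietly = TRUE)) {
      stop_input("nonneg = TRUE requires the pracma package")
    }
    sol <- pracma::lsqnonneg(A, r)
    a <- stats::setNames(sol$x, colnames(A))
    resid <- r - as.numeric(A %*% a)
  } else {
    a <- stats::setNames(qr.coef(qa, r), colnames(A))
    resid <- r - as.numeric(A %*% a)
    if (any(a < 0)) {
      warning("negative activity estimate for stage(s): ",
              paste(names(a)[a < 0], collapse = ", "),
              "; consider nonneg = TRUE")
    }
  }
  covm <- NA
  if (nrow(A) > 3 && !nonneg) {
    s2 <- sum(resid^2) / (nrow(A) - 3)
    V <- chol2inv(qr.R(qa))      # (R'R)^-1 in pivoted column order
    covm <- matrix(0, 3, 3, dimnames = list(colnames(A), colnames(A)))
    covm[qa$pivot, qa$pivot] <- V
    covm <- s2 * covm
  }
  structure(list(activity = a,
                 residual_norm = sqrt(sum(resid^2)),
                 covariance = covm),
            class = "stage_activities")
}

#' @export
print.stage_activities <- function(x, ...) {
  cat("stage_activities:\n")
  print(round(x$activity, 4))
  cat(sprintf("  residual norm: %.4g\n", x$residual_norm))
  invisible(x)
}

#' Activity of a pure (single-stage) fraction
#'
#' For samples enriched at 100% for one stage the mixture model reduces to
#' the plain calibration ratio.
#'
#' @param sample One-row data.frame with `dna_ng`, `cpm` and composition
#'   columns.
#' @param curve A [fit_standard_curve()] result.
#' @param tol Tolerance for the unit-vector composition check.
#' @return `cpm / expected_cpm`, a single number.
#' @export
pure_fraction_activity <- function(sample, curve, tol = 1e-9) {
  A <- .composition_matrix(sample)
  if (nrow(A) != 1) stop_input("sample must be a single row")
  if (!any(abs(A - 1) < tol) || abs(sum(A) - 1) > tol) {
    stop_contract("pure_fraction_activity requires a unit composition ",
                  "(one stage at 100%)")
  }
  as.numeric(sample$cpm / expected_cpm(curve, sample$dna_ng))
}

#' Run-on-calibrated library normalization factors
#'
#' Converts per-stage mapped-read counts and deconvolved activities into
#' multiplicative bedGraph factors,
#' `factor(s) = (1 / library_size(s)) * (activity(s) / activity(ref))`,
#' so that rescaled coverage is comparable across stages on an absolute
#' (run-on-anchored) scale. Also reports the DESeq2-style size factor
#' `1 / factor` (dividing a count matrix by it is the same as multiplying
#' by the factor, i.e. dividing by library size and multiplying by the
#' activity ratio).
#'
#' @param library_sizes Named per-stage mapped-read counts (> 0).
#' @param activities A [deconvolve_activities()] result, or a named
#'   numeric vector of activities.
#' @param reference Reference stage (default `"LZ"`); its factor is
#'   `1 / library_size(reference)`.
#' @return A data.frame: `stage`, `library_size`, `activity`,
#'   `activity_ratio`, `factor`, `size_factor`.
#' @export
normalization_factors <- function(library_sizes, activities,
                                  reference = "LZ") {
  act <- if (inherits(activities, "stage_activities")) {
    activities$activity
  } else activities
  stages <- names(library_sizes)
  if (is.null(stages) || !all(stages %in% names(act))) {
    stop_input("library_sizes and activities must share stage names")
  }
  if (any(library_sizes <= 0)) stop_input("library sizes must be positive")
  if (!reference %in% stages) stop_input("reference stage not present")
  if (act[[reference]] == 0) stop_input("reference activity is zero")
  ratio <- act[stages] / act[[reference]]
  fac <- (1 / library_sizes) * ratio
  data.frame(stage = stages,
             library_size = as.numeric(library_sizes),
             activity = as.numeric(act[stages]),
             activity_ratio = as.numeric(ratio),
             factor = as.numeric(fac),
             size_factor = as.numeric(1 / fac),
             row.names = NULL)
}
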