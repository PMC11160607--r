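#' Score-time correlations per validation cohort
#'
#' Validation-stage analog of the training screen: Pearson r and t-based p
#' of each component's projected score against the cohort's time axis,
#' grouped by dataset. Uses the same correlation engine as
#' [correlate_components_with_time()].
#'
#' @param scores Score tibble from [project_cohort()].
#' @param sheet Sample sheet covering the scored samples.
#' @return A tibble: one row per (component, dataset) with `r`, `p`, `n`.
#' @export
score_time_correlation <- function(scores, sheet) {
  out <- correlate_components_with_time(scores, sheet)
  bad <- dplyr::filter(out, .data$n < 3)
  if (nrow(bad) > 0) {
    abort("score_time_correlation: every group needs >= 3 timed samples.",
          class = "eldar_assoc_error")
  }
  out
}

#' Age by sun-exposure interaction model for a projected score
#'
#' Ordinary least squares of a component score on age, a 0/1 sun-exposure
#' indicator (protected = 0, exposed = 1), and their interaction; standard
#' errors come from the residual variance and the inverse Gram matrix, and
#' two-sided p-values from the t distribution on n - 4 degrees of freedom.
#' The exposure coding is recorded in the result so coefficient signs are
#' interpretable.
#'
#' @param score Numeric response (projected component score per sample).
#' @param age Numeric ages (years).
#' @param sun_exposed Logical exposure indicator.
#' @return An object of class `eldar_interaction` wrapping the `lm` fit,
#'   with `tidy()` and `glance()` methods.
#' @export
fit_age_sun_interaction <- function(score, age, sun_exposed) {
  n <- length(score)
  stopifnot(length(age) == n, length(sun_exposed) == n)
  if (n < 5) {
    abort("fit_age_sun_interaction: need at least 5 samples for 4 parameters.",
          class = "eldar_assoc_error")
  }
  sun <- as.numeric(sun_exposed)
  if (length(unique(sun)) < 2) {
    abort("fit_age_sun_interaction: singular design - all samples share one exposure level (column sun_exposed).",
          class = "eldar_assoc_error")
  }
  if (stats::sd(age) == 0) {
    abort("fit_age_sun_interaction: singular design - age is constant (column age).",
          class = "eldar_assoc_error")
  }
  df <- data.frame(score = score, age = age, sun = sun)
  fit <- lm(score ~ age + sun + age:sun, data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("fit_age_sun_interaction: singular design (collinear column: ",
                 bad[1], ")."), class = "eldar_assoc_error")
  }
  structure(list(fit = fit, n = n, coding = c(protected = 0, exposed = 1)),
            class = "eldar_interaction")
}

#' @describeIn fit_age_sun_interaction Coefficient table: term, estimate,
#'   std.error, statistic, p.value.
#' @param x An `eldar_interaction`.
#' @param ... Unused.
#' @export
tidy.eldar_interaction <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = c("(Intercept)", "age", "sun_exposed", "age:sun_exposed"),
                 estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
                 statistic = unname(sm[, 3]), p.value = unname(sm[, 4]))
}

#' @describeIn fit_age_sun_interaction One-row model summary.
#' @export
glance.eldar_interaction <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r.squared = sm$r.squared, sigma = sm$sigma,
                 n = x$n, df.residual = x$fit$df.residual)
}

#' @export
print.eldar_interaction <- function(x, ...) {
  cat(sprintf("score ~ age * sun_exposed (n = %d; exposure coded protected = 0, exposed = 1)\n",
              x$n))
  print(tidy(x))
  invisible(x)
}
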