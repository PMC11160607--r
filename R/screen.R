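#' Pearson correlation with a t-based two-sided p-value
#'
#' The single correlation engine shared by the component-time screen and the
#' validation-stage score/time associations: Pearson r plus the two-sided p
#' from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#' Degenerate inputs (fewer than 3 pairs, zero variance) yield missing r/p
#' with a warning.
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @return A one-row tibble with `r`, `p`, `n`.
#' @export
pearson_time_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("pearson_time_cor: fewer than 3 pairs or zero variance; r reported missing.")
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n))
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(r = r, p = p, n = n)
}

#' Screen components against each cohort's time axis
#'
#' Correlates every component's score with `time_value` within each dataset
#' separately (Pearson r, two-sided t-based p). Datasets without a time
#' axis (the transformation domain) are excluded from the screen.
#'
#' @param scores Score tibble from [fit_eldar()] (`$scores`) or
#'   [project_cohort()].
#' @param sheet Sample sheet covering the scored samples.
#' @return A tibble of class `eldar_screen`: one row per (component,
#'   dataset) with `domain`, `r`, `p`, `n`.
#' @seealso [classify_components()]
#' @export
correlate_components_with_time <- function(scores, sheet) {
  validate_sample_sheet(sheet)
  comp_cols <- grep("^PC\\d+$", names(scores), value = TRUE)
  if (length(comp_cols) == 0) {
    abort("correlate_components_with_time: no PC columns in scores.",
          class = "eldar_screen_error")
  }
  joined <- dplyr::inner_join(scores, sheet, by = "sample_id")
  timed <- dplyr::filter(joined, !is.na(.data$time_value))
  out <- timed |>
    tidyr::pivot_longer(dplyr::all_of(comp_cols), names_to = "component",
                        values_to = "score") |>
    dplyr::group_by(.data$component, .data$dataset, .data$domain) |>
    dplyr::reframe(pearson_time_cor(.data$score, .data$time_value)) |>
    dplyr::arrange(match(.data$component, comp_cols), .data$dataset)
  small <- dplyr::filter(out, .data$n < 3)
  if (nrow(small) > 0) {
    warn("correlate_components_with_time: some datasets have < 3 timed samples.")
  }
  structure(out, class = c("eldar_screen", class(out)))
}

#' Classify components as shared, refractory, or unclassified
#'
#' Applies the time-correlation dichotomy: a component is **shared** when
#' it rises with tissue age and passaging (r >= `t_hi` in both) and falls
#' with reprogramming (r <= -`t_hi`); **refractory** when it rises at least
#' moderately with age and passaging (r >= `t_lo`) but is *not* strongly
#' inverted by reprogramming (r > -`t_hi`); otherwise **unclassified**.
#' Per-domain r is the mean over that domain's datasets.
#'
#' @param screen An `eldar_screen` tibble containing tissue_age, passaging,
#'   and reprogramming datasets.
#' @param t_hi Strong-correlation threshold (default 0.5).
#' @param t_lo Moderate-correlation threshold (default 0.3).
#' @return A tibble with one row per component: `component`, `r_aging`,
#'   `r_passaging`, `r_reprogramming`, `class`.
#' @export
classify_components <- function(screen, t_hi = 0.5, t_lo = 0.3) {
  needed <- c("tissue_age", "passaging", "reprogramming")
  missing_dom <- setdiff(needed, unique(screen$domain))
  if (length(missing_dom) > 0) {
    abort(paste0("classify_components: screen lacks domain(s): ",
                 paste(missing_dom, collapse = ", ")), class = "eldar_screen_error")
  }
  wide <- screen |>
    dplyr::filter(.data$domain %in% needed) |>
    dplyr::group_by(.data$component, .data$domain) |>
    dplyr::summarise(r = mean(.data$r, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "domain", values_from = "r")
  wide |>
    dplyr::transmute(
      component = .data$component,
      r_aging = .data$tissue_age,
      r_passaging = .data$passaging,
      r_reprogramming = .data$reprogramming,
      class = dplyr::case_when(
        .data$tissue_age >= t_hi & .data$passaging >= t_hi &
          .data$reprogramming <= -t_hi ~ "shared",
        .data$tissue_age >= t_lo & .data$passaging >= t_lo &
          .data$reprogramming > -t_hi ~ "refractory",
        TRUE ~ "unclassified")) |>
    dplyr::arrange(match(.data$component, unique(screen$component)))
}
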