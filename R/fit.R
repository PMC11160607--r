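#' Fit the ELDAR latent decomposition on a pooled beta matrix
#'
#' Centers each CpG by its training mean and takes the thin singular value
#' decomposition of the centered sample x CpG matrix. Loadings are the
#' right singular vectors (one orthonormal column per component), training
#' scores are the centered data projected onto them, and the explained
#' variance of component k is `d_k^2 / (n - 1)` (the eigenvalues of the
#' sample covariance).
#'
#' When a sample sheet is supplied, each component's sign is oriented so
#' its score correlates non-negatively with time in the `tissue_age` domain
#' of the training pool; "increases with aging" is then a convention rather
#' than an accident of the SVD sign.
#'
#' @param beta Pooled beta matrix (CpGs x samples), no missing values.
#' @param n_components Number of components to retain; at most
#'   `min(n_cpgs, n_samples - 1)`.
#' @param sheet Optional training sample sheet used for sign orientation.
#' @param orient_domain Domain whose time axis fixes component signs.
#' @return An object of class `eldar_model` with elements `cpg_ids`,
#'   `center` (training means), `loadings` (CpG x component, orthonormal
#'   columns), `explained_variance`, `scores` (training score tibble),
#'   `sign_oriented`, `n_train`.
#' @seealso [project_cohort()], [correlate_components_with_time()]
#' @export
fit_eldar <- function(beta, n_components = 5L, sheet = NULL,
                      orient_domain = "tissue_age") {
  validate_beta_matrix(beta)
  if (anyNA(beta)) {
    abort("fit_eldar: beta matrix must have no missing values (pool first).",
          class = "eldar_fit_error")
  }
  n <- ncol(beta)
  p <- nrow(beta)
  k_max <- min(p, n - 1L)
  if (n_components > k_max) {
    abort(sprintf("fit_eldar: n_components must be <= min(n_cpgs, n_samples - 1) = %d.",
                  k_max), class = "eldar_fit_error")
  }
  center <- rowMeans(beta)
  x <- t(beta - center)                       # samples x CpGs, column-centered
  sv <- svd(x, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  # drop numerically null components (rank deficiency)
  keep <- d > max(sv$d[1], 1) * 1e-12 * sqrt(n)
  if (!all(keep)) {
    warn(sprintf("fit_eldar: rank-deficient input; returning %d of %d components.",
                 sum(keep), n_components))
  }
  k <- sum(keep)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- x %*% loadings
  ev <- d[seq_len(k)]^2 / (n - 1L)
  if (k > 0) {
    colnames(loadings) <- paste0("PC", seq_len(k))
    colnames(scores) <- paste0("PC", seq_len(k))
  }
  rownames(loadings) <- rownames(beta)

  sign_oriented <- FALSE
  if (!is.null(sheet)) {
    validate_sample_sheet(sheet)
    stopifnot(identical(sheet$sample_id, colnames(beta)))
    sel <- sheet$domain == orient_domain & !is.na(sheet$time_value)
    if (sum(sel) >= 3) {
      for (j in seq_len(k)) {
        r <- suppressWarnings(cor(scores[sel, j], sheet$time_value[sel]))
        if (!is.na(r) && r < 0) {
          loadings[, j] <- -loadings[, j]
          scores[, j] <- -scores[, j]
        }
      }
      sign_oriented <- TRUE
    } else {
      warn("fit_eldar: too few timed samples in orient_domain; signs left as-is.")
    }
  }

  structure(list(
    cpg_ids = rownames(beta),
    center = center,
    loadings = loadings,
    explained_variance = ev,
    scores = tibble::as_tibble(scores) |>
      tibble::add_column(sample_id = colnames(beta), .before = 1),
    sign_oriented = sign_oriented,
    n_train = n), class = "eldar_model")
}

#' @export
print.eldar_model <- function(x, ...) {
  cat(sprintf("ELDAR latent model: %d CpGs, %d components, %d training samples\n",
              length(x$cpg_ids), ncol(x$loadings), x$n_train))
  pct <- 100 * x$explained_variance / sum(x$explained_variance)
  cat("explained variance (% of retained): ",
      paste(sprintf("%s %.1f", colnames(x$loadings), pct), collapse = ", "), "\n")
  cat(if (x$sign_oriented) "signs oriented to increase with tissue age\n"
      else "signs not oriented\n")
  invisible(x)
}

#' @describeIn fit_eldar Per-CpG loadings in long form (one row per CpG and
#'   component).
#' @param x An `eldar_model`.
#' @param ... Unused.
#' @export
tidy.eldar_model <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "cpg_id") |>
    tidyr::pivot_longer(-"cpg_id", names_to = "component", values_to = "loading")
}

#' @describeIn fit_eldar One row per component with explained variance.
#' @export
glance.eldar_model <- function(x, ...) {
  tibble::tibble(component = colnames(x$loadings),
                 explained_variance = x$explained_variance,
                 prop_variance = x$explained_variance / sum(x$explained_variance),
                 n_train = x$n_train)
}

#' Project a cohort onto a fitted ELDAR model
#'
#' For each sample, the betas at CpGs shared with the model are centered by
#' the model's training means and multiplied into the loading rows. CpGs
#' absent from the cohort (or missing in a sample) contribute zero — i.e.
#' they are implicitly imputed at the training mean. Scores are not
#' rescaled by coverage; a per-sample `coverage_fraction` records how much
#' of the model each sample observed, with a warning below `min_coverage`.
#'
#' @param model An `eldar_model`.
#' @param beta Cohort beta matrix (CpGs x samples); may be missing model
#'   CpGs or contain NAs.
#' @param min_coverage Coverage fraction below which a warning is issued.
#' @return A tibble with `sample_id`, one column per component, and
#'   `coverage_fraction`.
#' @export
project_cohort <- function(model, beta, min_coverage = 0.5) {
  stopifnot(inherits(model, "eldar_model"))
  validate_beta_matrix(beta)
  shared <- intersect(model$cpg_ids, rownames(beta))
  if (length(shared) == 0) {
    abort("project_cohort: cohort shares no CpGs with the model.",
          class = "eldar_fit_error")
  }
  x <- beta[shared, , drop = FALSE] - model$center[shared]
  present <- !is.na(x)
  x[!present] <- 0
  scores <- t(x) %*% model$loadings[shared, , drop = FALSE]
  coverage <- colSums(present) / length(model$cpg_ids)
  if (any(coverage < min_coverage)) {
    warn(sprintf("project_cohort: %d sample(s) below %.0f%% model-CpG coverage.",
                 sum(coverage < min_coverage), 100 * min_coverage))
  }
  tibble::as_tibble(scores) |>
    tibble::add_column(sample_id = colnames(beta), .before = 1) |>
    tibble::add_column(coverage_fraction = unname(coverage))
}
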