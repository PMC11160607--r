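#' Overlap counts between latent-signature CpG sets and clock CpG lists
#'
#' Entry (s, c) is the size of the intersection of signature set s with
#' clock c. Sets and clocks are given as named lists of CpG ID vectors (a
#' clock tibble from [read_clock()] / [simulate_clock()] is also accepted
#' and split by its `clock` column).
#'
#' @param eldar_sets Named list of character vectors (e.g. the four
#'   positive/negative top-loading sets).
#' @param clocks Named list of character vectors, or a tibble with columns
#'   `clock`, `cpg_id`.
#' @return An integer matrix, sets x clocks.
#' @export
overlap_counts <- function(eldar_sets, clocks) {
  clocks <- as_clock_list(clocks)
  stopifnot(length(eldar_sets) > 0, length(clocks) > 0)
  out <- vapply(clocks, function(cl) {
    vapply(eldar_sets, function(s) length(intersect(unique(s), unique(cl))),
           integer(1))
  }, integer(length(eldar_sets)))
  matrix(out, nrow = length(eldar_sets),
         dimnames = list(names(eldar_sets), names(clocks)))
}

as_clock_list <- function(clocks) {
  if (is.data.frame(clocks)) {
    clocks <- split(clocks$cpg_id, clocks$clock)
  }
  if (any(lengths(clocks) == 0)) {
    abort("clock definitions must be non-empty.", class = "eldar_overlap_error")
  }
  lapply(clocks, unique)
}

#' Per-clock overlap percentages
#'
#' For each clock, the summed overlap counts across all signature sets,
#' divided by the clock's own size, times 100 — the only convention that
#' reproduces the reported percentages from the printed count tables. A
#' CpG appearing in two signature sets counts once per set.
#'
#' @param counts Count matrix from [overlap_counts()] (sets x clocks).
#' @param clock_sizes Named numeric vector of clock sizes (> 0), names
#'   matching the columns of `counts`.
#' @return A tibble: `clock`, `overlap_n`, `clock_size`, `percent`
#'   (rounded to one decimal).
#' @export
overlap_percent <- function(counts, clock_sizes) {
  stopifnot(all(colnames(counts) %in% names(clock_sizes)))
  sizes <- clock_sizes[colnames(counts)]
  if (any(sizes <= 0)) {
    abort("overlap_percent: clock sizes must be > 0.", class = "eldar_overlap_error")
  }
  tot <- colSums(counts)
  tibble::tibble(clock = colnames(counts), overlap_n = unname(tot),
                 clock_size = unname(sizes),
                 percent = round(100 * unname(tot) / unname(sizes), 1))
}

#' Pairwise overlap between clock CpG lists
#'
#' Symmetric count matrix with clock sizes on the diagonal.
#'
#' @param clocks Named list of CpG vectors or a tibble (`clock`, `cpg_id`).
#' @return A symmetric integer matrix.
#' @export
pairwise_clock_overlap <- function(clocks) {
  clocks <- as_clock_list(clocks)
  if (length(clocks) < 2) {
    abort("pairwise_clock_overlap: need at least two clocks.",
          class = "eldar_overlap_error")
  }
  k <- length(clocks)
  m <- matrix(0L, k, k, dimnames = list(names(clocks), names(clocks)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      m[i, j] <- length(intersect(clocks[[i]], clocks[[j]]))
    }
  }
  m
}

#' Where clock CpGs sit in a component's loading distribution
#'
#' Selecting fixed-size top/bottom sets can understate similarity, so this
#' compares the full distribution: for each clock CpG present in the model,
#' the percentile rank of its absolute loading against all model CpGs.
#' Summaries are the mean percentile, the fraction of clock CpGs above the
#' 90th percentile, and the two-sample Kolmogorov-Smirnov statistic of the
#' clock's |loading| distribution against the non-clock background.
#'
#' @param clock Character vector of clock CpG IDs, or a tibble with
#'   `cpg_id`.
#' @param model An `eldar_model`.
#' @param component Component name (e.g. `"PC1"`).
#' @return A one-row tibble: `component`, `n_in_model`, `n_absent`,
#'   `mean_percentile`, `frac_above_p90`, `ks_statistic`.
#' @export
loading_density <- function(clock, model, component) {
  stopifnot(inherits(model, "eldar_model"))
  if (is.data.frame(clock)) clock <- clock$cpg_id
  clock <- unique(clock)
  if (!component %in% colnames(model$loadings)) {
    abort("loading_density: unknown component.", class = "eldar_overlap_error")
  }
  in_model <- clock %in% model$cpg_ids
  if (!any(in_model)) {
    abort("loading_density: no clock CpG present in the model.",
          class = "eldar_overlap_error")
  }
  al <- abs(model$loadings[, component])
  pct <- ecdf(al)(al[clock[in_model]])
  is_clock <- model$cpg_ids %in% clock
  ks <- if (any(is_clock) && any(!is_clock)) {
    unname(suppressWarnings(ks.test(al[is_clock], al[!is_clock])$statistic))
  } else {
    NA_real_   # no background left to compare against
  }
  tibble::tibble(component = component,
                 n_in_model = sum(in_model), n_absent = sum(!in_model),
                 mean_percentile = mean(pct),
                 frac_above_p90 = mean(pct > 0.9),
                 ks_statistic = ks)
}
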