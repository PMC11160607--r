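#' Top- or bottom-loading CpGs of a component
#'
#' Selects the k CpGs with the largest (direction `"positive"`) or smallest
#' (direction `"negative"`) *signed* loadings on a component. Positive and
#' negative sets are built separately because methylation gainers and
#' losers with aging are characterized separately. Boundary ties are broken
#' by lexicographic CpG ID.
#'
#' @param model An `eldar_model`.
#' @param component Component name (e.g. `"PC1"`).
#' @param direction `"positive"` or `"negative"`.
#' @param k Set size; at most the number of model CpGs.
#' @return A tibble with `cpg_id`, `loading`, ordered most extreme first.
#' @export
top_loading_cpgs <- function(model, component, direction = c("positive", "negative"),
                             k = 1000L) {
  stopifnot(inherits(model, "eldar_model"))
  direction <- match.arg(direction)
  if (!component %in% colnames(model$loadings)) {
    abort(paste0("top_loading_cpgs: unknown component ", component),
          class = "eldar_enrich_error")
  }
  if (k > length(model$cpg_ids)) {
    abort("top_loading_cpgs: k exceeds the number of model CpGs.",
          class = "eldar_enrich_error")
  }
  load <- model$loadings[, component]
  ids <- model$cpg_ids
  key <- if (direction == "positive") -load else load
  ord <- order(key, ids, method = "radix")   # ties -> lexicographic CpG ID
  sel <- ord[seq_len(k)]
  tibble::tibble(cpg_id = ids[sel], loading = unname(load[sel]))
}

#' Background-normalized fold enrichment of a CpG set
#'
#' For one annotation track, computes per category the count and proportion
#' of the set falling in it, the background proportion over all annotated
#' analysis CpGs, and their ratio (fold). Categories absent from the set
#' get fold 0; categories with zero background are reported as `NA` with a
#' warning. The background universe is the full annotation (i.e. the
#' pooled-analysis CpG set), not an array manifest.
#'
#' @param cpg_set Character vector of CpG IDs (or a tibble with `cpg_id`).
#' @param annotation Annotation tibble (`cpg_id`, `island_relation`,
#'   `chrom_state`).
#' @param track `"island_relation"` or `"chrom_state"`.
#' @return A tibble: `track`, `category`, `n`, `set_size`, `prop`,
#'   `background_prop`, `fold`.
#' @export
fold_enrichment <- function(cpg_set, annotation, track = "island_relation") {
  if (is.data.frame(cpg_set)) cpg_set <- cpg_set$cpg_id
  annotation <- validate_annotation(annotation)
  if (!track %in% c("island_relation", "chrom_state")) {
    abort("fold_enrichment: track must be island_relation or chrom_state.",
          class = "eldar_enrich_error")
  }
  cpg_set <- unique(cpg_set)
  missing_cpg <- setdiff(cpg_set, annotation$cpg_id)
  if (length(missing_cpg) > 0) {
    abort(paste0("fold_enrichment: unannotated CpG(s) in set: ",
                 paste(head(missing_cpg, 5), collapse = ", ")),
          class = "eldar_enrich_error")
  }
  labels <- annotation[[track]]
  categories <- sort(unique(labels), method = "radix")
  bg <- as.vector(table(factor(labels, levels = categories))) / nrow(annotation)
  in_set <- annotation$cpg_id %in% cpg_set
  cnt <- as.vector(table(factor(labels[in_set], levels = categories)))
  prop <- cnt / length(cpg_set)
  fold <- ifelse(bg > 0, prop / bg, NA_real_)
  if (any(bg == 0)) warn("fold_enrichment: zero-background category; fold undefined.")
  tibble::tibble(track = track, category = categories, n = cnt,
                 set_size = length(cpg_set), prop = prop,
                 background_prop = bg, fold = fold)
}

#' Long-format composition report over several CpG sets
#'
#' Binds named [fold_enrichment()] results into one tidy table with a
#' percent column; percentages sum to 100 within each (set, track).
#'
#' @param results Named list of [fold_enrichment()] tibbles (typically the
#'   positive/negative sets of the shared and refractory components).
#' @return A tibble: `set`, `track`, `category`, `n`, `percent`, `fold`.
#' @export
composition_report <- function(results) {
  stopifnot(is.list(results), !is.null(names(results)))
  purrr::imap(results, function(res, nm) {
    dplyr::transmute(res, set = nm, track = .data$track,
                     category = .data$category, n = .data$n,
                     percent = 100 * .data$prop, fold = .data$fold)
  }) |>
    purrr::list_rbind()
}
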