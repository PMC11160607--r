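#' Run the full latent-signature analysis end-to-end
#'
#' Orchestrates simulate (or load) -> pool -> fit -> screen/classify ->
#' project -> associate -> enrich -> overlap and writes every stage's
#' output plus a machine-readable manifest to `out_dir`. Identical config
#' and seed give byte-identical outputs.
#'
#' In simulation mode (`config$simulation` set) the cohorts, annotation and
#' a synthetic clock are generated from one root seed, expanded to stage
#' seeds by fixed offsets: cohorts use `seed`, the annotation `seed + 1`
#' (inside [simulate_annotation()]), and the synthetic clock `seed + 2`.
#' In file mode, `config` carries paths to cohort matrices/sheets and
#' optionally an annotation and clock files.
#'
#' @param config A list. Either `simulation = sim_config(...)` or
#'   `beta_paths` + `sheet_paths` (parallel character vectors), plus
#'   optional `annotation_path`, `clock_paths`. Common fields:
#'   `n_components` (default 5), `t_hi` (0.5), `t_lo` (0.3), `top_k`
#'   (default 1000, capped at the CpG universe), `out_dir`.
#' @return Invisibly, a list with the fitted model, screen, classification,
#'   per-dataset scores, associations, enrichment report, overlap tables,
#'   and the manifest.
#' @export
run_eldar_pipeline <- function(config) {
  cfg <- utils::modifyList(list(n_components = 5L, t_hi = 0.5, t_lo = 0.3,
                                top_k = 1000L, out_dir = NULL), config)
  if (is.null(cfg$simulation) && is.null(cfg$beta_paths)) {
    abort("run_eldar_pipeline: config needs either a simulation block or beta_paths.",
          class = "eldar_pipeline_error")
  }
  if (cfg$top_k < 1) {
    abort("run_eldar_pipeline: top_k must be >= 1.", class = "eldar_pipeline_error")
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage 1: inputs -------------------------------------------------
  if (!is.null(cfg$simulation)) {
    sim <- simulate_cohorts(cfg$simulation)
    split_cols <- split(sim$sheet$sample_id, sim$sheet$dataset)
    matrices <- lapply(split_cols, function(ids) sim$beta[, ids, drop = FALSE])
    sheets <- lapply(split_cols, function(ids) {
      dplyr::filter(sim$sheet, .data$sample_id %in% ids)
    })
    annotation <- simulate_annotation(sim$truth, cfg$simulation)
    clocks <- simulate_clock(sim$truth,
                             n_hits = min(50L, ceiling(cfg$simulation$n_cpgs / 10)),
                             n_random = min(50L, cfg$simulation$n_cpgs -
                                              ceiling(cfg$simulation$n_cpgs / 10)),
                             seed = cfg$simulation$seed + 2L)
    truth <- sim$truth
  } else {
    matrices <- lapply(cfg$beta_paths, read_beta_matrix)
    sheets <- lapply(cfg$sheet_paths, read_sample_sheet)
    annotation <- if (!is.null(cfg$annotation_path)) read_annotation(cfg$annotation_path)
    clocks <- if (!is.null(cfg$clock_paths)) {
      purrr::list_rbind(lapply(cfg$clock_paths, read_clock))
    }
    truth <- NULL
  }

  # --- stage 2: pool ---------------------------------------------------
  pooled <- intersect_and_pool(matrices, sheets)

  # --- stage 3: fit ----------------------------------------------------
  model <- fit_eldar(pooled$beta, n_components = cfg$n_components,
                     sheet = pooled$sheet)

  # --- stage 4: screen + classify -------------------------------------
  screen <- correlate_components_with_time(model$scores, pooled$sheet)
  classes <- classify_components(screen, t_hi = cfg$t_hi, t_lo = cfg$t_lo)

  # --- stage 5: project each cohort -----------------------------------
  scores <- purrr::imap(matrices, function(m, nm) {
    project_cohort(model, m) |> tibble::add_column(dataset = nm, .before = 1)
  }) |> purrr::list_rbind()

  # --- stage 6: associations ------------------------------------------
  assoc <- score_time_correlation(
    dplyr::select(scores, -"dataset", -"coverage_fraction"), pooled$sheet)

  # --- stage 7: enrichment --------------------------------------------
  k <- cfg$top_k
  key_components <- key_component_pair(classes)
  sets <- list()
  for (comp in key_components) {
    for (dir_ in c("positive", "negative")) {
      sets[[paste0(comp, "_", dir_)]] <- top_loading_cpgs(model, comp, dir_, k)$cpg_id
    }
  }
  enrichment <- NULL
  if (!is.null(annotation)) {
    results <- list()
    for (nm in names(sets)) {
      results[[nm]] <- dplyr::bind_rows(
        fold_enrichment(sets[[nm]], annotation, "island_relation"),
        fold_enrichment(sets[[nm]], annotation, "chrom_state"))
    }
    enrichment <- composition_report(results)
  }

  # --- stage 8: clock overlap -----------------------------------------
  overlap <- NULL
  if (!is.null(clocks)) {
    counts <- overlap_counts(sets, clocks)
    clock_list <- as_clock_list(clocks)
    sizes <- lengths(clock_list)
    overlap <- list(counts = counts,
                    percent = overlap_percent(counts, sizes),
                    union_size = length(unique(unlist(sets))),
                    pairwise = if (length(clock_list) >= 2)
                      pairwise_clock_overlap(clock_list))
  }

  result <- list(model = model, screen = screen, classification = classes,
                 scores = scores, associations = assoc,
                 enrichment = enrichment, overlap = overlap,
                 sets = sets, annotation = annotation, truth = truth,
                 pooled_sheet = pooled$sheet)

  if (!is.null(out_dir)) {
    write_eldar_model(model, file.path(out_dir, "model"))
    readr::write_csv(screen, file.path(out_dir, "screen.csv"))
    readr::write_csv(classes, file.path(out_dir, "classification.csv"))
    readr::write_csv(scores, file.path(out_dir, "scores.csv"))
    readr::write_csv(assoc, file.path(out_dir, "associations.csv"))
    if (!is.null(enrichment)) {
      readr::write_csv(enrichment, file.path(out_dir, "enrichment.csv"))
    }
    if (!is.null(overlap)) {
      readr::write_csv(tibble::as_tibble(overlap$counts, rownames = "set"),
                       file.path(out_dir, "overlap_counts.csv"))
      readr::write_csv(overlap$percent, file.path(out_dir, "overlap_percent.csv"))
      if (!is.null(overlap$pairwise)) {
        readr::write_csv(tibble::as_tibble(overlap$pairwise, rownames = "clock"),
                         file.path(out_dir, "clock_pairwise.csv"))
      }
    }
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"),
                  method = "radix")
    manifest <- list(
      stages = c("inputs", "pool", "fit", "screen", "project", "associate",
                 "enrich", "overlap"),
      n_components = cfg$n_components, t_hi = cfg$t_hi, t_lo = cfg$t_lo,
      top_k = k,
      seed = if (!is.null(cfg$simulation)) cfg$simulation$seed,
      package_version = as.character(utils::packageVersion("eldar")),
      checksums = as.list(tools::md5sum(file.path(out_dir, files))) |>
        setNames(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <- manifest
  }
  invisible(result)
}

# The two components whose CpGs are characterized downstream: the
# best shared and best refractory components when classified, else the
# top two by explained variance.
key_component_pair <- function(classes) {
  shared <- classes$component[classes$class == "shared"]
  refr <- classes$component[classes$class == "refractory"]
  out <- c(head(shared, 1), head(refr, 1))
  if (length(out) < 2) {
    out <- unique(c(out, classes$component))[1:2]
  }
  out
}
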