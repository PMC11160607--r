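#' Read and write beta-value matrices
#'
#' Beta matrices travel as TSV with a `cpg_id` first column and one column
#' per sample. Reading validates identifiers (unique, non-empty) and values
#' (in \[0, 1\] or missing) and reports the offending CpG/sample on failure;
#' a write/read round trip reproduces values and ordering exactly.
#'
#' @param path File path.
#' @param beta Numeric matrix, rownames = CpG IDs, colnames = sample IDs.
#' @return `read_beta_matrix()` returns the validated numeric matrix;
#'   `write_beta_matrix()` returns `path` invisibly.
#' @export
read_beta_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    cpg_id = readr::col_character(), .default = readr::col_double()))
  if (!"cpg_id" %in% names(df)) {
    abort("read_beta_matrix: first column must be 'cpg_id'.", class = "eldar_io_error")
  }
  beta <- as.matrix(df[-1])
  rownames(beta) <- df$cpg_id
  validate_beta_matrix(beta)
  beta
}

#' @rdname read_beta_matrix
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  df <- tibble::as_tibble(beta, rownames = "cpg_id")
  readr::write_tsv(df, path)
  invisible(path)
}

validate_beta_matrix <- function(beta) {
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    abort("beta matrix must carry CpG rownames and sample colnames.",
          class = "eldar_io_error")
  }
  dup_r <- unique(rownames(beta)[duplicated(rownames(beta))])
  dup_c <- unique(colnames(beta)[duplicated(colnames(beta))])
  if (length(dup_r) > 0) {
    abort(paste0("duplicate CpG IDs: ", paste(head(dup_r, 5), collapse = ", ")),
          class = "eldar_io_error")
  }
  if (length(dup_c) > 0) {
    abort(paste0("duplicate sample IDs: ", paste(head(dup_c, 5), collapse = ", ")),
          class = "eldar_io_error")
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("beta out of [0, 1] at CpG %s, sample %s (value %.4g)",
                  rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
                  beta[bad[1, 1], bad[1, 2]]),
          class = "eldar_io_error")
  }
  invisible(beta)
}

#' Read and write sample sheets
#'
#' Sample sheets are CSV with columns `sample_id`, `dataset`, `domain`,
#' `time_value`, `time_units`, `sun_exposed`, `condition`. The domain must
#' be one of `tissue_age`, `passaging`, `reprogramming`, `transformation`;
#' `time_value` must be present exactly for the timed domains (the
#' transformation domain lacks a time axis).
#'
#' @param path File path.
#' @param sheet A sample-sheet tibble.
#' @return `read_sample_sheet()` returns a validated tibble;
#'   `write_sample_sheet()` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), dataset = readr::col_character(),
    domain = readr::col_character(), time_value = readr::col_double(),
    time_units = readr::col_character(), sun_exposed = readr::col_logical(),
    condition = readr::col_character()))
  validate_sample_sheet(sheet)
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  readr::write_csv(sheet, path)
  invisible(path)
}

validate_sample_sheet <- function(sheet) {
  needed <- c("sample_id", "dataset", "domain", "time_value", "time_units",
              "sun_exposed", "condition")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet lacks columns: ", paste(missing_cols, collapse = ", ")),
          class = "eldar_io_error")
  }
  if (anyDuplicated(sheet$sample_id)) {
    abort("sample sheet has duplicate sample_id values.", class = "eldar_io_error")
  }
  bad_domain <- setdiff(unique(sheet$domain), ELDAR_DOMAINS)
  if (length(bad_domain) > 0) {
    abort(paste0("unknown domain '", bad_domain[1], "'; allowed: ",
                 paste(ELDAR_DOMAINS, collapse = ", ")), class = "eldar_io_error")
  }
  timed <- sheet$domain != "transformation"
  if (any(timed & is.na(sheet$time_value))) {
    abort("time_value missing for a sample in a timed domain.",
          class = "eldar_io_error")
  }
  if (any(!timed & !is.na(sheet$time_value))) {
    abort("transformation samples must have a missing time_value.",
          class = "eldar_io_error")
  }
  invisible(sheet)
}

#' Read and write CpG annotations
#'
#' BED-like TSV with columns `cpg_id`, `island_relation`, `chrom_state`.
#' Island relations must be one of `island`, `shore`, `shelf`, `open_sea`;
#' chromatin-state labels are free-form. Duplicate CpG rows are
#' deduplicated with a warning.
#'
#' @param path File path.
#' @param annotation An annotation tibble.
#' @return `read_annotation()` returns a validated tibble;
#'   `write_annotation()` returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}

validate_annotation <- function(ann) {
  needed <- c("cpg_id", "island_relation", "chrom_state")
  if (!all(needed %in% names(ann))) {
    abort("annotation needs columns cpg_id, island_relation, chrom_state.",
          class = "eldar_io_error")
  }
  bad <- setdiff(unique(ann$island_relation), ISLAND_RELATIONS)
  if (length(bad) > 0) {
    abort(paste0("unknown island_relation '", bad[1], "'; allowed: ",
                 paste(ISLAND_RELATIONS, collapse = ", ")), class = "eldar_io_error")
  }
  if (anyDuplicated(ann$cpg_id)) {
    warn("annotation has duplicate cpg_id rows; keeping the first of each.")
    ann <- ann[!duplicated(ann$cpg_id), ]
  }
  ann
}

#' Read and write clock CpG lists
#'
#' Plain text: the first line names the clock, each following line is one
#' CpG ID. Duplicates are removed with a warning.
#'
#' @param path File path.
#' @param clock A tibble with columns `clock`, `cpg_id` (a single clock).
#' @return `read_clock()` returns a tibble with columns `clock`, `cpg_id`;
#'   `write_clock()` returns `path` invisibly.
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  if (length(lines) < 1 || lines[1] == "") {
    abort("clock file must start with a header line naming the clock.",
          class = "eldar_io_error")
  }
  name <- sub("^#\\s*", "", lines[1])
  cpgs <- lines[-1]
  cpgs <- cpgs[cpgs != ""]
  if (anyDuplicated(cpgs)) {
    warn(sprintf("clock '%s' has duplicate CpGs; deduplicated.", name))
    cpgs <- unique(cpgs)
  }
  tibble::tibble(clock = name, cpg_id = cpgs)
}

#' @rdname read_clock
#' @export
write_clock <- function(clock, path) {
  stopifnot(all(c("clock", "cpg_id") %in% names(clock)),
            length(unique(clock$clock)) == 1)
  writeLines(c(clock$clock[1], clock$cpg_id), path)
  invisible(path)
}

#' Read and write truth ledgers
#'
#' The simulation ledger travels as a single long TSV with columns
#' `record_type` (cpg / sample / batch), `id`, `field`, `value`, so one
#' plain-text file reconstructs the full ground truth.
#'
#' @param truth An `eldar_truth` ledger.
#' @param path File path.
#' @return `read_truth_ledger()` returns an `eldar_truth` list (without the
#'   originating config); `write_truth_ledger()` returns `path` invisibly.
#' @export
write_truth_ledger <- function(truth, path) {
  stopifnot(inherits(truth, "eldar_truth"))
  long <- dplyr::bind_rows(
    tidyr::pivot_longer(truth$cpgs, -"cpg_id", names_to = "field") |>
      dplyr::transmute(record_type = "cpg", id = .data$cpg_id,
                       field = .data$field, value = .data$value),
    tidyr::pivot_longer(truth$samples, -"sample_id", names_to = "field") |>
      dplyr::transmute(record_type = "sample", id = .data$sample_id,
                       field = .data$field, value = .data$value),
    dplyr::transmute(truth$batch, record_type = "batch", id = .data$dataset,
                     field = "offset", value = .data$offset))
  readr::write_tsv(long, path)
  invisible(path)
}

#' @rdname write_truth_ledger
#' @export
read_truth_ledger <- function(path) {
  long <- readr::read_tsv(path, col_types = readr::cols(
    record_type = readr::col_character(), id = readr::col_character(),
    field = readr::col_character(), value = readr::col_double()))
  wide <- function(type, id_col) {
    long |>
      dplyr::filter(.data$record_type == type) |>
      tidyr::pivot_wider(id_cols = "id", names_from = "field") |>
      dplyr::rename(!!id_col := "id")
  }
  structure(list(cpgs = wide("cpg", "cpg_id"),
                 samples = wide("sample", "sample_id"),
                 batch = long |>
                   dplyr::filter(.data$record_type == "batch") |>
                   dplyr::transmute(dataset = .data$id, offset = .data$value),
                 config = NULL),
            class = "eldar_truth")
}

#' Pool cohorts on their common complete CpGs
#'
#' Restricts each cohort to the CpGs present and non-missing in every
#' cohort, sorts CpGs lexicographically (C locale, for reproducible loading
#' order), column-concatenates the matrices, and row-binds the sheets.
#' Any CpG missing in any training sample is dropped, keeping the
#' decomposition exact on complete cases.
#'
#' @param matrices List of beta matrices.
#' @param sheets List of matching sample-sheet tibbles (same order).
#' @return A list with `beta` (pooled matrix) and `sheet` (merged tibble).
#' @export
intersect_and_pool <- function(matrices, sheets) {
  if (length(matrices) < 2) {
    abort("intersect_and_pool: need at least two cohorts.", class = "eldar_io_error")
  }
  stopifnot(length(matrices) == length(sheets))
  complete_sets <- lapply(matrices, function(m) {
    rownames(m)[rowSums(is.na(m)) == 0]
  })
  shared <- Reduce(intersect, complete_sets)
  if (length(shared) == 0) {
    counts <- vapply(complete_sets, length, integer(1))
    abort(paste0("intersect_and_pool: empty CpG intersection; per-cohort complete ",
                 "CpG counts: ", paste(counts, collapse = ", ")),
          class = "eldar_io_error")
  }
  shared <- sort(shared, method = "radix")
  beta <- do.call(cbind, lapply(matrices, function(m) m[shared, , drop = FALSE]))
  validate_beta_matrix(beta)
  sheet <- dplyr::bind_rows(sheets)
  if (!identical(sheet$sample_id, colnames(beta))) {
    abort("intersect_and_pool: sheet sample_id order does not match matrix columns.",
          class = "eldar_io_error")
  }
  list(beta = beta, sheet = sheet)
}
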