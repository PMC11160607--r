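#' Serialize a fitted ELDAR model to a directory
#'
#' Writes three plain-text files: `loadings.tsv` (cpg_id plus one column
#' per component), `means.tsv` (cpg_id, train_mean), and `model.json`
#' (explained variance, sign orientation, training size). The reader
#' reconstructs an `eldar_model` usable for projection.
#'
#' @param model An `eldar_model`.
#' @param dir Output directory (created if absent).
#' @return `write_eldar_model()` returns `dir` invisibly;
#'   `read_eldar_model()` returns an `eldar_model` (training scores are not
#'   serialized).
#' @export
write_eldar_model <- function(model, dir) {
  stopifnot(inherits(model, "eldar_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble::as_tibble(model$loadings, rownames = "cpg_id"),
                   file.path(dir, "loadings.tsv"))
  readr::write_tsv(tibble::tibble(cpg_id = model$cpg_ids,
                                  train_mean = unname(model$center)),
                   file.path(dir, "means.tsv"))
  meta <- list(explained_variance = model$explained_variance,
               sign_oriented = model$sign_oriented,
               n_train = model$n_train,
               components = colnames(model$loadings))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_eldar_model
#' @export
read_eldar_model <- function(dir) {
  ldf <- readr::read_tsv(file.path(dir, "loadings.tsv"), col_types = readr::cols(
    cpg_id = readr::col_character(), .default = readr::col_double()))
  mdf <- readr::read_tsv(file.path(dir, "means.tsv"), col_types = readr::cols(
    cpg_id = readr::col_character(), train_mean = readr::col_double()))
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  stopifnot(identical(ldf$cpg_id, mdf$cpg_id))
  loadings <- as.matrix(ldf[-1])
  rownames(loadings) <- ldf$cpg_id
  structure(list(cpg_ids = ldf$cpg_id,
                 center = setNames(mdf$train_mean, mdf$cpg_id),
                 loadings = loadings,
                 explained_variance = meta$explained_variance,
                 scores = NULL,
                 sign_oriented = isTRUE(meta$sign_oriented),
                 n_train = meta$n_train), class = "eldar_model")
}
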