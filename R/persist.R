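#' Model archives
#'
#' Models are saved as a single JSON document: a `metadata` block (chain,
#' V gene, universe, threshold, training counts, format version) plus the
#' serialized forest. The metadata can be read without touching the forest
#' payload, and loading refuses archives of an incompatible format version.
#'
#' @name model_archive
NULL

ARCHIVE_FORMAT <- "abhumanize-model"
ARCHIVE_VERSION <- 1L

#' Save a model to a JSON archive
#'
#' @param model a `humanness_model` or `chain_type_model`.
#' @param path output file (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "humanness_model"))
  doc <- list(
    format = ARCHIVE_FORMAT, version = ARCHIVE_VERSION,
    metadata = list(
      class = class(model)[1L], chain = model$chain,
      v_gene = if (is.null(model$v_gene)) NA_character_ else model$v_gene,
      universe = model$universe,
      # doubles that must survive the round trip bitwise are written as
      # %.17g strings (JSON numbers lose the last ulp through jsonlite)
      threshold = if (is.na(model$threshold)) NA_character_
                  else sprintf("%.17g", model$threshold),
      n_estimators = model$n_estimators, meta = model$meta),
    metrics = model$metrics,
    feature_freq_pos = model$feature_freq_pos,
    feature_freq_neg = model$feature_freq_neg,
    forest = list(n_features = model$forest$n_features,
                  importance = model$forest$importance,
                  trees = lapply(model$forest$trees, function(t) {
                    t$value <- sprintf("%.17g", t$value)
                    t
                  })))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read archive metadata without deserializing the forest
#'
#' @param path archive file.
#' @return the metadata list (chain, v_gene, universe, threshold, ...).
#' @export
read_model_metadata <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("unreadable model archive ", path,
                                           ": ", conditionMessage(e)))
  if (!identical(doc$format, ARCHIVE_FORMAT)) {
    stop(path, " is not a model archive (format field missing or wrong)")
  }
  if (!identical(as.integer(doc$version), ARCHIVE_VERSION)) {
    stop("incompatible archive version ", doc$version, " (supported: ",
         ARCHIVE_VERSION, ")")
  }
  doc$metadata
}

#' Load a model from a JSON archive
#'
#' @param path archive file written by [save_model()].
#' @return the model; scores are bitwise-identical to the saved model's.
#' @export
load_model <- function(path) {
  meta <- read_model_metadata(path)  # validates format + version
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(seq_len(nrow_safe(doc$forest$trees)), function(i) {
    t <- if (is.data.frame(doc$forest$trees)) {
      lapply(doc$forest$trees[i, ], `[[`, 1L)
    } else {
      doc$forest$trees[[i]]
    }
    list(feature = as.integer(t$feature), left = as.integer(t$left),
         right = as.integer(t$right), value = as.numeric(t$value))
  })
  forest <- list(trees = trees,
                 importance = as.numeric(doc$forest$importance),
                 n_features = as.integer(doc$forest$n_features))
  threshold <- doc$metadata$threshold
  model <- list(chain = meta$chain, v_gene = meta$v_gene, forest = forest,
                n_estimators = as.integer(meta$n_estimators),
                universe = as.character(meta$universe),
                threshold = if (is.null(threshold) || is.na(threshold))
                              NA_real_ else as.numeric(threshold),
                metrics = doc$metrics,
                feature_freq_pos = as.numeric(doc$feature_freq_pos),
                feature_freq_neg = as.numeric(doc$feature_freq_neg),
                meta = meta$meta)
  cls <- meta$class
  class(model) <- if (identical(cls, "chain_type_model")) {
    c("chain_type_model", "humanness_model")
  } else {
    "humanness_model"
  }
  model
}

nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
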