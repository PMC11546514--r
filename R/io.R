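# Dataset / prediction file I/O, checkpoints, and run manifests.

#' Read a SMILES-pair file
#'
#' Comma-delimited UTF-8 text with a header. Unlabeled files need columns
#' `smiles_a` and `smiles_b`; labeled files additionally need a 0/1
#' `label` column. Every SMILES is validated lexically; offending rows are
#' reported by number.
#'
#' @param path File path.
#' @param labeled Whether a `label` column is required (default `TRUE`).
#' @return Data frame with the validated rows.
#' @export
read_pairs <- function(path, labeled = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("smiles_a", "smiles_b", if (labeled) "label")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    for (col in c("smiles_a", "smiles_b")) {
      err <- tryCatch({
        pretokenize(df[[col]][[i]])
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(err)) {
        problems <- c(problems, sprintf("row %d (%s): %s", i, col, err))
      }
    }
    if (labeled && !(df$label[[i]] %in% c(0, 1))) {
      problems <- c(problems,
                    sprintf("row %d: label \"%s\" is not 0 or 1",
                            i, df$label[[i]]))
    }
  }
  if (length(problems) > 0L) {
    stop(paste0("invalid records in ", path, ":\n  ",
                paste(problems, collapse = "\n  ")), call. = FALSE)
  }
  if (labeled) df$label <- as.integer(df$label)
  df
}

#' Write a SMILES-pair dataset
#'
#' Writes the `smiles_a,smiles_b[,label]` columns as comma-delimited UTF-8
#' text with a header; [read_pairs()] inverts it row for row.
#'
#' @param dataset Data frame with the pair columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(dataset, path) {
  cols <- intersect(c("smiles_a", "smiles_b", "label"), names(dataset))
  utils::write.csv(dataset[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the model parameters (with the embedded
#' configuration), the vocabulary, and the training history, and is
#' validated for shape consistency on load.
#'
#' @param model A `ddi_model`.
#' @param vocab The `ddi_vocab` the model was trained with.
#' @param history Optional training history data frame.
#' @param path Checkpoint file path (`.rds`).
#' @return `path` invisibly for save; a list with `model`, `vocab`,
#'   `history` for load.
#' @export
save_checkpoint <- function(model, vocab, path, history = NULL) {
  stopifnot(inherits(model, "ddi_model"), inherits(vocab, "ddi_vocab"))
  saveRDS(list(model = model, vocab = vocab, history = history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("no such checkpoint: %s", path), call. = FALSE)
  }
  ck <- readRDS(path)
  if (!inherits(ck$model, "ddi_model") || !inherits(ck$vocab, "ddi_vocab")) {
    stop(sprintf("%s is not a ddipair checkpoint", path), call. = FALSE)
  }
  cfg <- ck$model$config
  if (nrow(ck$model$branch_a$emb) != cfg$vocab_size ||
      cfg$vocab_size != vocab_size(ck$vocab)) {
    stop("checkpoint is inconsistent: embedding/vocabulary size mismatch",
         call. = FALSE)
  }
  ck
}

#' Write a run manifest
#'
#' Records everything needed to re-execute a command bit-identically:
#' the command name, configuration snapshot, seeds, and MD5 hashes of the
#' input and output files. Deliberately carries no wall-clock timestamp so
#' a rerun under the same seed produces an identical manifest.
#'
#' @param path Manifest output path (JSON).
#' @param command Command name.
#' @param config Configuration snapshot (any JSON-serializable list).
#' @param inputs,outputs Character vectors of file paths to hash.
#' @param metrics Optional named list of metric values.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, inputs = character(0),
                           outputs = character(0), metrics = NULL) {
  hash_files <- function(paths) {
    if (length(paths) == 0L) return(stats::setNames(list(), character(0)))
    # keyed by file name, not absolute path, so relocated reruns compare equal
    stats::setNames(as.list(unname(tools::md5sum(paths))), basename(paths))
  }
  manifest <- list(command = command,
                   package_version = as.character(utils::packageVersion("ddipair")),
                   config = config,
                   inputs = hash_files(inputs),
                   outputs = hash_files(outputs),
                   metrics = metrics)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
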