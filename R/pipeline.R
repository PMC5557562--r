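# File-oriented orchestration: train from FASTA + site table and write all
# artifacts; score arginines of a FASTA with a saved model. These back the
# thin command-line script shipped in inst/cli/.

#' Run the full training pipeline from files
#'
#' Reads annotated proteins, fits [metharg()], and writes to `out_dir`:
#' the selection-sweep table (`sweep.tsv`), the feature ranking of the
#' winning negative subset (`ranking.tsv`), the selected feature subset
#' (`selected_features.json`), the held-out ROC points
#' (`roc.tsv`), the model archive (`model.json`), the held-out evaluation
#' (`evaluation.json`) and a provenance record (`provenance.json`: options,
#' seed, package and R versions) sufficient to reproduce the run.
#'
#' @param fasta_path,sites_path training inputs (see
#'   [read_annotated_proteins()]).
#' @param out_dir output directory, created if needed.
#' @param ... passed to [metharg()] (e.g. `window_length`, `config`,
#'   `subset_sizes`).
#' @param seed integer seed.
#' @return the `metharg` fit, invisibly.
#' @export
run_training_pipeline <- function(fasta_path, sites_path, out_dir, ...,
                                  seed = 1) {
  proteins <- read_annotated_proteins(fasta_path, sites_path)
  fit <- metharg(proteins, ..., seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$sweep, file.path(out_dir, "sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rk <- fit$rankings[[fit$negative_subset]]$entries
  rk$rank <- seq_len(nrow(rk))
  utils::write.table(rk[, c("rank", "feature", "score")],
                     file.path(out_dir, "ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$test_roc, file.path(out_dir, "roc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fit$selected_features,
                       file.path(out_dir, "selected_features.json"))
  write_metharg(fit, file.path(out_dir, "model.json"))
  jsonlite::write_json(fit$test_report[c("tp", "tn", "fp", "fn", "Sn", "Sp",
                                         "Acc", "MCC", "auc")],
                       file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  dots <- list(...)
  jsonlite::write_json(
    list(fasta = fasta_path, sites = sites_path, seed = seed,
         options = dots[vapply(dots, is.atomic, TRUE)],
         window_length = fit$window_length,
         package_version = as.character(utils::packageVersion("metharg")),
         r_version = R.version.string),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Score every arginine of a FASTA with a saved model
#'
#' @param model a `metharg` fit or the path to a `model.json` archive.
#' @param fasta_path FASTA file of query sequences.
#' @param out_path optional TSV output path (columns `protein_id`,
#'   `position`, `window`, `score`, `label`).
#' @return the prediction data frame, invisibly when `out_path` is given.
#' @export
predict_sites <- function(model, fasta_path, out_path = NULL) {
  if (is.character(model)) model <- read_metharg(model)
  stopifnot(inherits(model, "metharg"))
  res <- predict(model, fasta_path)
  if (!is.null(out_path)) {
    utils::write.table(res, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(res))
  }
  res
}
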