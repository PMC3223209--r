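#' Fit the barcode divergence analysis to a reference library
#'
#' The central model-fitting step: computes the pairwise distance matrix
#' under the chosen model, partitions every species into barcode
#' clusters at the divergence threshold (flagging putative cryptic
#' species and attaching interim names), and summarises divergence by
#' taxonomic rank with the flagged species excluded.  The returned
#' object supports `print()`, `summary()`, `predict()` (query
#' identification) and `plot()` (neighbour-joining tree).
#'
#' @param ref A `barcode_ref` from [build_library()].
#' @param model Distance model, `"k2p"` (default) or `"p"`.
#' @param threshold Cluster/assignment threshold in substitutions/site.
#' @param min_overlap Minimum comparable sites per pair.
#' @param exclude_policy Passed to [summarize_ranks()].
#' @return Object of class `barcode_fit` with elements `ref`, `dist`,
#'   `splits`, `flagged`, `ranks`, `threshold`, `min_overlap`, `model`,
#'   `call`.
#' @examples
#' sim <- simulate_library(sim_config(n_genera = 3, species_per_genus = 2,
#'                                    specimens_per_species = 3, seed = 42))
#' fit <- barcode_fit(sim$ref)
#' fit
#' summary(fit)
#' @export
barcode_fit <- function(ref, model = c("k2p", "p"), threshold = 0.02,
                        min_overlap = 100,
                        exclude_policy = c("within_species", "all")) {
  stopifnot(inherits(ref, "barcode_ref"))
  model <- match.arg(model)
  exclude_policy <- match.arg(exclude_policy)
  stopifnot(threshold > 0, threshold < 0.5)
  dmat <- distance_matrix(ref, model = model, min_overlap = min_overlap)
  splits <- detect_splits(ref, dmat, threshold = threshold)
  flagged <- flagged_species(splits)
  ranks <- summarize_ranks(ref, dmat, exclude = flagged,
                           exclude_policy = exclude_policy)
  structure(list(ref = ref, dist = dmat, splits = splits, flagged = flagged,
                 ranks = ranks, threshold = threshold,
                 min_overlap = min_overlap, model = model,
                 call = match.call()),
            class = "barcode_fit")
}

#' @export
print.barcode_fit <- function(x, ...) {
  cat("Barcode divergence analysis\n")
  cat(sprintf("  model: %s, threshold: %.2f%%, min overlap: %d sites\n",
              toupper(x$model), 100 * x$threshold, x$min_overlap))
  cat(sprintf("  library: %d specimens, %d species\n",
              nrow(x$ref$records), length(x$ref$species_index)))
  cat(sprintf("  species with multiple barcode clusters: %d\n",
              length(x$flagged)))
  if (length(x$flagged)) {
    cat("   ", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.barcode_fit <- function(object, ...) {
  out <- list(ranks = object$ranks, splits = object$splits,
              flagged = object$flagged,
              n_specimens = nrow(object$ref$records),
              n_species = length(object$ref$species_index))
  class(out) <- "summary.barcode_fit"
  out
}

#' @export
print.summary.barcode_fit <- function(x, ...) {
  cat(sprintf("Library of %d specimens in %d species\n\n",
              x$n_specimens, x$n_species))
  print(x$ranks)
  cat("\n")
  print(x$splits)
  invisible(x)
}

#' Identify query sequences against a fitted analysis
#'
#' @param object A `barcode_fit`.
#' @param newdata Query data.frame with `specimen_id` and `sequence`
#'   columns; defaults to the larval queries set aside by
#'   [build_library()].
#' @param ... Unused.
#' @return An `identification_set` (see [batch_identify()]).
#' @export
predict.barcode_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$ref$queries
  batch_identify(newdata, object$ref, splits = object$splits,
                 threshold = object$threshold,
                 min_overlap = object$min_overlap)
}

#' Plot the neighbour-joining tree of a fitted analysis
#'
#' @param x A `barcode_fit`.
#' @param ... Passed to [ape::plot.phylo()].
#' @return Invisibly, the `phylo` tree.
#' @export
plot.barcode_fit <- function(x, ...) {
  tree <- nj_tree(x$dist)
  ape::plot.phylo(tree, ...)
  invisible(tree)
}

#' Run the full barcoding pipeline from files on disk
#'
#' Reads sequences and metadata, builds the library, fits the divergence
#' analysis, builds the NJ tree, identifies larval queries, and writes a
#' report bundle: PHYLIP + long-form distances, Newick tree, the
#' split/rank/identification tables and a run log recording every
#' filter and clamp event.  Any stage error aborts with a stage-named
#' message and removes partial outputs.
#'
#' @param fasta Path to the FASTA file (adults and larvae together).
#' @param metadata Path to the metadata TSV.
#' @param out_dir Output directory.
#' @param threshold Divergence threshold in substitutions/site.
#' @param min_length Minimum informative length for adults.
#' @param min_overlap Minimum comparable sites per pair.
#' @param model Distance model.
#' @return Invisibly, a named vector of report paths.
#' @export
run_pipeline <- function(fasta, metadata, out_dir, threshold = 0.02,
                         min_length = 267, min_overlap = 100,
                         model = c("k2p", "p")) {
  model <- match.arg(model)
  stopifnot(threshold > 0, threshold < 0.5)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(distances_phylip = file.path(out_dir, "distances.phy"),
             distances_long = file.path(out_dir, "distances_long.tsv"),
             tree = file.path(out_dir, "tree.nwk"),
             splits = file.path(out_dir, "split_table.tsv"),
             ranks = file.path(out_dir, "rank_table.tsv"),
             id_summary = file.path(out_dir, "identification_summary.tsv"),
             id_detail = file.path(out_dir, "identification_detail.tsv"),
             log = file.path(out_dir, "run_log.txt"))
  log_collect_start()
  stage <- "setup"
  ok <- FALSE
  on.exit({
    log_collect_stop()
    if (!ok) unlink(paths[file.exists(paths)])
  })
  result <- tryCatch({
    stage <- "read_fasta"
    seqs <- read_fasta(fasta)
    stage <- "read_metadata"
    md <- read_metadata(metadata)
    stage <- "build_library"
    ref <- build_library(seqs, md, min_length = min_length)
    stage <- "fit"
    fit <- barcode_fit(ref, model = model, threshold = threshold,
                       min_overlap = min_overlap)
    stage <- "nj_tree"
    tree <- nj_tree(fit$dist)
    stage <- "identify"
    idres <- predict(fit)
    stage <- "reports"
    write_phylip(fit$dist, paths["distances_phylip"])
    write_dist_long(fit$dist, paths["distances_long"])
    write_newick(tree, decimals = 6, path = paths["tree"])
    write_split_table(fit$splits, paths["splits"])
    write_rank_table(fit$ranks, paths["ranks"])
    write_identification_tables(idres, paths["id_summary"], paths["id_detail"])
    list(fit = fit, tree = tree, identifications = idres)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  header <- c(sprintf("coibarcode %s run log",
                      as.character(utils::packageVersion("coibarcode"))),
              sprintf("inputs: fasta=%s metadata=%s", fasta, metadata),
              sprintf("settings: model=%s threshold=%g min_length=%d min_overlap=%d",
                      model, threshold, min_length, min_overlap),
              "events:")
  writeLines(c(header, paste0("  ", .cb_state$log %||% character(0))), paths["log"])
  ok <- TRUE
  invisible(structure(paths, result = result))
}
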