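#' Single-linkage components at a divergence threshold
#'
#' Builds the graph joining every pair of specimens with distance
#' `<= threshold` and returns its connected components.  This is the
#' single-linkage ("chaining") reading of barcode clusters: two clusters
#' are separated only when every cross-pair exceeds the threshold.
#'
#' @param ids Specimen ids to partition.
#' @param dmat A `barcode_dist` covering the ids.
#' @param threshold Join threshold in substitutions/site (default 0.02;
#'   a pair at exactly the threshold stays together).
#' @return List of character vectors (disjoint id sets, union = `ids`),
#'   ordered by decreasing size then smallest member id; members sorted.
#' @export
threshold_components <- function(ids, dmat, threshold = 0.02) {
  sub <- dist_subset(dmat, ids)
  m <- length(ids)
  if (m == 1L) return(list(ids))
  off <- upper.tri(sub$flags)
  if (any(sub$flags[off] != "ok")) {
    bad <- which(sub$flags != "ok" & off, arr.ind = TRUE)
    pairs <- apply(bad, 1L, function(ij) paste0(ids[ij[1]], "/", ids[ij[2]]))
    stop("flagged pair(s) among ids: ", paste(pairs, collapse = ", "),
         call. = FALSE)
  }
  # union-find over threshold edges
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  edges <- which(sub$d <= threshold & off, arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(m), find, integer(1))
  groups <- split(ids, comp)
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, `[`, character(1), 1L))
  unname(groups[ord])
}

#' Partition every species into barcode clusters and flag splits
#'
#' Applies [threshold_components()] within each species of the library.
#' Species whose specimens fall into two or more clusters at the
#' threshold are flagged as putative cryptic species and their clusters
#' receive interim names via [assign_interim_names()].  Single-specimen
#' species are a single cluster and never flagged.
#'
#' @param ref A `barcode_ref`.
#' @param dmat A `barcode_dist` over the library records.
#' @param threshold Divergence threshold in substitutions/site.
#' @return Object of class `split_report`: list of per-species partitions
#'   (class `cluster_partition`), each with elements `species`, `genus`,
#'   `epithet`, `clusters`, `flagged`, `interim_names`, `mean_between`,
#'   `mean_within`, `max_within`.
#' @export
detect_splits <- function(ref, dmat, threshold = 0.02) {
  stopifnot(inherits(ref, "barcode_ref"))
  parts <- lapply(names(ref$species_index), function(taxon) {
    ids <- sort(ref$species_index[[taxon]])
    rec <- ref$records[match(ids[1], ref$records$specimen_id), ]
    clusters <- threshold_components(ids, dmat, threshold)
    flagged <- length(clusters) > 1L
    sub <- dist_subset(dmat, ids)$d
    within_vals <- numeric(0)
    between_vals <- numeric(0)
    if (length(ids) > 1L) {
      cl_of <- rep(seq_along(clusters), vapply(clusters, length, integer(1)))
      names(cl_of) <- unlist(clusters)
      ut <- which(upper.tri(sub), arr.ind = TRUE)
      same <- cl_of[ids[ut[, 1]]] == cl_of[ids[ut[, 2]]]
      within_vals <- sub[ut][same]
      between_vals <- sub[ut][!same]
    }
    part <- structure(list(
      species = taxon,
      genus = rec$genus,
      epithet = rec$species,
      clusters = clusters,
      flagged = flagged,
      interim_names = NULL,
      mean_between = if (length(between_vals)) mean(between_vals) else NA_real_,
      mean_within = if (length(within_vals)) mean(within_vals) else NA_real_,
      max_within = if (length(within_vals)) max(within_vals) else NA_real_,
      n = length(ids)
    ), class = "cluster_partition")
    if (flagged) part <- assign_interim_names(part)
    part
  })
  names(parts) <- names(ref$species_index)
  n_flag <- sum(vapply(parts, `[[`, logical(1), "flagged"))
  log_event("split detection at %.2f%%: %d of %d species flagged",
            100 * threshold, n_flag, length(parts))
  structure(parts, class = "split_report", threshold = threshold)
}

#' Assign interim names to the clusters of a flagged species
#'
#' Clusters are ordered by decreasing size, ties by smallest member id,
#' and named `"<Genus> <species>ECO<NN>"` with a zero-padded two-digit
#' counter — the interim-naming convention used for barcode clusters
#' pending taxonomic resolution.
#'
#' @param partition A `cluster_partition` with at least two clusters.
#' @return The partition with clusters reordered and `interim_names` set.
#' @export
assign_interim_names <- function(partition) {
  stopifnot(inherits(partition, "cluster_partition"))
  k <- length(partition$clusters)
  if (k < 2L) {
    stop("interim names apply only to species with >= 2 clusters", call. = FALSE)
  }
  sizes <- vapply(partition$clusters, length, integer(1))
  firsts <- vapply(partition$clusters, `[`, character(1), 1L)
  ord <- order(-sizes, firsts)
  partition$clusters <- partition$clusters[ord]
  partition$interim_names <- sprintf("%s %sECO%02d", partition$genus,
                                     partition$epithet, seq_len(k))
  partition
}

#' Species flagged as containing multiple barcode clusters
#'
#' @param splits A `split_report`.
#' @return Character vector of flagged taxon labels.
#' @export
flagged_species <- function(splits) {
  stopifnot(inherits(splits, "split_report"))
  names(splits)[vapply(splits, `[[`, logical(1), "flagged")]
}

#' @export
print.split_report <- function(x, ...) {
  fl <- flagged_species(x)
  cat(sprintf("Barcode cluster report: %d species, %d flagged at %.2f%% divergence\n",
              length(x), length(fl), 100 * attr(x, "threshold")))
  for (sp in fl) {
    p <- x[[sp]]
    cat(sprintf("  %s: %d clusters (sizes %s), mean between-cluster %.2f%%\n",
                sp, length(p$clusters),
                paste(vapply(p$clusters, length, integer(1)), collapse = "/"),
                100 * p$mean_between))
  }
  invisible(x)
}

#' Write the flagged-species table (splits with interim names)
#'
#' One row per cluster of each flagged species: species, interim name,
#' mean between-cluster K2P distance (percent), cluster size and member
#' ids.
#'
#' @param splits A `split_report`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_split_table <- function(splits, path) {
  rows <- list()
  for (sp in flagged_species(splits)) {
    p <- splits[[sp]]
    for (i in seq_along(p$clusters)) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = p$species,
        interim_name = p$interim_names[i],
        mean_between_pct = sprintf("%.2f", 100 * p$mean_between),
        cluster_size = length(p$clusters[[i]]),
        member_ids = paste(p$clusters[[i]], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), interim_name = character(0),
               mean_between_pct = character(0), cluster_size = integer(0),
               member_ids = character(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
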