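# Precomputed per-library context reused across queries.
query_context <- function(ref, splits = NULL) {
  enc <- encode_seqs(stats::setNames(ref$records$sequence, ref$records$specimen_id),
                     ref$alignment_length)
  taxon <- ref$records$taxon
  # flagged species: replace taxon label with the interim cluster label
  if (!is.null(splits)) {
    for (sp in flagged_species(splits)) {
      p <- splits[[sp]]
      for (i in seq_along(p$clusters)) {
        taxon[ref$records$specimen_id %in% p$clusters[[i]]] <- p$interim_names[i]
      }
    }
  }
  list(enc = enc,
       ids = ref$records$specimen_id,
       taxon = taxon,
       M = (enc > 0L) * 1,
       XA = (enc == 1L) * 1, XC = (enc == 2L) * 1,
       XG = (enc == 3L) * 1, XT = (enc == 4L) * 1)
}

# n, s, v of one query against every library record (vectorised).
query_counts <- function(ctx, qseq, width) {
  q <- encode_seqs(qseq, width)[1, ]
  qa <- (q == 1L) * 1; qc <- (q == 2L) * 1
  qg <- (q == 3L) * 1; qt <- (q == 4L) * 1
  qm <- (q > 0L) * 1
  n <- round(as.vector(ctx$M %*% qm))
  same <- round(as.vector(ctx$XA %*% qa + ctx$XC %*% qc + ctx$XG %*% qg + ctx$XT %*% qt))
  s <- round(as.vector(ctx$XA %*% qg + ctx$XG %*% qa + ctx$XC %*% qt + ctx$XT %*% qc))
  v <- n - same - s
  list(n = n, s = s, v = v)
}

#' Identify one query sequence against a reference library
#'
#' Computes the K2P distance from the query to every library record
#' (pairwise deletion), assigns the query to the taxon of its nearest
#' neighbour when that distance is below the threshold, and reports the
#' BOLD-style similarity (100 x (1 - p-distance) to the nearest record).
#' When the nearest species was flagged as containing several barcode
#' clusters, the assignment carries the interim cluster label.  Two
#' distinct taxa tied for nearest (within 1e-9) give status
#' `"ambiguous"`; a nearest distance at or above the threshold, or no
#' reference with sufficient overlap, gives `"no_match"`.
#'
#' @param query A single-row data.frame or list with `specimen_id` and
#'   `sequence`, or a named length-1 character vector.
#' @param ref A `barcode_ref`.
#' @param splits Optional `split_report` from [detect_splits()]; enables
#'   interim-cluster labelling.
#' @param threshold Assignment threshold in substitutions/site.
#' @param min_overlap Minimum comparable sites between query and a
#'   reference record.
#' @param ctx Precomputed context (internal use by [batch_identify()]).
#' @return One-row data.frame (class `identification`): `query_id`,
#'   `assigned_taxon`, `best_match_id`, `best_distance`,
#'   `mean_distance_to_taxon`, `runner_up_taxon`, `margin`, `status`,
#'   `similarity_pct`.
#' @export
identify_query <- function(query, ref, splits = NULL, threshold = 0.02,
                           min_overlap = 100, ctx = NULL) {
  if (is.character(query)) {
    query <- list(specimen_id = names(query)[1] %||% "query", sequence = query[[1]])
  }
  if (is.null(ctx)) ctx <- query_context(ref, splits)
  qc <- query_counts(ctx, toupper(query$sequence), ref$alignment_length)
  P <- qc$s / qc$n; Q <- qc$v / qc$n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  ok <- qc$n >= min_overlap & w1 > 0 & w2 > 0
  d <- rep(NA_real_, length(qc$n))
  d[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok]) + 0
  pd <- (qc$s + qc$v) / qc$n

  res <- data.frame(query_id = query$specimen_id, assigned_taxon = NA_character_,
                    best_match_id = NA_character_, best_distance = NA_real_,
                    mean_distance_to_taxon = NA_real_,
                    runner_up_taxon = NA_character_, margin = NA_real_,
                    status = "no_match", similarity_pct = NA_real_,
                    stringsAsFactors = FALSE)
  if (!any(ok)) {
    res$status <- "no_match"
    attr(res, "reason") <- "no reference with sufficient overlap"
    class(res) <- c("identification", "data.frame")
    return(res)
  }
  # per-taxon minimum distances; within equal distances prefer smallest id
  ordl <- order(d, ctx$ids, na.last = TRUE)
  best_i <- ordl[1]
  best <- d[best_i]
  taxon_min <- tapply(d[ok], ctx$taxon[ok], min)
  taxon_min <- sort(taxon_min)
  best_taxon <- names(taxon_min)[1]
  tie <- length(taxon_min) > 1L && (taxon_min[2] - taxon_min[1]) <= 1e-9

  res$best_match_id <- ctx$ids[best_i]
  res$best_distance <- best
  res$similarity_pct <- 100 * (1 - pd[best_i])
  if (length(taxon_min) > 1L) {
    res$runner_up_taxon <- names(taxon_min)[2]
    res$margin <- unname(taxon_min[2] - taxon_min[1])
  }
  if (tie && best < threshold) {
    res$status <- "ambiguous"
    res$assigned_taxon <- NA_character_
    attr(res, "tied_taxa") <- names(taxon_min)[taxon_min - taxon_min[1] <= 1e-9]
  } else if (best < threshold) {
    res$status <- "assigned"
    res$assigned_taxon <- best_taxon
    members <- ok & ctx$taxon == best_taxon
    res$mean_distance_to_taxon <- mean(d[members])
  } else {
    res$status <- "no_match"
  }
  class(res) <- c("identification", "data.frame")
  res
}

#' Identify a batch of query sequences
#'
#' Runs [identify_query()] over a query set and aggregates a per-taxon
#' summary: for each assigned taxon, the mean over its queries of each
#' query's distance to the nearest record of that taxon.
#'
#' @param queries Data.frame with columns `specimen_id` and `sequence`
#'   (the `queries` element of a `barcode_ref` works directly), or an
#'   empty data.frame.
#' @param ref A `barcode_ref`.
#' @inheritParams identify_query
#' @return Object of class `identification_set`: list with `results`
#'   (one row per query) and `taxon_summary` (`taxon`, `n_queries`,
#'   `mean_dist`, `mean_dist_pct`).
#' @export
batch_identify <- function(queries, ref, splits = NULL, threshold = 0.02,
                           min_overlap = 100) {
  ctx <- query_context(ref, splits)
  if (is.null(queries) || !nrow(queries)) {
    results <- data.frame(query_id = character(0), assigned_taxon = character(0),
                          best_match_id = character(0), best_distance = numeric(0),
                          mean_distance_to_taxon = numeric(0),
                          runner_up_taxon = character(0), margin = numeric(0),
                          status = character(0), similarity_pct = numeric(0),
                          stringsAsFactors = FALSE)
  } else {
    rows <- lapply(seq_len(nrow(queries)), function(i) {
      r <- identify_query(list(specimen_id = queries$specimen_id[i],
                               sequence = queries$sequence[i]),
                          ref, splits, threshold, min_overlap, ctx = ctx)
      class(r) <- "data.frame"
      r
    })
    results <- do.call(rbind, rows)
  }
  assigned <- results[results$status == "assigned", , drop = FALSE]
  if (nrow(assigned)) {
    agg <- aggregate(best_distance ~ assigned_taxon, data = assigned, FUN = mean)
    cnt <- aggregate(query_id ~ assigned_taxon, data = assigned, FUN = length)
    ts <- merge(cnt, agg, by = "assigned_taxon")
    names(ts) <- c("taxon", "n_queries", "mean_dist")
    ts$mean_dist_pct <- 100 * ts$mean_dist
    ts <- ts[order(ts$taxon), , drop = FALSE]
    rownames(ts) <- NULL
  } else {
    ts <- data.frame(taxon = character(0), n_queries = integer(0),
                     mean_dist = numeric(0), mean_dist_pct = numeric(0))
  }
  n_fail <- sum(results$status != "assigned")
  if (n_fail) {
    log_event("identification: %d of %d queries not assigned (%s)",
              n_fail, nrow(results),
              paste(results$query_id[results$status != "assigned"], collapse = ", "))
  }
  structure(list(results = results, taxon_summary = ts,
                 threshold = threshold), class = "identification_set")
}

#' @export
print.identification_set <- function(x, ...) {
  n <- nrow(x$results)
  cat(sprintf("Identification of %d queries at %.1f%% threshold: %d assigned, %d ambiguous, %d no match\n",
              n, 100 * x$threshold,
              sum(x$results$status == "assigned"),
              sum(x$results$status == "ambiguous"),
              sum(x$results$status == "no_match")))
  if (nrow(x$taxon_summary)) {
    cat("Per-taxon mean nearest-match distance (%):\n")
    disp <- data.frame(taxon = x$taxon_summary$taxon,
                       n = x$taxon_summary$n_queries,
                       mean_dist_pct = sprintf("%.2f", x$taxon_summary$mean_dist_pct))
    print(disp, row.names = FALSE)
  }
  invisible(x)
}

#' Write identification reports as TSV
#'
#' `path_summary` receives the per-taxon table (taxon, number of queries,
#' mean nearest-match distance in percent); `path_detail` the per-query
#' rows.
#'
#' @param x An `identification_set`.
#' @param path_summary,path_detail Output TSV paths (either may be NULL).
#' @return Invisibly, NULL.
#' @export
write_identification_tables <- function(x, path_summary = NULL, path_detail = NULL) {
  if (!is.null(path_summary)) {
    out <- data.frame(taxon = x$taxon_summary$taxon,
                      n_queries = x$taxon_summary$n_queries,
                      mean_dist_pct = sprintf("%.2f", x$taxon_summary$mean_dist_pct),
                      stringsAsFactors = FALSE)
    write.table(out, path_summary, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_detail)) {
    det <- x$results
    det$best_distance_pct <- sprintf("%.2f", 100 * det$best_distance)
    det$similarity_pct <- sprintf("%.2f", det$similarity_pct)
    write.table(det, path_detail, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
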