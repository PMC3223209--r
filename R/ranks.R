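#' Enumerate specimen pairs at a taxonomic rank
#'
#' Ranks are exclusive: `within_species` pairs are conspecific,
#' `within_genus` pairs are congeneric but heterospecific, and
#' `within_family` pairs come from different genera.
#'
#' @param ref A `barcode_ref`.
#' @param rank One of `"within_species"`, `"within_genus"`,
#'   `"within_family"`.
#' @return Two-column character matrix of specimen-id pairs.
#' @export
rank_pairs <- function(ref, rank = c("within_species", "within_genus", "within_family")) {
  rank <- match.arg(rank)
  ids <- ref$records$specimen_id
  sp <- ref$records$taxon
  ge <- ref$records$genus
  ut <- which(upper.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
  same_sp <- sp[ut[, 1]] == sp[ut[, 2]]
  same_ge <- ge[ut[, 1]] == ge[ut[, 2]]
  keep <- switch(rank,
                 within_species = same_sp,
                 within_genus = same_ge & !same_sp,
                 within_family = !same_ge)
  cbind(ids[ut[keep, 1]], ids[ut[keep, 2]])
}

#' Divergence summary by taxonomic rank
#'
#' Computes, for each exclusive rank, the pair count, minimum, mean,
#' maximum and standard error of the pairwise distances — the classic
#' barcoding-gap summary table.  Flagged (saturated or low-overlap)
#' pairs are skipped with a logged count.  The standard error is the
#' sample standard deviation of the pair distances divided by
#' `sqrt(n)`; pair non-independence is acknowledged, not modelled.
#'
#' @param ref A `barcode_ref`.
#' @param dmat A `barcode_dist` covering the library.
#' @param exclude Taxon labels (typically species flagged by
#'   [detect_splits()]) to exclude.
#' @param exclude_policy `"within_species"` (default) removes excluded
#'   species' pairs from the within-species row only, so their congeneric
#'   and family-level comparisons remain; `"all"` removes every pair that
#'   involves an excluded species.
#' @return Object of class `rank_summary`: data.frame with columns
#'   `rank`, `n_comparisons`, `min`, `mean`, `max`, `se` (distances in
#'   substitutions/site).
#' @export
summarize_ranks <- function(ref, dmat, exclude = character(0),
                            exclude_policy = c("within_species", "all")) {
  exclude_policy <- match.arg(exclude_policy)
  sp_of <- stats::setNames(ref$records$taxon, ref$records$specimen_id)
  n_skipped <- 0L
  rows <- lapply(c("within_species", "within_genus", "within_family"), function(rk) {
    pr <- rank_pairs(ref, rk)
    if (nrow(pr)) {
      drop_excl <- if (exclude_policy == "all" || rk == "within_species") {
        sp_of[pr[, 1]] %in% exclude | sp_of[pr[, 2]] %in% exclude
      } else rep(FALSE, nrow(pr))
      pr <- pr[!drop_excl, , drop = FALSE]
    }
    if (!nrow(pr)) {
      return(data.frame(rank = rk, n_comparisons = 0L, min = NA_real_,
                        mean = NA_real_, max = NA_real_, se = NA_real_,
                        stringsAsFactors = FALSE))
    }
    idx <- cbind(match(pr[, 1], dmat$ids), match(pr[, 2], dmat$ids))
    vals <- dmat$d[idx]
    ok <- dmat$flags[idx] == "ok"
    n_skipped <<- n_skipped + sum(!ok)
    vals <- vals[ok]
    if (!length(vals)) {
      return(data.frame(rank = rk, n_comparisons = 0L, min = NA_real_,
                        mean = NA_real_, max = NA_real_, se = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(rank = rk, n_comparisons = length(vals),
               min = min(vals), mean = mean(vals), max = max(vals),
               se = if (length(vals) > 1L) sd(vals) / sqrt(length(vals)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  if (n_skipped > 0) {
    log_event("rank summary: %d flagged pair(s) skipped", n_skipped)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rank_summary", "data.frame")
  attr(out, "excluded") <- exclude
  attr(out, "exclude_policy") <- exclude_policy
  out
}

#' @export
print.rank_summary <- function(x, ...) {
  cat("K2P divergence by taxonomic rank (percent):\n")
  disp <- data.frame(rank = x$rank,
                     comparisons = x$n_comparisons,
                     min = sprintf("%.2f", 100 * x$min),
                     mean = sprintf("%.2f", 100 * x$mean),
                     max = sprintf("%.2f", 100 * x$max),
                     se = sprintf("%.3f", 100 * x$se))
  print(disp, row.names = FALSE)
  if (length(attr(x, "excluded"))) {
    cat(sprintf("(%d flagged species excluded, policy '%s')\n",
                length(attr(x, "excluded")), attr(x, "exclude_policy")))
  }
  invisible(x)
}

#' Write the rank-summary table as TSV (percent scale)
#'
#' Distances are rendered in percent with two decimals, standard errors
#' with three, matching the conventional presentation of barcode
#' divergence tables.
#'
#' @param x A `rank_summary`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_rank_table <- function(x, path) {
  out <- data.frame(rank = x$rank,
                    comparisons = x$n_comparisons,
                    min_dist_pct = sprintf("%.2f", 100 * x$min),
                    mean_dist_pct = sprintf("%.2f", 100 * x$mean),
                    max_dist_pct = sprintf("%.2f", 100 * x$max),
                    se_dist_pct = sprintf("%.3f", 100 * x$se),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
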