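#' Count comparable sites, transitions and transversions for one pair
#'
#' Applies pairwise deletion: only alignment columns where both sequences
#' carry an unambiguous A/C/G/T are compared.  Transitions are A<->G and
#' C<->T; every other mismatch is a transversion.
#'
#' @param seq_a,seq_b Equal-length aligned sequences (character strings).
#' @return List with integer elements `n` (comparable sites), `s`
#'   (transition differences) and `v` (transversion differences).
#' @export
count_site_pairs <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences differ in length (", nchar(seq_a), " vs ", nchar(seq_b), ")",
         call. = FALSE)
  }
  a <- encode_seqs(toupper(seq_a))[1, ]
  b <- encode_seqs(toupper(seq_b))[1, ]
  both <- a > 0L & b > 0L
  a <- a[both]; b <- b[both]
  # transition partner: A(1)<->G(3), C(2)<->T(4)
  ts <- (a == 1L & b == 3L) | (a == 3L & b == 1L) |
        (a == 2L & b == 4L) | (a == 4L & b == 2L)
  diff <- a != b
  list(n = sum(both), s = sum(ts), v = sum(diff & !ts))
}

#' Kimura two-parameter distance from site-pair counts
#'
#' Evaluates d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q) with P = s/n the
#' transition proportion and Q = v/n the transversion proportion.  When a
#' log argument is non-positive the pair is saturated and no distance is
#' returned; when fewer than `min_overlap` sites are comparable the pair
#' is flagged `insufficient_overlap`.
#'
#' @param stats A list as returned by [count_site_pairs()].
#' @param min_overlap Minimum comparable-site count for estimation.
#' @return List with `distance` (substitutions/site, or `NA`) and `flag`
#'   (one of `"ok"`, `"saturated"`, `"insufficient_overlap"`).
#' @export
k2p_distance <- function(stats, min_overlap = 100) {
  n <- stats$n
  if (is.null(n) || n < max(1L, min_overlap)) {
    return(list(distance = NA_real_, flag = "insufficient_overlap"))
  }
  P <- stats$s / n
  Q <- stats$v / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(distance = NA_real_, flag = "saturated"))
  }
  # + 0 normalises IEEE negative zero from -0.5 * log(1)
  list(distance = -0.5 * log(w1) - 0.25 * log(w2) + 0, flag = "ok")
}

#' Uncorrected p-distance from site-pair counts
#'
#' @inheritParams k2p_distance
#' @return List with `distance` ((s+v)/n) and `flag`.
#' @export
p_distance <- function(stats, min_overlap = 1) {
  n <- stats$n
  if (is.null(n) || n < max(1L, min_overlap)) {
    return(list(distance = NA_real_, flag = "insufficient_overlap"))
  }
  list(distance = (stats$s + stats$v) / n, flag = "ok")
}

# Pairwise n/s/v over an encoded sequence matrix, via indicator cross
# products (exact integer counts; rounded to kill BLAS float fuzz).
pair_counts <- function(enc) {
  M <- (enc > 0L) * 1
  XA <- (enc == 1L) * 1; XC <- (enc == 2L) * 1
  XG <- (enc == 3L) * 1; XT <- (enc == 4L) * 1
  N <- round(tcrossprod(M))
  same <- round(tcrossprod(XA) + tcrossprod(XC) + tcrossprod(XG) + tcrossprod(XT))
  Sh <- tcrossprod(XA, XG) + tcrossprod(XC, XT)
  S <- round(Sh + t(Sh))
  V <- N - same - S
  list(N = N, S = S, V = V)
}

#' Pairwise distance matrix over a reference library
#'
#' Computes all unordered pairwise distances under the chosen model with
#' pairwise deletion.  Pairs whose correction saturates, or that share
#' fewer than `min_overlap` comparable sites, carry no numeric value and
#' are flagged instead.
#'
#' @param x A `barcode_ref`, or a named character vector of equal-length
#'   aligned sequences.
#' @param model `"k2p"` (default) or `"p"`.
#' @param min_overlap Minimum comparable sites per pair.
#' @return An object of class `barcode_dist`: list with `ids`, `d`
#'   (symmetric numeric matrix, `NA` where flagged), `flags` (character
#'   matrix) and `model`.
#' @export
distance_matrix <- function(x, model = c("k2p", "p"), min_overlap = 100) {
  model <- match.arg(model)
  if (inherits(x, "barcode_ref")) {
    seqs <- stats::setNames(x$records$sequence, x$records$specimen_id)
    width <- x$alignment_length
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    if (length(unique(nchar(x))) != 1L) {
      stop("sequences must share a common frame (equal lengths)", call. = FALSE)
    }
    seqs <- x
    width <- nchar(x[[1]])
  }
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  enc <- encode_seqs(seqs, width)
  pc <- pair_counts(enc)
  N <- pc$N; S <- pc$S; V <- pc$V
  flags <- matrix("ok", nrow(N), ncol(N))
  d <- matrix(NA_real_, nrow(N), ncol(N))
  if (model == "k2p") {
    P <- S / N; Q <- V / N
    w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
    ok <- N >= min_overlap & w1 > 0 & w2 > 0
    flags[N < min_overlap] <- "insufficient_overlap"
    flags[N >= min_overlap & !(w1 > 0 & w2 > 0)] <- "saturated"
    d[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok]) + 0
  } else {
    ok <- N >= min_overlap
    flags[!ok] <- "insufficient_overlap"
    d[ok] <- (S[ok] + V[ok]) / N[ok]
  }
  diag(d) <- 0
  diag(flags) <- "ok"
  ids <- names(seqs)
  dimnames(d) <- dimnames(flags) <- list(ids, ids)
  n_bad <- sum(flags[upper.tri(flags)] != "ok")
  if (n_bad > 0) {
    log_event("distance matrix: %d pair(s) flagged (%s)", n_bad,
              paste(names(table(flags[upper.tri(flags) & flags != "ok"])), collapse = ", "))
  }
  structure(list(ids = ids, d = d, flags = flags, model = model,
                 min_overlap = min_overlap),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  n <- length(x$ids)
  bad <- sum(x$flags[upper.tri(x$flags)] != "ok")
  cat(sprintf("%s distance matrix over %d specimens (%d pairs, %d flagged)\n",
              toupper(x$model), n, n * (n - 1) / 2, bad))
  invisible(x)
}

#' @export
as.matrix.barcode_dist <- function(x, ...) x$d

#' @export
as.dist.barcode_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Export a distance matrix in square PHYLIP format
#'
#' Relaxed PHYLIP: full ids (whitespace-padded), not truncated to 10
#' characters.  Flagged pairs are written as `NA`.
#'
#' @param dmat A `barcode_dist`.
#' @param path Output path.
#' @param digits Decimal places for distances.
#' @return Invisibly, `path`.
#' @export
write_phylip <- function(dmat, path, digits = 6) {
  ids <- format(dmat$ids)
  rows <- vapply(seq_along(ids), function(i) {
    paste(ids[i], paste(formatC(dmat$d[i, ], format = "f", digits = digits),
                        collapse = " "))
  }, character(1))
  writeLines(c(format(length(ids)), rows), path)
  invisible(path)
}

#' Export pairwise distances as a long-form TSV
#'
#' Columns: `id_a`, `id_b`, `distance` (substitutions/site), `flag`.
#'
#' @inheritParams write_phylip
#' @return Invisibly, `path`.
#' @export
write_dist_long <- function(dmat, path) {
  n <- length(dmat$ids)
  ut <- which(upper.tri(dmat$d), arr.ind = TRUE)
  out <- data.frame(id_a = dmat$ids[ut[, 1]], id_b = dmat$ids[ut[, 2]],
                    distance = dmat$d[ut], flag = dmat$flags[ut],
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Submatrix accessor with consistency checks.
dist_subset <- function(dmat, ids) {
  missing <- setdiff(ids, dmat$ids)
  if (length(missing)) {
    stop("ids absent from distance matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  list(d = dmat$d[ids, ids, drop = FALSE],
       flags = dmat$flags[ids, ids, drop = FALSE])
}
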