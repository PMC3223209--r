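# Internal state: optional log collector used by run_pipeline().
.cb_state <- new.env(parent = emptyenv())

log_event <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  if (!is.null(.cb_state$log)) .cb_state$log <- c(.cb_state$log, msg)
  if (isTRUE(getOption("coibarcode.verbose", FALSE))) message(msg)
  invisible(msg)
}

log_collect_start <- function() .cb_state$log <- character(0)

log_collect_stop <- function() {
  out <- .cb_state$log
  .cb_state$log <- NULL
  out
}

DNA_BASES <- c("A", "C", "G", "T")
# IUPAC nucleotide codes plus alignment gap; anything else is rejected.
IUPAC_CODES <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "-")

#' @noRd
validate_iupac <- function(seqs, ids = names(seqs)) {
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(ch), IUPAC_CODES)
    if (length(bad)) {
      stop(sprintf("sequence '%s' contains non-IUPAC character(s): %s",
                   ids[i], paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Encode sequences as an n x width integer matrix: A=1, C=2, G=3, T=4,
# everything else (ambiguity codes, gaps, padding) 0 = missing.
encode_seqs <- function(seqs, width = NULL) {
  seqs <- as.character(seqs)
  if (is.null(width)) width <- max(nchar(seqs), 1L)
  mat <- matrix(0L, length(seqs), width)
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    if (length(ch) > width) ch <- ch[seq_len(width)]
    mat[i, seq_along(ch)] <- match(ch, DNA_BASES, nomatch = 0L)
  }
  rownames(mat) <- names(seqs)
  mat
}

# Count of unambiguous A/C/G/T positions, the length used by filters.
informative_length <- function(seqs) {
  vapply(seqs, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1]] %in% DNA_BASES)
  }, integer(1), USE.NAMES = FALSE)
}

pad_to <- function(seqs, width, pad = "N") {
  vapply(seqs, function(s) {
    d <- width - nchar(s)
    if (d > 0) paste0(s, strrep(pad, d)) else substr(s, 1L, width)
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
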