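#' Read a FASTA file of barcode sequences
#'
#' Reads sequences into a named character vector, uppercasing residues and
#' preserving alignment gaps.  Specimen ids are the first whitespace-
#' delimited token of each header.  Errors on structural problems name the
#' offending line so malformed submissions can be fixed quickly.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercased sequences, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp1", "acgt", ">sp2", "ACGA"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("FASTA format error: file is empty: ", path, call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("FASTA format error at line %d: expected a '>' header", nonblank[1]),
         call. = FALSE)
  }
  hdr <- startsWith(lines, ">")
  idx <- which(hdr)
  ids <- sub("\\s.*$", "", sub("^>\\s*", "", lines[idx]))
  if (any(!nzchar(ids))) {
    stop(sprintf("FASTA format error at line %d: empty sequence id", idx[which(!nzchar(ids))[1]]),
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ends <- c(idx[-1] - 1L, length(lines))
  seqs <- character(length(idx))
  for (k in seq_along(idx)) {
    body <- if (idx[k] < ends[k]) lines[seq(idx[k] + 1L, ends[k])] else character(0)
    seqs[k] <- toupper(paste(gsub("[ \t]", "", body), collapse = ""))
    if (!nzchar(seqs[k])) {
      stop(sprintf("FASTA format error at line %d: record '%s' has no sequence",
                   idx[k], ids[k]), call. = FALSE)
    }
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Reads a tab-separated, UTF-8 metadata table with a header row.  The
#' columns `specimen_id`, `genus`, `species` and `life_stage` are
#' mandatory; any further columns are carried through untouched.
#' `life_stage` is normalised to the controlled vocabulary
#' `adult`/`larva` (accepting synonyms such as "caterpillar").
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per specimen.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  md <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character", na.strings = character(0))
  required <- c("specimen_id", "genus", "species", "life_stage")
  missing <- setdiff(required, names(md))
  if (length(missing)) {
    stop("metadata schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(md$specimen_id)) {
    stop("metadata schema error: duplicate specimen_id(s): ",
         paste(unique(md$specimen_id[duplicated(md$specimen_id)]), collapse = ", "),
         call. = FALSE)
  }
  stage <- tolower(trimws(md$life_stage))
  stage[stage %in% c("adult", "imago")] <- "adult"
  stage[stage %in% c("larva", "larval", "caterpillar", "immature")] <- "larva"
  bad <- setdiff(unique(stage), c("adult", "larva"))
  if (length(bad)) {
    stop("metadata schema error: unrecognised life_stage value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  md$life_stage <- stage
  md
}

#' Assemble a validated barcode reference library
#'
#' Joins sequences to specimen metadata, keeps adult records whose
#' unambiguous-base count passes `min_length`, pads every sequence to a
#' common left-anchored coordinate frame with the missing-data symbol
#' `N`, and sets larval records aside as queries.  Metadata rows without
#' a sequence are retained (flagged) but excluded from the library, with
#' a warning.
#'
#' @param seqs Named character vector of sequences (see [read_fasta()]).
#' @param metadata Metadata data.frame (see [read_metadata()]).
#' @param min_length Minimum number of unambiguous A/C/G/T positions an
#'   adult record must carry to enter the library.  The default 267
#'   matches the shortest fragment class the barcoding literature retains
#'   from old museum specimens.
#' @param alignment_length Site count of the common coordinate frame;
#'   defaults to the longest joined sequence.
#' @return An object of class `barcode_ref` with elements `records` (adult
#'   data.frame), `queries` (larval data.frame), `alignment_length` and
#'   `species_index` (list mapping taxon label to specimen ids).
#' @export
build_library <- function(seqs, metadata, min_length = 267, alignment_length = NULL) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate specimen_id(s) among sequences: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  validate_iupac(seqs)
  md <- metadata
  md$has_sequence <- md$specimen_id %in% names(seqs)
  if (any(!md$has_sequence)) {
    miss <- md$specimen_id[!md$has_sequence]
    warning("specimen(s) in metadata without a sequence: ",
            paste(miss, collapse = ", "), call. = FALSE)
    log_event("missing-sequence flag set for %d specimen(s): %s",
              length(miss), paste(miss, collapse = ", "))
  }
  orphan <- setdiff(names(seqs), md$specimen_id)
  if (length(orphan)) {
    warning("sequence(s) without metadata dropped: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }
  md2 <- md[md$has_sequence, , drop = FALSE]
  md2$sequence <- unname(seqs[md2$specimen_id])
  taxon <- paste(trimws(md2$genus), trimws(md2$species))
  if (any(!nzchar(trimws(md2$genus)) | !nzchar(trimws(md2$species)))) {
    bad <- md2$specimen_id[!nzchar(trimws(md2$genus)) | !nzchar(trimws(md2$species))]
    stop("empty taxon label for specimen(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  md2$taxon <- taxon
  if (is.null(alignment_length)) alignment_length <- max(nchar(md2$sequence))
  md2$sequence <- pad_to(md2$sequence, alignment_length)

  adults <- md2[md2$life_stage == "adult", , drop = FALSE]
  queries <- md2[md2$life_stage == "larva", , drop = FALSE]
  ilen <- informative_length(adults$sequence)
  drop <- ilen < min_length
  if (any(drop)) {
    log_event("length filter (< %d informative nt) excluded %d adult record(s): %s",
              min_length, sum(drop), paste(adults$specimen_id[drop], collapse = ", "))
  }
  adults <- adults[!drop, , drop = FALSE]
  if (!nrow(adults)) {
    stop("empty library: no adult records pass the filters", call. = FALSE)
  }
  rownames(adults) <- NULL
  rownames(queries) <- NULL
  counts <- table(adults$taxon)
  log_event("library built: %d adult record(s), %d species; %d larval query record(s) set aside",
            nrow(adults), length(counts), nrow(queries))
  structure(list(
    records = adults,
    queries = queries,
    alignment_length = alignment_length,
    min_length = min_length,
    species_index = split(adults$specimen_id, adults$taxon)
  ), class = "barcode_ref")
}

#' @export
print.barcode_ref <- function(x, ...) {
  cat("COI barcode reference library\n")
  cat(sprintf("  %d adult specimens, %d species, %d genera; frame of %d sites\n",
              nrow(x$records), length(x$species_index),
              length(unique(x$records$genus)), x$alignment_length))
  if (nrow(x$queries)) {
    cat(sprintf("  %d larval query record(s) set aside\n", nrow(x$queries)))
  }
  invisible(x)
}

#' @export
summary.barcode_ref <- function(object, ...) {
  counts <- vapply(object$species_index, length, integer(1))
  out <- data.frame(taxon = names(counts), n_specimens = as.integer(counts),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$taxon), , drop = FALSE]
}
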