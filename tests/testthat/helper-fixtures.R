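# Shared fixtures and tiny independent oracles.

rand_seq <- function(L, p_n = 0, p_gap = 0) {
  pool <- c("A", "C", "G", "T")
  ch <- sample(pool, L, replace = TRUE)
  if (p_n > 0) ch[runif(L) < p_n] <- "N"
  if (p_gap > 0) ch[runif(L) < p_gap] <- "-"
  paste(ch, collapse = "")
}

# Wrap a plain symmetric matrix as a barcode_dist (all pairs ok unless
# flags given).
dist_obj <- function(m, flags = NULL) {
  ids <- rownames(m)
  if (is.null(flags)) {
    flags <- matrix("ok", nrow(m), ncol(m), dimnames = dimnames(m))
  }
  structure(list(ids = ids, d = m, flags = flags, model = "k2p",
                 min_overlap = 0), class = "barcode_dist")
}

# Reference library from explicit sequences: `species` is a named list of
# character vectors (name "Genus epithet"), each element one specimen.
make_ref <- function(species, min_length = 5, larvae = NULL) {
  ids <- c(); seqs <- c(); gen <- c(); sp <- c(); stage <- c()
  k <- 0
  for (tx in names(species)) {
    parts <- strsplit(tx, " ", fixed = TRUE)[[1]]
    for (s in species[[tx]]) {
      k <- k + 1
      ids <- c(ids, sprintf("S%03d", k))
      seqs <- c(seqs, s); gen <- c(gen, parts[1]); sp <- c(sp, parts[2])
      stage <- c(stage, "adult")
    }
  }
  if (!is.null(larvae)) {
    for (tx in names(larvae)) {
      parts <- strsplit(tx, " ", fixed = TRUE)[[1]]
      for (s in larvae[[tx]]) {
        k <- k + 1
        ids <- c(ids, sprintf("S%03d", k))
        seqs <- c(seqs, s); gen <- c(gen, parts[1]); sp <- c(sp, parts[2])
        stage <- c(stage, "larva")
      }
    }
  }
  md <- data.frame(specimen_id = ids, genus = gen, species = sp,
                   life_stage = stage, stringsAsFactors = FALSE)
  build_library(stats::setNames(seqs, ids), md, min_length = min_length)
}

# Mutate `seq` at `k` chosen sites into a fixed substitution class.
mutate_sites <- function(seq, pos, kind = c("transition", "transversion")) {
  kind <- match.arg(kind)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "A", T = "G")
  map <- if (kind == "transition") ts_map else tv_map
  ch[pos] <- map[ch[pos]]
  paste(ch, collapse = "")
}

# Exhaustive connected-components oracle on a thresholded graph.
brute_components <- function(ids, d, threshold) {
  n <- length(ids)
  adj <- d <= threshold
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% adj > 0)
  comps <- unique(apply(reach, 1, function(r) paste(sort(ids[r]), collapse = ",")))
  lapply(strsplit(comps, ",", fixed = TRUE), identity)
}
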