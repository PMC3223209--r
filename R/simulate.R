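# K80 per-site replacement probabilities after divergence t with
# transition/transversion rate ratio kappa.  Rates are normalised so t is
# the expected number of substitutions per site (alpha + 2 beta = 1).
k80_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa / (kappa + 2)
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts   = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv   = 0.25 - 0.25 * e1)   # each of the two transversion targets
}

#' Evolve a sequence under the K80 substitution model
#'
#' Each A/C/G/T site is replaced independently using the closed-form K80
#' transition probabilities for divergence `t` (expected substitutions
#' per site along the branch) and transition/transversion rate ratio
#' `kappa`.  Ambiguous or gap positions are left untouched.  Uses the
#' current R random-number stream; call `set.seed()` for reproducibility.
#'
#' @param seq Character string (IUPAC DNA).
#' @param t Branch length in expected substitutions/site (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return The evolved sequence (character string, same length).
#' @export
evolve_seq <- function(seq, t, kappa = 4) {
  if (t < 0) stop("branch length t must be >= 0", call. = FALSE)
  stopifnot(kappa > 0)
  if (t == 0) return(seq)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(ch, DNA_BASES, nomatch = 0L)
  pr <- k80_probs(t, kappa)
  ts_partner <- c(3L, 4L, 1L, 2L)          # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)                 # first transversion target
  tv2 <- c(4L, 3L, 4L, 3L)                 # second transversion target
  live <- idx > 0L
  u <- runif(sum(live))
  cur <- idx[live]
  new <- cur
  new[u >= pr["same"] & u < pr["same"] + pr["ts"]] <-
    ts_partner[cur][u >= pr["same"] & u < pr["same"] + pr["ts"]]
  in_tv1 <- u >= pr["same"] + pr["ts"] & u < pr["same"] + pr["ts"] + pr["tv"]
  in_tv2 <- u >= pr["same"] + pr["ts"] + pr["tv"]
  new[in_tv1] <- tv1[cur][in_tv1]
  new[in_tv2] <- tv2[cur][in_tv2]
  ch[live] <- DNA_BASES[new]
  paste(ch, collapse = "")
}

#' Simulation configuration for synthetic barcode libraries
#'
#' Depths are lineage-pair divergences: the expected estimated distance
#' between two lineages separated at a depth equals that depth (each
#' branch carries half).  The seed fixes the full output byte-for-byte.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus.
#' @param n_species Optional total species cap (truncates the genus x
#'   species grid); NULL keeps all.
#' @param specimens_per_species Specimens per species; scalar or vector
#'   recycled across species.
#' @param seq_length Barcode frame length in sites.
#' @param kappa Transition/transversion rate ratio of the K80 process.
#' @param depth_intra Expected divergence between conspecific specimens.
#' @param depth_species Depth separating congeneric species ancestors.
#' @param depth_genus Depth separating genus ancestors.
#' @param split_plan Optional data.frame with columns `species` (index
#'   into the species list), `n_clusters` (2 or 3) and `depth` (cluster
#'   separation); injects deep intraspecific splits.
#' @param short_fraction Fraction of adult records truncated (emulating
#'   degraded museum specimens; the default 0.016 is the rate at which
#'   regional barcode surveys recover only the shortest 267-399 nt
#'   fragment class from old material).
#' @param short_length Length the truncated records keep.
#' @param n_queries_per_species Queries drawn per species (every species)
#'   when no `query_plan` is given.
#' @param query_plan Optional data.frame with columns `species` (index),
#'   `cluster` (index, 1 for unsplit species) and `n` (queries).
#' @param seed Integer RNG seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genera = 8, species_per_genus = 4, n_species = NULL,
                       specimens_per_species = 7, seq_length = 658, kappa = 4,
                       depth_intra = 0.003, depth_species = 0.05,
                       depth_genus = 0.10, split_plan = NULL,
                       short_fraction = 0.016, short_length = 267,
                       n_queries_per_species = 0, query_plan = NULL, seed = 1) {
  stopifnot(n_genera >= 1, species_per_genus >= 1, seq_length >= 1,
            kappa > 0, depth_intra >= 0, depth_species >= 0, depth_genus >= 0,
            short_fraction >= 0, short_fraction <= 1,
            short_length >= 1, short_length <= seq_length,
            n_queries_per_species >= 0)
  total <- n_genera * species_per_genus
  if (is.null(n_species)) n_species <- total
  stopifnot(n_species >= 1, n_species <= total)
  if (!is.null(split_plan)) {
    stopifnot(is.data.frame(split_plan),
              all(c("species", "n_clusters", "depth") %in% names(split_plan)))
    if (any(split_plan$species < 1 | split_plan$species > n_species)) {
      stop("split_plan references nonexistent species index", call. = FALSE)
    }
    stopifnot(all(split_plan$n_clusters >= 2), all(split_plan$depth >= 0),
              !anyDuplicated(split_plan$species))
  }
  if (!is.null(query_plan)) {
    stopifnot(is.data.frame(query_plan),
              all(c("species", "n") %in% names(query_plan)))
    if (is.null(query_plan$cluster)) query_plan$cluster <- 1L
    if (any(query_plan$species < 1 | query_plan$species > n_species)) {
      stop("query_plan references nonexistent species index", call. = FALSE)
    }
  }
  structure(list(n_genera = n_genera, species_per_genus = species_per_genus,
                 n_species = n_species,
                 specimens_per_species = specimens_per_species,
                 seq_length = seq_length, kappa = kappa,
                 depth_intra = depth_intra, depth_species = depth_species,
                 depth_genus = depth_genus, split_plan = split_plan,
                 short_fraction = short_fraction, short_length = short_length,
                 n_queries_per_species = n_queries_per_species,
                 query_plan = query_plan, seed = as.integer(seed)),
            class = "sim_config")
}

#' Study-scale simulation configuration
#'
#' The default synthetic analogue of a regional all-species barcode
#' survey: 31 genera x 4 species truncated to 121 species; 857 adult
#' specimens (7 per species, 8 for the first ten); shallow intraspecific
#' divergence (0.3%), congeneric depth 5%, intergeneric depth 10%;
#' 8 species carry injected splits at 4% (seven two-cluster, one
#' three-cluster); 71 larval queries from 16 species, one of which is a
#' split species queried from its second cluster; 1.6% of adults
#' truncated to 267 nt.
#'
#' @param seed Integer RNG seed.
#' @param short_fraction Fraction of adults truncated to 267 nt; set to 0
#'   for an all-full-length library.
#' @return A `sim_config`.
#' @export
study_config <- function(seed = 1, short_fraction = 0.016) {
  n_species <- 121L
  nspec <- rep(7L, n_species)
  nspec[1:10] <- 8L                      # 857 adults in total
  split_idx <- round(seq(10, 115, length.out = 8))
  split_plan <- data.frame(species = split_idx,
                           n_clusters = c(2L, 2L, 2L, 2L, 3L, 2L, 2L, 2L),
                           depth = 0.04)
  # 16 query species: one split species (second cluster), 15 unsplit
  unsplit <- setdiff(seq_len(n_species), split_idx)
  q_species <- c(split_idx[5], unsplit[round(seq(1, length(unsplit), length.out = 15))])
  query_plan <- data.frame(species = q_species,
                           cluster = c(2L, rep(1L, 15)),
                           n = c(rep(5L, 7), rep(4L, 9)))   # 71 queries
  sim_config(n_genera = 31, species_per_genus = 4, n_species = n_species,
             specimens_per_species = nspec, split_plan = split_plan,
             query_plan = query_plan, short_fraction = short_fraction,
             seed = seed)
}

#' Simulate a barcode reference library with recorded ground truth
#'
#' Hierarchical K80 generation: a random root sequence; genus ancestors
#' at `depth_genus`; species ancestors at `depth_species`; for species in
#' the split plan, cluster ancestors at the planned split depth; and
#' specimens at `depth_intra` (each level placing half the depth on each
#' branch).  A configured fraction of adult records is truncated to
#' emulate short museum fragments.
#'
#' @param config A `sim_config`.
#' @return Object of class `sim_library`: list with `records` (adult
#'   data.frame: specimen_id, sequence, genus, species, life_stage,
#'   locality), `truth` (specimen_id, taxon, cluster), `ancestors`
#'   (cluster ancestor sequences, for query simulation), `ref` (the
#'   corresponding `barcode_ref`) and `config`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$seq_length
  root <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")

  # genus / species grid, truncated to n_species
  grid <- expand.grid(sp = seq_len(config$species_per_genus),
                      ge = seq_len(config$n_genera))[, 2:1]
  grid <- grid[seq_len(config$n_species), , drop = FALSE]
  nspec <- rep_len(config$specimens_per_species, config$n_species)

  genus_anc <- lapply(seq_len(config$n_genera), function(g) {
    evolve_seq(root, config$depth_genus / 2, config$kappa)
  })

  split_map <- config$split_plan
  records <- vector("list", config$n_species)
  truth <- vector("list", config$n_species)
  ancestors <- list()
  spec_counter <- 0L
  for (k in seq_len(config$n_species)) {
    g <- grid$ge[k]
    genus <- sprintf("Genus%02d", g)
    epithet <- sprintf("sp%02d", grid$sp[k])
    taxon <- paste(genus, epithet)
    sp_anc <- evolve_seq(genus_anc[[g]], config$depth_species / 2, config$kappa)
    n_cl <- 1L
    cl_depth <- 0
    if (!is.null(split_map) && k %in% split_map$species) {
      row <- split_map[split_map$species == k, ]
      n_cl <- row$n_clusters
      cl_depth <- row$depth
    }
    cl_anc <- lapply(seq_len(n_cl), function(ci) {
      if (n_cl == 1L) sp_anc else evolve_seq(sp_anc, cl_depth / 2, config$kappa)
    })
    names(cl_anc) <- paste0(taxon, "#", seq_len(n_cl))
    ancestors <- c(ancestors, cl_anc)
    # round-robin specimens over clusters
    cl_of <- rep_len(seq_len(n_cl), nspec[k])
    ids <- sprintf("ADU%04d", spec_counter + seq_len(nspec[k]))
    spec_counter <- spec_counter + nspec[k]
    seqs <- vapply(cl_of, function(ci) {
      evolve_seq(cl_anc[[ci]], config$depth_intra / 2, config$kappa)
    }, character(1))
    records[[k]] <- data.frame(specimen_id = ids, sequence = seqs,
                               genus = genus, species = epithet,
                               life_stage = "adult", locality = "simulated",
                               stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(specimen_id = ids, taxon = taxon,
                             cluster = cl_of, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, records)
  truth <- do.call(rbind, truth)

  n_short <- round(config$short_fraction * nrow(records))
  if (n_short > 0) {
    short_idx <- sample(nrow(records), n_short)
    records$sequence[short_idx] <- pad_to(
      substr(records$sequence[short_idx], 1L, config$short_length), L)
    truth$truncated <- seq_len(nrow(truth)) %in% short_idx
  } else {
    truth$truncated <- FALSE
  }

  md <- records[, c("specimen_id", "genus", "species", "life_stage", "locality")]
  ref <- suppressWarnings(build_library(
    stats::setNames(records$sequence, records$specimen_id), md,
    min_length = min(267, config$short_length), alignment_length = L))
  structure(list(records = records, truth = truth, ancestors = ancestors,
                 ref = ref, config = config), class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("Simulated barcode library: %d specimens, %d species (%d with planted splits), seed %d\n",
              nrow(x$records), length(unique(x$truth$taxon)),
              if (is.null(x$config$split_plan)) 0L else nrow(x$config$split_plan),
              x$config$seed))
  invisible(x)
}

#' Simulate larval query sequences from a library's ground truth
#'
#' Queries are drawn from the recorded cluster ancestors at
#' `depth_intra` (so a query's expected distance to conspecific
#' references equals the intraspecific depth), labelled
#' `life_stage = "larva"`, with their true taxon and cluster recorded.
#' The RNG is seeded from `config$seed` with a fixed offset so queries
#' are reproducible but independent of library generation order.
#'
#' @param sim A `sim_library`.
#' @param config A `sim_config`; defaults to the library's.
#' @return Object of class `sim_queries`: list with `records` (query
#'   data.frame) and `truth` (query_id, taxon, cluster).
#' @export
simulate_queries <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_library"))
  set.seed((config$seed %% 2000000000L) + 7919L)
  taxa <- unique(sim$truth$taxon)
  if (!is.null(config$query_plan)) {
    plan <- config$query_plan
    plan$taxon <- taxa[plan$species]
  } else if (config$n_queries_per_species > 0) {
    plan <- data.frame(species = seq_along(taxa), cluster = 1L,
                       n = config$n_queries_per_species, taxon = taxa)
  } else {
    plan <- data.frame(species = integer(0), cluster = integer(0),
                       n = integer(0), taxon = character(0))
  }
  rows <- list(); truths <- list(); qc <- 0L
  for (i in seq_len(nrow(plan))) {
    anc_key <- paste0(plan$taxon[i], "#", plan$cluster[i])
    anc <- sim$ancestors[[anc_key]]
    if (is.null(anc)) stop("query_plan references unknown cluster: ", anc_key,
                           call. = FALSE)
    for (j in seq_len(plan$n[i])) {
      qc <- qc + 1L
      id <- sprintf("LAR%03d", qc)
      s <- evolve_seq(anc, config$depth_intra / 2, config$kappa)
      gsp <- strsplit(plan$taxon[i], " ", fixed = TRUE)[[1]]
      rows[[qc]] <- data.frame(specimen_id = id, sequence = s,
                               genus = gsp[1], species = gsp[2],
                               life_stage = "larva", locality = "simulated",
                               stringsAsFactors = FALSE)
      truths[[qc]] <- data.frame(query_id = id, taxon = plan$taxon[i],
                                 cluster = plan$cluster[i],
                                 stringsAsFactors = FALSE)
    }
  }
  records <- if (qc) do.call(rbind, rows) else
    data.frame(specimen_id = character(0), sequence = character(0),
               genus = character(0), species = character(0),
               life_stage = character(0), locality = character(0))
  truth <- if (qc) do.call(rbind, truths) else
    data.frame(query_id = character(0), taxon = character(0), cluster = integer(0))
  structure(list(records = records, truth = truth, config = config),
            class = "sim_queries")
}

#' Score identification results against simulator ground truth
#'
#' A query counts as correct when it was assigned and its assigned taxon
#' matches its true species; for species the detector split, the
#' assigned interim cluster must majority-overlap the query's true
#' cluster (interim names are ordered by size, the truth by generation
#' order, so labels are matched by membership, not by suffix).
#'
#' @param idres An `identification_set` from [batch_identify()].
#' @param query_truth The `truth` element of a `sim_queries`.
#' @param sim The `sim_library` the references came from.
#' @param splits The `split_report` used during identification (or NULL).
#' @return List with `correct` (logical per query, in `idres` order) and
#'   `accuracy`.
#' @export
score_against_truth <- function(idres, query_truth, sim, splits = NULL) {
  res <- idres$results
  truth <- query_truth[match(res$query_id, query_truth$query_id), ]
  correct <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    if (res$status[i] != "assigned") next
    assigned <- res$assigned_taxon[i]
    species_part <- sub("ECO[0-9]+$", "", assigned)
    if (species_part != truth$taxon[i]) next
    p <- if (!is.null(splits)) splits[[species_part]] else NULL
    if (is.null(p) || !p$flagged) {
      correct[i] <- !grepl("ECO[0-9]+$", assigned)
      next
    }
    # the expected interim label is the detected cluster holding the
    # majority of the query's true cluster's reference specimens
    true_members <- sim$truth$specimen_id[sim$truth$taxon == species_part &
                                            sim$truth$cluster == truth$cluster[i]]
    overlap <- vapply(p$clusters, function(cl) {
      length(intersect(cl, true_members))
    }, integer(1))
    correct[i] <- identical(assigned, p$interim_names[which.max(overlap)])
  }
  list(correct = correct, accuracy = if (nrow(res)) mean(correct) else NA_real_)
}

#' Write a simulated library (and optional queries) to disk
#'
#' Emits FASTA + metadata TSV consumable by [read_fasta()] and
#' [read_metadata()], plus truth TSVs.
#'
#' @param sim A `sim_library`.
#' @param dir Output directory (created if needed).
#' @param queries Optional `sim_queries` to include.
#' @return Invisibly, named vector of written paths.
#' @export
write_simulation <- function(sim, dir, queries = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- sim$records
  md_cols <- c("specimen_id", "genus", "species", "life_stage", "locality")
  md <- recs[, md_cols]
  seqs <- stats::setNames(recs$sequence, recs$specimen_id)
  truth <- sim$truth
  if (!is.null(queries) && nrow(queries$records)) {
    md <- rbind(md, queries$records[, md_cols])
    seqs <- c(seqs, stats::setNames(queries$records$sequence,
                                    queries$records$specimen_id))
    qt <- queries$truth
    write.table(qt, file.path(dir, "query_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "library_truth.tsv"))
  write_fasta(seqs, paths["fasta"])
  write.table(md, paths["metadata"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth, paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
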