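test_that("a clear nearest neighbour under the threshold is assigned", {
  set.seed(61)
  base <- rand_seq(658)
  far <- mutate_sites(base, 1:40, "transversion")
  ref <- make_ref(list("GenA sp1" = list(base, mutate_sites(base, 1:2, "transition")),
                       "GenB sp1" = list(far, mutate_sites(far, 5:6, "transition"))))
  q <- mutate_sites(base, 100:102, "transition")   # ~0.5% from sp1
  res <- identify_query(c(Q1 = q), ref)
  expect_equal(res$status, "assigned")
  expect_equal(res$assigned_taxon, "GenA sp1")
  expect_lt(res$best_distance, 0.01)
  expect_lte(res$best_distance, res$mean_distance_to_taxon)
  expect_equal(res$runner_up_taxon, "GenB sp1")
  expect_gt(res$margin, 0.04)
  expect_gt(res$similarity_pct, 99)
})

test_that("queries beyond the threshold from every reference get no match", {
  set.seed(62)
  base <- rand_seq(658)
  ref <- make_ref(list("GenA sp1" = list(base),
                       "GenA sp2" = list(mutate_sites(base, 1:30, "transversion"))))
  q <- mutate_sites(base, seq(2, 658, by = 3), "transversion")  # far from both
  res <- identify_query(c(Qfar = q), ref)
  expect_equal(res$status, "no_match")
  expect_true(is.na(res$assigned_taxon))
  expect_gte(res$best_distance, 0.02)
})

test_that("exact ties between two taxa are reported as ambiguous", {
  set.seed(63)
  s <- rand_seq(658)
  ref <- make_ref(list("GenA sp1" = list(s), "GenA sp2" = list(s)))
  res <- identify_query(c(Qtie = s), ref)
  expect_equal(res$status, "ambiguous")
  expect_true(is.na(res$assigned_taxon))
  expect_setequal(attr(res, "tied_taxa"), c("GenA sp1", "GenA sp2"))
})

test_that("insufficient overlap with all references is an explained no-match", {
  set.seed(64)
  base <- rand_seq(658)
  ref <- make_ref(list("GenA sp1" = list(base)))
  q <- paste0(substr(base, 1, 50), strrep("N", 608))
  res <- identify_query(c(Qshort = q), ref)
  expect_equal(res$status, "no_match")
  expect_match(attr(res, "reason"), "overlap")
})

test_that("every reference self-identifies at distance zero", {
  sim <- simulate_library(sim_config(n_genera = 3, species_per_genus = 2,
                                     specimens_per_species = 3,
                                     short_fraction = 0, seed = 65))
  ref <- sim$ref
  for (i in seq_len(nrow(ref$records))) {
    res <- identify_query(list(specimen_id = ref$records$specimen_id[i],
                               sequence = ref$records$sequence[i]), ref)
    expect_equal(res$status, "assigned")
    expect_equal(res$assigned_taxon, ref$records$taxon[i])
    expect_equal(res$best_distance, 0)
  }
})

test_that("assignments are invariant to library record order", {
  sim <- simulate_library(sim_config(n_genera = 3, species_per_genus = 2,
                                     specimens_per_species = 3,
                                     short_fraction = 0,
                                     n_queries_per_species = 1, seed = 66))
  qs <- simulate_queries(sim)
  ref <- sim$ref
  id1 <- batch_identify(qs$records, ref)
  perm <- sample(nrow(ref$records))
  ref2 <- ref
  ref2$records <- ref$records[perm, ]
  id2 <- batch_identify(qs$records, ref2)
  expect_equal(id2$results$assigned_taxon, id1$results$assigned_taxon)
  expect_equal(id2$results$best_distance, id1$results$best_distance)
})

test_that("queries from a split species are labelled with the interim cluster name", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2, specimens_per_species = 6,
                    split_plan = data.frame(species = 1, n_clusters = 2, depth = 0.05),
                    query_plan = data.frame(species = 1, cluster = 2, n = 3),
                    short_fraction = 0, seed = 67)
  sim <- simulate_library(cfg)
  dm <- distance_matrix(sim$ref)
  splits <- detect_splits(sim$ref, dm)
  qs <- simulate_queries(sim)
  idres <- batch_identify(qs$records, sim$ref, splits)
  expect_true(all(grepl("ECO0[12]$", idres$results$assigned_taxon)))
  sc <- score_against_truth(idres, qs$truth, sim, splits)
  expect_equal(sc$accuracy, 1)
})

test_that("an empty query set produces an empty report", {
  sim <- simulate_library(sim_config(n_genera = 2, species_per_genus = 2,
                                     specimens_per_species = 2,
                                     short_fraction = 0, seed = 68))
  idres <- batch_identify(sim$ref$queries, sim$ref)
  expect_equal(nrow(idres$results), 0)
  expect_equal(nrow(idres$taxon_summary), 0)
})

test_that("the per-taxon summary averages nearest-match distances per species", {
  sim <- simulate_library(sim_config(n_genera = 3, species_per_genus = 2,
                                     specimens_per_species = 3,
                                     n_queries_per_species = 2,
                                     short_fraction = 0, seed = 69))
  qs <- simulate_queries(sim)
  idres <- batch_identify(qs$records, sim$ref)
  expect_equal(sum(idres$taxon_summary$n_queries), nrow(qs$records))
  for (tx in idres$taxon_summary$taxon) {
    rows <- idres$results[idres$results$assigned_taxon == tx &
                            idres$results$status == "assigned", ]
    expect_equal(idres$taxon_summary$mean_dist[idres$taxon_summary$taxon == tx],
                 mean(rows$best_distance), tolerance = 1e-12)
  }
})

test_that("accuracy degrades monotonically as query depth approaches species depth", {
  accs <- vapply(c(0.003, 0.02, 0.05), function(dq) {
    cfg <- sim_config(n_genera = 4, species_per_genus = 2,
                      specimens_per_species = 3, depth_intra = 0.003,
                      depth_species = 0.05, short_fraction = 0,
                      n_queries_per_species = 3, seed = 70)
    sim <- simulate_library(cfg)
    qcfg <- cfg; qcfg$depth_intra <- dq
    qs <- simulate_queries(sim, qcfg)
    idres <- batch_identify(qs$records, sim$ref)
    sc <- score_against_truth(idres, qs$truth, sim)
    sc$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
  expect_equal(accs[1], 1)
})
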