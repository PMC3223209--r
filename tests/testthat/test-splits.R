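sym <- function(v, labs) {
  n <- length(labs)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  m[lower.tri(m)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

test_that("threshold components follow single-linkage chaining", {
  labs <- c("A", "B", "C")
  # A-B 0.01, A-C 0.025, B-C 0.01: chained into one component at 2%
  m <- sym(c(0.01, 0.025, 0.01), labs)
  expect_equal(threshold_components(labs, dist_obj(m), 0.02), list(c("A", "B", "C")))

  labs4 <- c("A", "B", "C", "D")
  m2 <- sym(c(0.005, 0.03, 0.03, 0.03, 0.03, 0.004), labs4)
  comps <- threshold_components(labs4, dist_obj(m2), 0.02)
  expect_setequal(lapply(comps, sort), list(c("A", "B"), c("C", "D")))

  # a pair at exactly the threshold stays together
  m3 <- sym(0.02, c("A", "B"))
  expect_equal(length(threshold_components(c("A", "B"), dist_obj(m3), 0.02)), 1)
  m4 <- sym(0.020001, c("A", "B"))
  expect_equal(length(threshold_components(c("A", "B"), dist_obj(m4), 0.02)), 2)
})

test_that("components match an exhaustive graph-reachability oracle", {
  set.seed(41)
  labs <- sprintf("N%02d", 1:8)
  for (rep in 1:30) {
    m <- sym(runif(28, 0, 0.05), labs)
    got <- threshold_components(labs, dist_obj(m), 0.02)
    want <- brute_components(labs, m, 0.02)
    expect_setequal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("raising the threshold never increases the cluster count", {
  set.seed(42)
  labs <- sprintf("N%02d", 1:9)
  for (rep in 1:10) {
    m <- sym(runif(36, 0, 0.06), labs)
    ks <- vapply(c(0.005, 0.01, 0.02, 0.03, 0.05), function(th) {
      length(threshold_components(labs, dist_obj(m), th))
    }, integer(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("flagged pairs abort clustering with the pairs listed", {
  labs <- c("A", "B", "C")
  m <- sym(c(0.01, 0.01, 0.01), labs)
  flags <- matrix("ok", 3, 3, dimnames = list(labs, labs))
  flags["B", "C"] <- flags["C", "B"] <- "insufficient_overlap"
  expect_error(threshold_components(labs, dist_obj(m, flags), 0.02), "B/C")
})

test_that("split detection recovers planted clusters and leaves shallow species alone", {
  cfg <- sim_config(n_genera = 4, species_per_genus = 3, specimens_per_species = 5,
                    split_plan = data.frame(species = c(2, 7),
                                            n_clusters = c(2, 3), depth = 0.05),
                    short_fraction = 0, seed = 43)
  sim <- simulate_library(cfg)
  dm <- distance_matrix(sim$ref)
  splits <- detect_splits(sim$ref, dm)
  planted <- unique(sim$truth$taxon)[c(2, 7)]
  expect_setequal(flagged_species(splits), planted)
  expect_equal(length(splits[[planted[1]]]$clusters), 2)
  expect_equal(length(splits[[planted[2]]]$clusters), 3)
  # unflagged species carry no interim names and a single covering cluster
  other <- setdiff(names(splits), planted)
  for (tx in other) {
    expect_null(splits[[tx]]$interim_names)
    expect_equal(length(splits[[tx]]$clusters), 1)
  }
  # between-cluster mean reflects the planted depth (4 sd tolerance)
  expect_gt(splits[[planted[1]]]$mean_between, 0.03)
})

test_that("a flag is raised iff the single-linkage merge height exceeds the threshold", {
  set.seed(44)
  for (rep in 1:20) {
    labs <- sprintf("S%02d", 1:7)
    m <- sym(runif(21, 0, 0.05), labs)
    # enforce metric-free but symmetric input; single-linkage height oracle
    h <- stats::hclust(stats::as.dist(m), method = "single")
    disconnected <- max(h$height) > 0.02
    k <- length(threshold_components(labs, dist_obj(m), 0.02))
    expect_equal(k > 1, disconnected)
  }
})

test_that("single-specimen species form one cluster and are never flagged", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                    specimens_per_species = c(1, 3, 1, 4),
                    short_fraction = 0, seed = 45)
  sim <- simulate_library(cfg)
  splits <- detect_splits(sim$ref, distance_matrix(sim$ref))
  singles <- names(which(table(sim$truth$taxon) == 1))
  for (tx in singles) {
    expect_false(splits[[tx]]$flagged)
    expect_equal(length(splits[[tx]]$clusters), 1)
  }
  expect_equal(length(flagged_species(splits)), 0)
})

test_that("interim names follow the ECO numbering and ordering conventions", {
  p <- structure(list(species = "Biblis hyperia", genus = "Biblis",
                      epithet = "hyperia",
                      clusters = list(c("x1", "x2", "x3"),
                                      c("a1", "a2", "a3", "a4", "a5")),
                      flagged = TRUE, interim_names = NULL),
                 class = "cluster_partition")
  named <- assign_interim_names(p)
  expect_equal(named$interim_names, c("Biblis hyperiaECO01", "Biblis hyperiaECO02"))
  expect_equal(length(named$clusters[[1]]), 5)       # largest first

  p3 <- p; p3$clusters <- list(c("b1"), c("a1"), c("c1"))
  named3 <- assign_interim_names(p3)
  expect_equal(named3$interim_names[3], "Biblis hyperiaECO03")
  # equal sizes: ordered by smallest member id
  expect_equal(vapply(named3$clusters, `[`, character(1), 1), c("a1", "b1", "c1"))

  p1 <- p; p1$clusters <- list(c("a1", "a2"))
  expect_error(assign_interim_names(p1), ">= 2 clusters")
})

test_that("split table export mirrors the flagged-species report", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2, specimens_per_species = 6,
                    split_plan = data.frame(species = 1, n_clusters = 2, depth = 0.05),
                    short_fraction = 0, seed = 46)
  sim <- simulate_library(cfg)
  splits <- detect_splits(sim$ref, distance_matrix(sim$ref))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_split_table(splits, tf)
  tab <- read.delim(tf)
  expect_equal(nrow(tab), 2)
  expect_match(tab$interim_name[1], "ECO01$")
  expect_equal(sum(tab$cluster_size), 6)
})
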