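path_lengths <- function(tree) {
  n <- length(tree$tip.label)
  m <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(m) <- list(tree$tip.label, tree$tip.label)
  m
}

test_that("three-taxon tree solves the closed form", {
  D <- matrix(c(0, 0.02, 0.04,
                0.02, 0, 0.04,
                0.04, 0.04, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  expect_equal(length(tr$tip.label), 3)
  pl <- path_lengths(tr)
  expect_equal(pl["A", "B"], 0.02)
  # a = (d_AB + d_AC - d_BC)/2 = 0.01, b = 0.01, c = 0.03
  len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len[c("A", "B", "C")]), c(0.01, 0.01, 0.03))
  expect_equal(write_newick(tr, decimals = 2), "(A:0.01,B:0.01,C:0.03);")
})

test_that("four-taxon additive distances recover the generating tree", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(labs, labs))
  D["A", "B"] <- D["B", "A"] <- 0.03
  D["C", "D"] <- D["D", "C"] <- 0.07
  D["A", "C"] <- D["C", "A"] <- 0.05
  D["A", "D"] <- D["D", "A"] <- 0.06
  D["B", "C"] <- D["C", "B"] <- 0.06
  D["B", "D"] <- D["D", "B"] <- 0.07
  tr <- nj_tree(D)
  expect_equal(path_lengths(tr)[labs, labs], D, tolerance = 1e-12)
  truth <- ape::read.tree(text = "((A:0.01,B:0.02):0.01,C:0.03,D:0.04);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(truth)), 0,
               ignore_attr = TRUE)
  # internal edge 0.01
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(unname(internal), 0.01)
})

test_that("degenerate zero matrix joins in lexicographic order, all branches zero", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(labs, labs))
  tr1 <- nj_tree(D)
  expect_true(all(tr1$edge.length == 0))
  nw1 <- write_newick(tr1, decimals = 2)
  # identical result when rows arrive in a different order
  perm <- c(3, 1, 4, 2)
  tr2 <- nj_tree(D[perm, perm])
  expect_identical(write_newick(tr2, decimals = 2), nw1)
  # first join must be the lexicographically smallest pair {A, B}
  ab_parent <- tr1$edge[match(match(c("A", "B"), tr1$tip.label), tr1$edge[, 2]), 1]
  expect_equal(ab_parent[1], ab_parent[2])
})

test_that("NJ exactly recovers random additive trees (topology and path lengths)", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(6:10, 1)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- runif(nrow(true$edge), 0.001, 0.12)
    D <- ape::dist.nodes(true)[1:n, 1:n]
    dimnames(D) <- list(true$tip.label, true$tip.label)
    tr <- nj_tree(D)
    expect_equal(path_lengths(tr)[true$tip.label, true$tip.label], D,
                 tolerance = 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(tr), true), 0, ignore_attr = TRUE)
    # agreement with the reference NJ implementation
    ora <- ape::nj(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ora)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("leaf set is preserved and row order does not change the tree", {
  set.seed(32)
  true <- ape::rtree(8, rooted = FALSE)
  true$edge.length <- runif(nrow(true$edge), 0.01, 0.1)
  D <- ape::dist.nodes(true)[1:8, 1:8]
  dimnames(D) <- list(true$tip.label, true$tip.label)
  perm <- sample(8)
  tr1 <- nj_tree(D)
  tr2 <- nj_tree(D[perm, perm])
  expect_setequal(tr1$tip.label, rownames(D))
  expect_equal(ape::dist.topo(ape::unroot(tr1), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  expect_equal(path_lengths(tr2)[rownames(D), rownames(D)],
               path_lengths(tr1)[rownames(D), rownames(D)], tolerance = 1e-9)
})

test_that("Newick output quotes unsafe labels and round-trips through a parser", {
  labs <- c("Biblis hyperiaECO02", "Marpesia chiron", "Consul electra")
  D <- matrix(c(0, 0.02, 0.08, 0.02, 0, 0.08, 0.08, 0.08, 0), 3, 3,
              dimnames = list(labs, labs))
  txt <- write_newick(nj_tree(D), decimals = 4)
  expect_match(txt, "'Biblis hyperiaECO02'", fixed = TRUE)
  back <- ape::read.tree(text = txt)
  # the parser keeps the quote characters; strip them before comparing
  expect_setequal(gsub("'", "", back$tip.label), labs)

  set.seed(33)
  true <- ape::rtree(7, rooted = FALSE)
  true$edge.length <- round(runif(nrow(true$edge), 0.01, 0.2), 6)
  D2 <- ape::dist.nodes(true)[1:7, 1:7]
  dimnames(D2) <- list(true$tip.label, true$tip.label)
  tr <- nj_tree(D2)
  back2 <- ape::read.tree(text = write_newick(tr, decimals = 6))
  expect_equal(ape::dist.topo(ape::unroot(back2), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back2$edge.length), sort(unname(tr$edge.length)),
               tolerance = 1e-9)
})

test_that("negative branch estimates are clamped to zero", {
  # near-degenerate distances known to produce a negative leaf estimate
  labs <- c("A", "B", "C", "D")
  D <- matrix(c(0, 0.01, 0.011, 0.012,
                0.01, 0, 0.002, 0.003,
                0.011, 0.002, 0, 0.001,
                0.012, 0.003, 0.001, 0), 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("trees demand at least three resolvable taxa and clean pairs", {
  D <- matrix(c(0, 0.1, 0.1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(nj_tree(D), "at least 3")
  m <- matrix(0.05, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(m) <- 0
  flags <- matrix("ok", 3, 3, dimnames = dimnames(m))
  flags["A", "B"] <- flags["B", "A"] <- "saturated"
  expect_error(nj_tree(dist_obj(m, flags)), "A/B")
})

test_that("conspecific specimens cluster together when depths are nested", {
  sim <- simulate_library(sim_config(n_genera = 3, species_per_genus = 3,
                                     specimens_per_species = 4, seed = 34))
  tr <- nj_tree(distance_matrix(sim$ref))
  for (tx in unique(sim$truth$taxon)) {
    ids <- sim$truth$specimen_id[sim$truth$taxon == tx]
    expect_true(ape::is.monophyletic(tr, ids))
  }
})
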