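#' Neighbour-joining tree from a distance matrix
#'
#' Saitou & Nei agglomeration with the Q-criterion
#' `Q(i,j) = (r - 2) d(i,j) - R_i - R_j`, `R_i = sum_k d(i,k)`.  Branch
#' lengths come from the standard formulas; negative estimates are
#' clamped to zero (logged, not redistributed).  Ties on Q are broken
#' deterministically by the lexicographically smallest pair of clade
#' representative labels (the smallest leaf label within each clade), so
#' the result does not depend on input row order.  The unrooted tree is
#' represented with the final three-way join as the top node.
#'
#' @param dmat A `barcode_dist` (all pairs must be flag `"ok"`) or a
#'   symmetric numeric matrix with dimnames.
#' @return An [ape::phylo] tree whose tip labels are the matrix ids.
#' @export
nj_tree <- function(dmat) {
  if (inherits(dmat, "barcode_dist")) {
    bad <- which(dmat$flags != "ok" & upper.tri(dmat$flags), arr.ind = TRUE)
    if (nrow(bad)) {
      pairs <- apply(bad, 1L, function(ij) {
        paste0(dmat$ids[ij[1]], "/", dmat$ids[ij[2]])
      })
      stop("cannot build NJ tree: unresolved flagged pair(s): ",
           paste(head(pairs, 10L), collapse = ", "),
           if (length(pairs) > 10L) ", ..." else "", call. = FALSE)
    }
    D <- dmat$d
  } else {
    D <- as.matrix(dmat)
  }
  labs <- rownames(D)
  if (is.null(labs)) stop("distance matrix must carry ids as dimnames", call. = FALSE)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa for an NJ tree", call. = FALSE)
  if (anyNA(D)) stop("distance matrix contains missing values", call. = FALSE)

  node_id <- seq_len(n)           # tips 1..n; internals appended
  rep_lab <- labs                 # clade representative for tie-breaks
  next_id <- n + 1L
  # children[[k]] holds (child id, branch length) pairs of internal node n+k
  children <- vector("list", n - 2L)
  n_clamped <- 0L
  Dm <- D

  clamp <- function(x) {
    if (x < 0) { n_clamped <<- n_clamped + 1L; 0 } else x
  }

  while (length(node_id) > 3L) {
    r <- length(node_id)
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    la <- rep_lab[cand[, 1]]; lb <- rep_lab[cand[, 2]]
    sel <- order(pmin(la, lb), pmax(la, lb))[1]
    i <- cand[sel, 1]; j <- cand[sel, 2]
    dij <- Dm[i, j]
    li <- clamp(dij / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(dij / 2 + (R[j] - R[i]) / (2 * (r - 2)))
    u <- next_id; next_id <- next_id + 1L
    children[[u - n]] <- list(ids = c(node_id[i], node_id[j]), len = c(li, lj))
    keep <- setdiff(seq_len(r), c(i, j))
    dnew <- (Dm[i, keep] + Dm[j, keep] - dij) / 2
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    node_id <- c(node_id[keep], u)
    rep_lab <- c(rep_lab[keep], min(rep_lab[i], rep_lab[j]))
  }

  # final trifurcation
  dab <- Dm[1, 2]; dac <- Dm[1, 3]; dbc <- Dm[2, 3]
  la <- clamp((dab + dac - dbc) / 2)
  lb <- clamp((dab + dbc - dac) / 2)
  lc <- clamp((dac + dbc - dab) / 2)
  root <- next_id
  children[[root - n]] <- list(ids = node_id[1:3], len = c(la, lb, lc))

  if (n_clamped > 0) {
    log_event("NJ: %d negative branch length estimate(s) clamped to 0", n_clamped)
  }

  # Renumber internals in preorder from the root (ape cladewise layout).
  n_internal <- root - n
  new_num <- integer(root)
  new_num[seq_len(n)] <- seq_len(n)
  counter <- n
  assign_num <- function(old) {
    counter <<- counter + 1L
    new_num[old] <<- counter
  }
  assign_num(root)
  edges_p <- integer(0); edges_c <- integer(0); edges_l <- numeric(0)
  walk <- function(old) {
    kids <- children[[old - n]]
    for (t in seq_along(kids$ids)) {
      ch <- kids$ids[t]
      if (ch > n) {
        assign_num(ch)
        edges_p <<- c(edges_p, new_num[old]); edges_c <<- c(edges_c, new_num[ch])
        edges_l <<- c(edges_l, kids$len[t])
        walk(ch)
      } else {
        edges_p <<- c(edges_p, new_num[old]); edges_c <<- c(edges_c, ch)
        edges_l <<- c(edges_l, kids$len[t])
      }
    }
  }
  old_limit <- getOption("expressions")
  if (n > 1000L) options(expressions = 500000L)
  on.exit(options(expressions = old_limit), add = TRUE)
  walk(root)

  tree <- structure(list(edge = cbind(edges_p, edges_c),
                         edge.length = unname(edges_l),
                         tip.label = labs,
                         Nnode = n_internal),
                    class = "phylo", order = "cladewise")
  dimnames(tree$edge) <- NULL
  tree
}

needs_quoting <- function(lab) grepl("[^A-Za-z0-9_.|-]", lab)

quote_label <- function(lab) {
  if (needs_quoting(lab)) paste0("'", gsub("'", "''", lab), "'") else lab
}

#' Serialize a tree to Newick text
#'
#' Writes branch lengths with a fixed number of decimals and single-quotes
#' any label containing spaces or other Newick-unsafe characters.
#'
#' @param tree An [ape::phylo] tree.
#' @param decimals Decimal places for branch lengths.
#' @param path Optional file to write the Newick string to.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, decimals = 6, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) formatC(x, format = "f", digits = decimals)
  build <- function(node) {
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      ch <- tree$edge[r, 2]
      sub <- if (ch <= n) quote_label(tree$tip.label[ch]) else build(ch)
      paste0(sub, ":", fmt(tree$edge.length[r]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- n + 1L
  txt <- paste0(build(root), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
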