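# Random rooted trees with branch lengths, built as Newick text so the
# generator is independent of the package's tree machinery. Occasional
# polytomies and zero-length edges are included on purpose.
random_tree_newick <- function(n_tips, seed = NULL,
                               polytomy_prob = 0.15, zero_prob = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  labels <- paste0("t", seq_len(n_tips))
  elen <- function() {
    if (stats::runif(1) < zero_prob) 0 else round(stats::runif(1, 0.05, 2), 4)
  }
  nodes <- as.list(labels)
  while (length(nodes) > 1L) {
    k <- if (length(nodes) > 2L && stats::runif(1) < polytomy_prob) 3L else 2L
    k <- min(k, length(nodes))
    pick <- sample.int(length(nodes), k)
    merged <- paste0("(", paste(vapply(nodes[pick], function(s)
      paste0(s, ":", elen()), character(1)), collapse = ","), ")")
    nodes <- c(nodes[-pick], merged)
  }
  paste0(nodes[[1]], ";")
}

# Brute-force phylogenetic vcv by explicit root-to-tip path enumeration on
# the raw edge table: entry (i,j) = summed length of edges shared by the
# two root-to-tip paths.
brute_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  path_edges <- lapply(seq_len(n), function(tip) {
    p <- integer(0)
    v <- tip
    while (v != root) {
      e <- parent_edge[v]
      p <- c(p, e)
      v <- tree$edge[e, 1L]
    }
    p
  })
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in i:n) {
      shared <- intersect(path_edges[[i]], path_edges[[j]])
      V[i, j] <- V[j, i] <- sum(tree$edge.length[shared])
    }
  }
  V
}

# small fixed tree shapes used by the Brownian-motion calibration checks
balanced_tree8 <- function() {
  ratemorph::read_newick(
    "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
}
caterpillar_tree8 <- function() {
  ratemorph::read_newick(
    "(a:7,(b:6,(c:5,(d:4,(e:3,(f:2,(g:1,h:1):1):1):1):1):1):1);")
}
star_tree <- function(n, depth = 1) {
  ratemorph::read_newick(paste0(
    "(", paste0("s", seq_len(n), ":", depth, collapse = ","), ");"))
}

# Monte-Carlo Brownian tip covariance vs sigma2 * vcv; returns the relative
# Frobenius error
bm_frobenius_error <- function(tree, sigma2 = 1, n_rep = 2000, seed = 1) {
  set.seed(seed)
  X <- t(replicate(n_rep, ratemorph::simulate_bm(tree, sigma2 = sigma2)))
  emp <- stats::cov(X)
  target <- sigma2 * ratemorph::phylo_vcv(tree)
  norm(emp - target[colnames(X), colnames(X)], "F") / norm(target, "F")
}
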