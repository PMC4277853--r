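# Shared fixtures and independent oracles. Oracles are deliberately naive
# (explicit loops, path enumeration) and never share code with the package
# implementation they check.

# labelled binary/weighted matrix shorthand
lmat <- function(x, nrow, byrow = TRUE) {
  m <- matrix(x, nrow = nrow, byrow = byrow)
  dimnames(m) <- list(paste0("p", seq_len(nrow(m))),
                      paste0("a", seq_len(ncol(m))))
  m
}

# random connected binary matrix (rejection at small sizes is cheap)
random_binary <- function(nr, nc, fill = 0.4) {
  repeat {
    m <- lmat(rbinom(nr * nc, 1, fill), nr, byrow = FALSE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

random_quantitative_net <- function(nr, nc, fill = 0.5) {
  m <- random_binary(nr, nc, fill)
  m[m > 0] <- 1 + rpois(sum(m > 0), 3)
  bipartite_network(m, quantitative = TRUE)
}

# Brute-force NODF: explicit ordered scan over row pairs and column pairs;
# each unordered pair contributes through at most one ordering (the one with
# strictly decreasing fill).
nodf_brute <- function(m) {
  b <- (as.matrix(m) > 0) * 1
  half <- function(b) {
    tot <- 0
    for (u in seq_len(nrow(b))) {
      for (v in seq_len(nrow(b))) {
        if (u == v) next
        ku <- sum(b[u, ]); kv <- sum(b[v, ])
        if (ku > kv && kv > 0) {
          shared <- sum(b[u, ] == 1 & b[v, ] == 1)
          tot <- tot + 100 * shared / kv
        }
      }
    }
    tot
  }
  (half(b) + half(t(b))) /
    (choose(nrow(b), 2) + choose(ncol(b), 2))
}

# Brute-force patristic distance by path enumeration on the tree edges.
patristic_brute <- function(tree, a, b) {
  # build parent map with edge lengths
  n_tip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  plen <- numeric(max(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  path_to_root <- function(node) {
    nodes <- node; d <- 0
    while (parent[node] != 0) {
      d <- c(d, d[length(d)] + plen[node])
      node <- parent[node]
      nodes <- c(nodes, node)
    }
    setNames(d, nodes)
  }
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  pa <- path_to_root(ia); pb <- path_to_root(ib)
  shared <- intersect(names(pa), names(pb))
  mrca <- shared[which.min(pa[shared])]
  pa[mrca] + pb[mrca]
}

# tiny quantitative network with both exotic and native plants
fixture_quant_net <- function(seed = 42) {
  set.seed(seed)
  m <- lmat(c(3, 1, 0, 2,
              0, 2, 4, 1,
              1, 0, 2, 3,
              2, 3, 1, 0), 4)
  bipartite_network(m, quantitative = TRUE, exotic = c("p2", "p4"))
}
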