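# Independent brute-force oracles. Each one re-derives its statistic from the
# printed definition, by direct enumeration, without sharing code paths with
# the package implementation.

bf_bray <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[[i]] - y[[i]])
    den <- den + x[[i]] + y[[i]]
  }
  num / den
}

# Patristic distance by walking root-to-tip paths: distance(i, j) =
# depth(i) + depth(j) - 2 * depth(mrca).
bf_patristic <- function(tree) {
  nt <- length(tree$tip.label)
  parent <- integer(nt + tree$Nnode)
  plen <- numeric(nt + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  path_to_root <- function(node) {
    nodes <- node
    while (parent[node] != 0) {
      node <- parent[node]
      nodes <- c(nodes, node)
    }
    nodes
  }
  depth <- function(node) {
    s <- 0
    while (parent[node] != 0) {
      s <- s + plen[node]
      node <- parent[node]
    }
    s
  }
  D <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    common <- intersect(path_to_root(i), path_to_root(j))
    # the MRCA is the common ancestor with the greatest depth
    mrca <- common[which.max(vapply(common, depth, numeric(1)))]
    D[i, j] <- D[j, i] <- depth(i) + depth(j) - 2 * depth(mrca)
  }
  D
}

# Unweighted UniFrac from the clade bipartitions reported by ape::prop.part
# (an independent route to per-branch descendant sets).
bf_unifrac_pair <- function(tree, present_a, present_b) {
  nt <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  tips_below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) tips_below[[i]] <- tree$tip.label[i]
  for (i in seq_along(parts))
    tips_below[[nt + i]] <- tree$tip.label[parts[[i]]]
  shared <- 0; total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    below <- tips_below[[tree$edge[e, 2]]]
    in_a <- any(below %in% present_a)
    in_b <- any(below %in% present_b)
    if (in_a || in_b) total <- total + tree$edge.length[e]
    if (in_a && in_b) shared <- shared + tree$edge.length[e]
  }
  1 - shared / total
}

# Weighted betaMNTD by double loop over present taxa.
bf_bmntd <- function(fa, fb, D) {
  a <- fa[fa > 0]; b <- fb[fb > 0]
  s1 <- 0
  for (i in names(a)) s1 <- s1 + a[[i]] * min(D[i, names(b)])
  s2 <- 0
  for (j in names(b)) s2 <- s2 + b[[j]] * min(D[names(a), j])
  0.5 * (s1 + s2)
}

# ANOSIM R from its definition (ranks of all pairwise dissimilarities).
bf_anosim_r <- function(dm, groups) {
  m <- as.matrix(dm)
  n <- nrow(m)
  v <- c(); within <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- c(v, m[i, j])
    within <- c(within, groups[i] == groups[j])
  }
  r <- rank(v)
  (mean(r[!within]) - mean(r[within])) / (length(v) / 2)
}

bf_mantel_r <- function(d1, d2, method = "pearson") {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  v1 <- m1[lower.tri(m1)]; v2 <- m2[lower.tri(m2)]
  cor(v1, v2, method = method)
}

# Random fixture: small count table with guaranteed non-empty samples.
random_table <- function(n_taxa, n_samples, max_count = 20) {
  repeat {
    m <- matrix(rpois(n_taxa * n_samples, 3), n_taxa, n_samples,
                dimnames = list(paste0("Z", seq_len(n_taxa)),
                                paste0("s", seq_len(n_samples))))
    if (all(colSums(m) > 0) && all(rowSums(m) > 0)) return(zotu_table(m))
  }
}

random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, tip.label = paste0("Z", seq_len(n_tips)))
  tr$edge.length <- tr$edge.length + 0.05
  tr
}
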