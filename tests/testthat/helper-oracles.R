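# Independent oracles used across tests. These deliberately take the
# slowest, most literal route (path walking, exhaustive enumeration,
# double loops) so they share no code with the implementation they check.

# Patristic distance by explicit root-path walking.
oracle_patristic <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent_of <- integer(n + tree$Nnode)
  len_to_parent <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent_of[tree$edge[e, 2]] <- tree$edge[e, 1]
    len_to_parent[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  path_to_root <- function(node) {
    path <- node
    while (node != root) {
      node <- parent_of[node]
      path <- c(path, node)
    }
    path
  }
  labs <- sort(tree$tip.label)
  idx <- match(labs, tree$tip.label)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (a in seq_len(n - 1)) {
    pa <- path_to_root(idx[a])
    for (b in (a + 1):n) {
      pb <- path_to_root(idx[b])
      mrca <- intersect(pa, pb)[1]
      walk <- function(from) {
        tot <- 0
        while (from != mrca) {
          tot <- tot + len_to_parent[from]
          from <- parent_of[from]
        }
        tot
      }
      D[a, b] <- D[b, a] <- walk(idx[a]) + walk(idx[b])
    }
  }
  D
}

# MPD by explicit double loop.
oracle_mpd <- function(species, D) {
  tot <- 0; npairs <- 0
  for (a in seq_along(species)) {
    for (b in seq_along(species)) {
      if (a < b) {
        tot <- tot + D[species[a], species[b]]
        npairs <- npairs + 1
      }
    }
  }
  tot / npairs
}

# Exact taxa-label-shuffle null for a k-species site in a pool of np
# species: uniform over all C(np, k) subsets (each subset is induced by
# the same number of label permutations). Returns population mean and sd.
oracle_exhaustive_null <- function(D, k) {
  labs <- rownames(D)
  sets <- utils::combn(labs, k, simplify = FALSE)
  vals <- vapply(sets, oracle_mpd, numeric(1), D = D)
  list(mean = mean(vals),
       sd = sqrt(mean((vals - mean(vals))^2)),
       values = vals)
}

# Log clade-credibility score of one tree against a sample, via string
# clade identifiers built from sorted tip labels (root clade excluded).
oracle_clades <- function(tree) {
  n <- ape::Ntip(tree)
  out <- character(0)
  for (node in (n + 1):(n + tree$Nnode)) {
    tips <- tree$tip.label[
      setdiff(unlist(phangorn::Descendants(tree, node, "tips")), integer(0))]
    if (length(tips) < n) {
      out <- c(out, paste(sort(tips), collapse = "|"))
    }
  }
  out
}

oracle_mcc_scores <- function(trees) {
  all_clades <- lapply(trees, oracle_clades)
  freq <- table(unlist(all_clades))
  vapply(all_clades, function(cl) {
    sum(log(as.numeric(freq[cl]) / length(trees)))
  }, numeric(1))
}

# Moran's I permutation envelope bounds for x under random relabeling.
oracle_moran_envelope <- function(x, W, n_perm = 999, prob = c(0.005, 0.995)) {
  obs <- ape::Moran.I(x, W)$observed
  null <- vapply(seq_len(n_perm), function(i) {
    ape::Moran.I(sample(x), W)$observed
  }, numeric(1))
  list(observed = obs, bounds = stats::quantile(null, prob))
}

# Small fixed trees used by several files.
tree_ab <- function() ape::read.tree(text = "(A:1,B:1);")
tree_abc <- function() ape::read.tree(text = "(A:1,(B:1,C:1):1);")
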