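#' Read one or more Newick trees from a file
#'
#' Multi-tree files hold one Newick string per line. When more than one
#' tree is present, all trees must share the same tip-label set.
#'
#' @param path path to a Newick file.
#' @return A list of `phylo` trees (class `multiPhylo`), in file order.
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop_param("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_param("no trees found in %s", path)
  trees <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tr <- tryCatch(ape::read.tree(text = lines[[i]]),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr) || !inherits(tr, "phylo")) {
      stop_param("malformed Newick at line %d of %s", i, path)
    }
    trees[[i]] <- tr
  }
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop_param("tip sets differ: tree at line %d does not match line 1", i)
    }
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Write trees to a Newick file, one per line
#'
#' @param trees a `phylo` object or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, ape::write.tree, character(1)), path)
  invisible(path)
}

#' Subsample a posterior tree sample without replacement
#'
#' @param trees list of `phylo` trees.
#' @param n_keep number of trees to keep, `1 <= n_keep <= length(trees)`.
#' @param seed integer RNG seed.
#' @return A uniform subsample of `n_keep` trees with original order
#'   preserved.
#' @export
subsample_posterior <- function(trees, n_keep, seed) {
  n <- length(trees)
  if (n_keep < 1 || n_keep > n) {
    stop_param("`n_keep` must be in [1, %d] (got %s)", n, format(n_keep))
  }
  keep <- with_seed(seed, sort(sample.int(n, n_keep)))
  out <- trees[keep]
  class(out) <- "multiPhylo"
  out
}

# Descendant-tip index sets (relative to `taxa`) for every internal node,
# via one postorder sweep. Returns character clade keys; the root clade
# (all tips) is the key of all indices.
clade_keys <- function(tree, taxa) {
  n <- ape::Ntip(tree)
  tip_idx <- match(tree$tip.label, taxa)
  if (anyNA(tip_idx)) stop_param("tree tips not in the common taxon set")
  tr <- stats::reorder(tree, "postorder")
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tip_idx[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  vapply(sets[(n + 1):(n + tree$Nnode)],
         function(s) paste(sort(s), collapse = "."), character(1))
}

# Mean distance from each node to its descendant tips (equals node age for
# ultrametric trees). Returns a vector over all node ids (tips are 0).
node_mean_tip_depth <- function(tree) {
  n <- ape::Ntip(tree)
  tr <- stats::reorder(tree, "postorder")
  tot <- numeric(n + tree$Nnode) # sum of distances to descendant tips
  cnt <- c(rep(1, n), numeric(tree$Nnode))
  cnt[(n + 1):(n + tree$Nnode)] <- 0
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; len <- tr$edge.length[e]
    tot[p] <- tot[p] + tot[ch] + len * cnt[ch]
    cnt[p] <- cnt[p] + cnt[ch]
  }
  tot / cnt
}

#' Maximum clade credibility tree from a posterior sample
#'
#' Scores every tree in the sample by the sum over its internal clades of
#' the log of that clade's frequency in the sample (the root clade, always
#' present, is excluded as a constant), and returns the highest-scoring
#' tree — ties broken by first occurrence. Each internal node of the
#' selected tree is then assigned the mean height of its clade across the
#' trees that contain it (height = mean distance to descendant tips, i.e.
#' node age on ultrametric trees), with child heights clamped below their
#' parent so the annotated tree remains a valid tree with non-negative
#' branch lengths.
#'
#' @param trees list of `phylo` trees on a common tip set.
#' @return The selected `phylo` tree with annotated branch lengths;
#'   attributes `log_clade_credibility` (its score) and `mcc_index` (its
#'   position in `trees`).
#' @export
mcc_tree <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop_param("`trees` must contain at least one tree")
  taxa <- sort(trees[[1]]$tip.label)
  n_tip <- length(taxa)
  root_key <- paste(seq_len(n_tip), collapse = ".")

  keys <- lapply(trees, clade_keys, taxa = taxa)
  freq <- table(unlist(lapply(keys, unique)))
  n_trees <- length(trees)

  scores <- vapply(keys, function(k) {
    k <- k[k != root_key]
    sum(log(as.numeric(freq[k]) / n_trees))
  }, numeric(1))
  best <- which.max(scores)

  # mean clade heights over the trees containing each clade
  h_sum <- new.env(parent = emptyenv())
  h_cnt <- new.env(parent = emptyenv())
  for (i in seq_len(n_trees)) {
    depth <- node_mean_tip_depth(trees[[i]])
    ki <- keys[[i]]
    ni <- ape::Ntip(trees[[i]])
    for (j in seq_along(ki)) {
      k <- ki[[j]]
      h_sum[[k]] <- (h_sum[[k]] %||% 0) + depth[ni + j]
      h_cnt[[k]] <- (h_cnt[[k]] %||% 0) + 1
    }
  }

  tree <- trees[[best]]
  n <- ape::Ntip(tree)
  kb <- keys[[best]]
  target <- numeric(n + tree$Nnode) # tips stay at height 0
  for (j in seq_along(kb)) {
    k <- kb[[j]]
    target[n + j] <- h_sum[[k]] / h_cnt[[k]]
  }

  # preorder clamp: child height strictly below parent height
  pre <- stats::reorder(tree, "postorder")
  height <- target
  eps <- 1e-9 * max(target)
  for (e in rev(seq_len(nrow(pre$edge)))) { # reverse postorder = preorder
    p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
    if (ch > n) height[ch] <- min(height[ch], height[p] - eps)
  }
  tree$edge.length <- height[tree$edge[, 1]] - height[tree$edge[, 2]]

  attr(tree, "log_clade_credibility") <- scores[best]
  attr(tree, "mcc_index") <- best
  tree
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' @param tree `phylo` tree with at least 2 tips and branch lengths.
#' @return A symmetric matrix of path lengths with zero diagonal, rows and
#'   columns in sorted tip-label order.
#' @export
patristic_distances <- function(tree) {
  if (ape::Ntip(tree) < 2) stop_param("tree must have >= 2 tips")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop_param("tree has missing branch lengths")
  }
  D <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(D))
  D[ord, ord]
}
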