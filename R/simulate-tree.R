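#' Simulate a birth-death phylogeny with a fixed number of tips
#'
#' Draws a rooted binary tree under a constant-rate birth-death process
#' conditioned on the number of extant tips, mirroring a regional species
#' pool (e.g. the resident avifauna of a study region). Tips are relabeled
#' `sp001`, `sp002`, ... so downstream community matrices have stable column
#' names.
#'
#' @param n_tips number of extant tips (>= 3).
#' @param birth_rate per-lineage speciation rate; must exceed `death_rate`.
#' @param death_rate per-lineage extinction rate (>= 0).
#' @param seed integer RNG seed; the same seed always yields the same tree.
#' @return An `ape::phylo` rooted binary tree with `n_tips` uniquely labeled
#'   tips and strictly positive branch lengths.
#' @export
#' @examples
#' tr <- simulate_tree(10, birth_rate = 1, death_rate = 0.2, seed = 1)
#' ape::Ntip(tr)
simulate_tree <- function(n_tips, birth_rate = 1, death_rate = 0, seed) {
  if (!is.numeric(n_tips) || n_tips < 3 || n_tips != round(n_tips)) {
    stop_param("`n_tips` must be an integer >= 3 (got %s)", format(n_tips))
  }
  if (!is.numeric(birth_rate) || !is.numeric(death_rate) ||
      death_rate < 0 || birth_rate <= death_rate) {
    stop_param("rates must satisfy birth_rate > death_rate >= 0")
  }
  tree <- with_seed(seed, ape::rphylo(n = n_tips, birth = birth_rate,
                                      death = death_rate))
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  # rphylo returns zero-length edges with probability zero; guard anyway
  # so the branch-length invariant is explicit.
  tree$edge.length <- pmax(tree$edge.length, .Machine$double.eps)
  tree
}

#' Simulate a pseudo-posterior sample around a reference tree
#'
#' Emulates a posterior distribution of phylogenies by perturbing a
#' reference tree: branch lengths are multiplied by positive lognormal
#' noise, and with probability `topology_swap_prob` a single random
#' nearest-neighbor interchange is applied. All trees share the reference
#' tip set.
#'
#' @param tree reference `phylo` tree.
#' @param n_trees number of trees to generate (>= 1).
#' @param jitter_sd standard deviation (log scale) of the multiplicative
#'   branch-length noise; 0 leaves lengths untouched.
#' @param topology_swap_prob probability in \[0, 1\] that a tree receives one
#'   random NNI move.
#' @param seed integer RNG seed.
#' @return A list of `phylo` trees of length `n_trees` (class `multiPhylo`).
#' @export
simulate_posterior_sample <- function(tree, n_trees, jitter_sd = 0.1,
                                      topology_swap_prob = 0.2, seed) {
  if (is.null(tree) || !inherits(tree, "phylo") || ape::Ntip(tree) < 2) {
    stop_param("`tree` must be a phylo object with >= 2 tips")
  }
  if (n_trees < 1) stop_param("`n_trees` must be >= 1")
  if (jitter_sd < 0) stop_param("`jitter_sd` must be >= 0")
  if (topology_swap_prob < 0 || topology_swap_prob > 1) {
    stop_param("`topology_swap_prob` must be in [0, 1]")
  }
  out <- with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      tr <- tree
      if (jitter_sd > 0) {
        tr$edge.length <- tr$edge.length *
          exp(stats::rnorm(length(tr$edge.length), 0, jitter_sd))
      }
      if (stats::runif(1) < topology_swap_prob) {
        tr <- phangorn::rNNI(tr, moves = 1)
      }
      tr
    })
  })
  class(out) <- "multiPhylo"
  out
}
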