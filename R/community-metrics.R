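#' Mean pairwise phylogenetic distance of a species set
#'
#' The unweighted mean of the patristic distance over all unordered
#' distinct pairs of species in the set (presence/absence; occurrence
#' data carry no abundances).
#'
#' @param species_set character vector of at least two species labels.
#' @param distances patristic distance matrix with labeled rows/columns.
#' @return The mean pairwise distance (branch-length units).
#' @export
#' @examples
#' tr <- simulate_tree(10, seed = 1)
#' D <- patristic_distances(tr)
#' mpd(c("sp001", "sp002", "sp003"), D)
mpd <- function(species_set, distances) {
  species_set <- unique(species_set)
  if (length(species_set) < 2) {
    stop_param("MPD is undefined for fewer than 2 species")
  }
  miss <- setdiff(species_set, rownames(distances))
  if (length(miss)) {
    stop_param("species not in distance matrix: %s",
               paste(miss, collapse = ", "))
  }
  d <- distances[species_set, species_set]
  mean(d[upper.tri(d)])
}

#' Net Relatedness Index per site under a taxa-label permutation null
#'
#' For each site the observed mean pairwise distance (MPD) of its species
#' is compared with a null distribution obtained by shuffling the labels
#' of the distance matrix `n_null` times and recomputing MPD of the same
#' species set under each relabeling (equivalently: random draws of equal
#' richness from the pool). The index is the negated z-score,
#' `NRI = -(MPD_obs - mean_null) / sd_null`: positive values mean the
#' assemblage is more closely related than expected (phylogenetically
#' clustered), negative values mean overdispersion.
#'
#' One permutation stream is shared across sites: each of the `n_null`
#' relabelings is applied to every site, so results are reproducible and
#' site-order independent.
#'
#' @param community_matrix binary sites x species matrix (rows: site IDs,
#'   columns: species labels).
#' @param distances patristic distance matrix whose labels cover the
#'   community columns.
#' @param n_null number of null permutations (default 999).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param pool `"tree"` (default) shuffles all labels of the distance
#'   matrix — the full species pool of the phylogeny; `"observed"`
#'   restricts the pool to species observed in at least one site.
#' @return A data.frame with one row per site: `site_id`, `n_species`,
#'   `mpd_obs`, `null_mean`, `null_sd`, `nri`, `n_null`, and a `flag`
#'   column (`""`, `"fewer_than_2_species"`, or `"degenerate_null"`).
#'   Sites with fewer than 2 species or a zero-variance null get `NA`
#'   rather than an infinite or silent value.
#' @export
nri <- function(community_matrix, distances, n_null = 999, seed,
                pool = c("tree", "observed")) {
  pool <- match.arg(pool)
  if (n_null < 1) stop_param("`n_null` must be >= 1")
  cm <- as.matrix(community_matrix)
  if (!all(cm %in% c(0, 1))) stop_param("community matrix must be binary")
  if (is.null(rownames(cm))) rownames(cm) <- sprintf("site%03d", seq_len(nrow(cm)))
  unknown <- setdiff(colnames(cm), rownames(distances))
  if (length(unknown)) {
    stop_param("community species not in distance matrix: %s",
               paste(unknown, collapse = ", "))
  }

  pool_labels <- if (pool == "tree") rownames(distances) else {
    colnames(cm)[colSums(cm) > 0]
  }
  D <- distances[pool_labels, pool_labels]
  np <- length(pool_labels)

  # incidence aligned to the pool (absent pool species get zero columns)
  S <- matrix(0, nrow(cm), np, dimnames = list(rownames(cm), pool_labels))
  keep <- intersect(colnames(cm), pool_labels)
  S[, keep] <- cm[, keep]

  k <- rowSums(S)
  pairs2 <- k * (k - 1) # twice the number of unordered pairs
  ok <- k >= 2

  site_mpd <- function(Dm) {
    # sum_{i,j in site} Dm[i, j] = rowSums((S %*% Dm) * S); halve later
    rowSums((S %*% Dm) * S)
  }
  mpd_obs <- ifelse(ok, site_mpd(D) / pairs2, NA_real_)

  V <- matrix(NA_real_, nrow(S), n_null) # null MPD replicates, sites x reps
  with_seed(seed, {
    for (b in seq_len(n_null)) {
      perm <- sample.int(np)
      V[, b] <- site_mpd(D[perm, perm]) / pairs2
    }
  })
  null_mean <- ifelse(ok, rowMeans(V), NA_real_)
  null_sd <- if (n_null > 1) {
    ifelse(ok, sqrt(rowSums((V - null_mean)^2) / (n_null - 1)), NA_real_)
  } else {
    rep(NA_real_, nrow(S))
  }

  tol <- 1e-10 * pmax(abs(null_mean), 1)
  degen <- ok & !is.na(null_sd) & null_sd <= tol
  nri_val <- ifelse(ok & !degen, -(mpd_obs - null_mean) / null_sd, NA_real_)
  flag <- ifelse(!ok, "fewer_than_2_species",
                 ifelse(degen, "degenerate_null", ""))

  data.frame(site_id = rownames(S), n_species = as.integer(k),
             mpd_obs = mpd_obs, null_mean = null_mean, null_sd = null_sd,
             nri = nri_val, n_null = as.integer(n_null), flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}
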