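#' Random-forest predictive correlation under repeated random splits
#'
#' For each split the sites are partitioned uniformly at random into a
#' training half (`ceiling(n/2)` sites; odd n gives training the extra
#' site) and an evaluation half. A random-forest regressor is fit on the
#' training half and the Pearson correlation between its out-of-sample
#' predictions and the observed evaluation values is recorded. The score
#' is the mean correlation over splits. Splits where either the
#' predictions or the observations are constant (correlation undefined)
#' are excluded from the mean with a warning rather than silently imputed.
#'
#' @param y numeric response (e.g. log richness).
#' @param X_subset data.frame or matrix of predictors (>= 1 column).
#' @param n_splits number of random 50/50 splits (default 1000).
#' @param n_trees trees per forest (default 500).
#' @param seed integer RNG seed; scores are deterministic given the seed.
#' @return The mean Pearson correlation; the number of valid splits is
#'   attached as attribute `"n_valid"`.
#' @export
rf_split_score <- function(y, X_subset, n_splits = 1000, n_trees = 500,
                           seed) {
  X_subset <- as.data.frame(X_subset)
  n <- length(y)
  if (n < 8) stop_param("need at least 8 sites")
  if (!ncol(X_subset)) stop_param("predictor subset is empty")
  if (n_splits < 1) stop_param("`n_splits` must be >= 1")
  if (stats::sd(y) == 0) stop_param("constant response: correlation undefined")
  n_train <- ceiling(n / 2)
  cors <- with_seed(seed, {
    vapply(seq_len(n_splits), function(b) {
      train <- sample.int(n, n_train)
      # randomForest warns when a regression response has few unique
      # values; expected with small discrete richness, so muted here
      rf <- withCallingHandlers(
        randomForest::randomForest(
          x = X_subset[train, , drop = FALSE], y = y[train],
          ntree = n_trees),
        warning = function(w) {
          if (grepl("five or fewer unique values", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      pred <- stats::predict(rf, X_subset[-train, , drop = FALSE])
      obs <- y[-train]
      if (stats::sd(pred) == 0 || stats::sd(obs) == 0) NA_real_
      else stats::cor(pred, obs)
    }, numeric(1))
  })
  n_bad <- sum(is.na(cors))
  if (n_bad > 0) {
    warning(sprintf("%d of %d splits had constant predictions/observations%s",
                    n_bad, n_splits, " and were excluded"), call. = FALSE)
  }
  structure(mean(cors, na.rm = TRUE), n_valid = as.integer(n_splits - n_bad))
}

#' Enumerate all non-empty variable subsets
#'
#' Deterministic order: by subset size, then lexicographically by variable
#' name within each size.
#'
#' @param variables character vector of variable names.
#' @return A list of character vectors.
#' @export
#' @examples
#' enumerate_combinations(c("a", "b", "c"))
enumerate_combinations <- function(variables) {
  if (!length(variables)) stop_param("need at least one variable")
  vars <- sort(variables)
  out <- list()
  for (size in seq_along(vars)) {
    cmb <- utils::combn(vars, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Rank variable combinations by random-forest predictive correlation
#'
#' Scores every non-empty subset of `variables` with [rf_split_score()]
#' (each subset drawing its RNG substream from the master seed and the
#' subset's index, so scores do not depend on evaluation order), sorts
#' descending by mean correlation (ties: smaller subset first, then
#' lexicographic), then fits the SAR spatial error model on each of the
#' `top_k` best subsets and computes Akaike weights across those fits.
#'
#' @param site_table preprocessed (standardized) data.frame including the
#'   response, the candidate variables, and `x`/`y` centroids.
#' @param response response column name.
#' @param variables candidate predictor names.
#' @param n_splits random splits per subset (default 1000).
#' @param top_k number of top combinations to report (default 6).
#' @param n_trees trees per forest (default 500).
#' @param weights `spatial_weights`; built from the table with
#'   `weights_k` neighbors when omitted.
#' @param weights_k neighbors for [build_weights()] when `weights` is
#'   omitted (default 8).
#' @param seed master integer seed.
#' @return A data.frame with one row per reported combination: `rank`,
#'   `combination` (variables joined by `+`), one indicator column per
#'   candidate variable, `mean_pearson`, `n_splits`, `aic_weight`,
#'   `sar_pseudo_r2`, `sar_aic`.
#' @export
rank_combinations <- function(site_table, response, variables,
                              n_splits = 1000, top_k = 6, n_trees = 500,
                              weights = NULL, weights_k = 8, seed) {
  miss <- setdiff(c(response, variables), names(site_table))
  if (length(miss)) {
    stop_param("columns missing from site table: %s",
               paste(miss, collapse = ", "))
  }
  subsets <- enumerate_combinations(variables)
  if (top_k > length(subsets)) {
    stop_param("top_k (%d) exceeds the number of subsets (%d)",
               top_k, length(subsets))
  }
  y <- site_table[[response]]
  scores <- vapply(seq_along(subsets), function(i) {
    as.numeric(rf_split_score(y, site_table[, subsets[[i]], drop = FALSE],
                              n_splits = n_splits, n_trees = n_trees,
                              seed = stage_seed(seed, paste0("subset_", i))))
  }, numeric(1))

  key <- vapply(subsets, paste, character(1), collapse = "+")
  ord <- order(-scores, lengths(subsets), key)
  top <- ord[seq_len(top_k)]

  if (is.null(weights)) weights <- build_weights(site_table, k = weights_k)
  sar_fits <- lapply(top, function(i) {
    fit_sar_error(y, as.matrix(site_table[, subsets[[i]], drop = FALSE]),
                  weights)
  })
  aics <- vapply(sar_fits, `[[`, numeric(1), "aic")
  aw <- aic_weights(aics)

  out <- data.frame(rank = seq_len(top_k), combination = key[top],
                    stringsAsFactors = FALSE)
  for (v in sort(variables)) {
    out[[v]] <- vapply(subsets[top], function(s) as.integer(v %in% s),
                       integer(1))
  }
  out$mean_pearson <- scores[top]
  out$n_splits <- n_splits
  out$aic_weight <- aw
  out$sar_pseudo_r2 <- vapply(sar_fits, `[[`, numeric(1), "pseudo_r2")
  out$sar_aic <- aics
  out
}
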