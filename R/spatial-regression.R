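#' Derive Last-Glacial-Maximum climate change variables
#'
#' For each climate variable with two LGM reconstruction columns
#' (`<var>_LGM_ccsm`, `<var>_LGM_miroc`), the LGM value is the mean of the
#' two reconstructions and the change variable is contemporary minus LGM,
#' appended as `Change_<var>`.
#'
#' @param site_table data.frame of per-site covariates.
#' @param climate_vars contemporary climate columns to process.
#' @return `site_table` with `<var>_LGM` and `Change_<var>` columns
#'   appended (existing columns of those names are overwritten).
#' @export
derive_lgm_change <- function(site_table, climate_vars = c("MAT", "MAP")) {
  for (v in climate_vars) {
    r1 <- paste0(v, "_LGM_ccsm")
    r2 <- paste0(v, "_LGM_miroc")
    need <- c(v, r1, r2)
    miss <- setdiff(need, names(site_table))
    if (length(miss)) {
      stop_param("missing column(s) for %s: %s", v,
                 paste(miss, collapse = ", "))
    }
    lgm <- (site_table[[r1]] + site_table[[r2]]) / 2
    site_table[[paste0(v, "_LGM")]] <- lgm
    site_table[[paste0("Change_", v)]] <- site_table[[v]] - lgm
  }
  site_table
}

#' Log-transform and standardize analysis variables
#'
#' Applies a base-10 log to the named variables (richness-like quantities
#' and area; the base is cosmetic after standardization but fixed for
#' reporting), then centers and scales every analysis variable to sample
#' mean 0 and sample standard deviation 1 (n - 1 denominator).
#'
#' @param site_table data.frame.
#' @param log_vars columns to log10-transform first; must be strictly
#'   positive.
#' @param all_vars columns to standardize (defaults to `log_vars`); other
#'   columns pass through untouched.
#' @return The transformed data.frame; the per-variable log flags, means
#'   and sds are attached as attribute `"transforms"`.
#' @export
preprocess <- function(site_table, log_vars = character(),
                       all_vars = log_vars) {
  for (v in log_vars) {
    if (!v %in% names(site_table)) stop_param("unknown column: %s", v)
    bad <- which(site_table[[v]] <= 0)
    if (length(bad)) {
      ids <- if ("site_id" %in% names(site_table)) {
        site_table$site_id[bad]
      } else bad
      stop_param("non-positive values in log variable %s at site(s): %s",
                 v, paste(utils::head(ids, 5), collapse = ", "))
    }
    site_table[[v]] <- log10(site_table[[v]])
  }
  rec <- data.frame(variable = all_vars, logged = all_vars %in% log_vars,
                    mean = NA_real_, sd = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(all_vars)) {
    v <- all_vars[i]
    if (!v %in% names(site_table)) stop_param("unknown column: %s", v)
    x <- site_table[[v]]
    m <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop_param("variable %s is constant; cannot standardize", v)
    }
    site_table[[v]] <- (x - m) / s
    rec$mean[i] <- m
    rec$sd[i] <- s
  }
  attr(site_table, "transforms") <- rec
  site_table
}

#' Row-standardized symmetrized k-nearest-neighbor spatial weights
#'
#' Builds the k-nearest-neighbor graph on site centroids (Euclidean
#' distance), symmetrizes it (i and j are neighbors if either is among the
#' other's k nearest), and row-standardizes, so every row sums to 1.
#' Distance ties are broken by row order (site_id order) with a warning
#' when exact duplicates of coordinates occur.
#'
#' @param site_table data.frame with `x` and `y` columns (and optionally
#'   `site_id`).
#' @param k number of nearest neighbors, `1 <= k < n`.
#' @return An object of class `spatial_weights`: a list with the dense
#'   row-standardized matrix `W`, the binary symmetric adjacency `A`, and
#'   `k`.
#' @export
build_weights <- function(site_table, k = 8) {
  xy <- as.matrix(site_table[, c("x", "y")])
  n <- nrow(xy)
  if (k < 1 || k >= n) stop_param("`k` must satisfy 1 <= k < n (n = %d)", n)
  if (anyDuplicated(xy)) {
    warning("duplicate coordinates; neighbor ties broken by site order",
            call. = FALSE)
  }
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    # order() breaks ties by index, i.e. by site order
    A[i, order(d[i, ])[seq_len(k)]] <- 1
  }
  A <- pmax(A, t(A)) # symmetrize: union of neighbor relations
  W <- A / rowSums(A)
  ids <- if ("site_id" %in% names(site_table)) {
    as.character(site_table$site_id)
  } else as.character(seq_len(n))
  dimnames(W) <- dimnames(A) <- list(ids, ids)
  structure(list(W = W, A = A, k = k), class = "spatial_weights")
}

# Eigenvalues of a row-standardized weights matrix W = D^-1 A with A
# symmetric: identical to those of the symmetric D^-1/2 A D^-1/2, hence
# real; computed from the symmetric form for speed and stability.
weights_eigenvalues <- function(weights) {
  s <- 1 / sqrt(rowSums(weights$A))
  M <- weights$A * (s %o% s)
  eigen(M, symmetric = TRUE, only.values = TRUE)$values
}

#' Ordinary least squares fit with standardized reporting
#'
#' @param y numeric response.
#' @param X numeric matrix or data.frame of predictors (no intercept
#'   column; one is added).
#' @return A `regression_result` list: `kind = "OLS"`, `coefficients`,
#'   `intercept`, standard errors, `p_values` (Wald t-tests), `r2`
#'   (adjusted), `log_likelihood`, `aic` (Gaussian, counting the error
#'   variance), and `n`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) stop_param("missing values in y or X")
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop_param("need n > p + 1 observations")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1) {
    idx <- qrX$pivot[-seq_len(qrX$rank)]
    dep <- colnames(X)[idx[idx > 1] - 1]
    stop_param("rank-deficient design; collinear column(s): %s",
               paste(dep, collapse = ", "))
  }
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  co <- stats::coef(sm)
  structure(list(
    kind = "OLS",
    coefficients = stats::setNames(co[-1, 1], colnames(X)),
    intercept = co[1, 1],
    std_errors = stats::setNames(co[-1, 2], colnames(X)),
    p_values = stats::setNames(co[-1, 4], colnames(X)),
    r2 = sm$adj.r.squared,
    log_likelihood = as.numeric(stats::logLik(fit)),
    aic = stats::AIC(fit),
    n = n
  ), class = "regression_result")
}

#' Simultaneous autoregressive spatial error model by maximum likelihood
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ N(0, sigma^2 I)`.
#' The log-likelihood is concentrated over `lambda`: for a candidate
#' `lambda`, both sides are transformed by `(I - lambda W)` and `beta`,
#' `sigma^2` follow by least squares; the Jacobian term
#' `log|I - lambda W|` is evaluated from the (real) eigenvalues of the
#' row-standardized weights. `lambda` is profiled over the feasible
#' interval inside (-1, 1) with [stats::optimize()].
#'
#' The reported pseudo-r-squared is Nagelkerke's,
#' `1 - exp(-(2/n) (logL_model - logL_null))`, against a non-spatial
#' intercept-only null.
#'
#' @param y numeric response.
#' @param X predictors (no intercept column).
#' @param weights `spatial_weights` from [build_weights()].
#' @param lambda if supplied, the autoregressive parameter is fixed at
#'   this value instead of estimated (``lambda = 0`` reproduces OLS).
#' @return A `regression_result` list: `kind = "SAR_error"`,
#'   `coefficients`, `intercept`, `std_errors`, `p_values` (asymptotic z),
#'   `lambda`, `pseudo_r2`, `log_likelihood`, `aic` (counting intercept,
#'   slopes, lambda and the error variance), `n`, and
#'   `boundary` (TRUE when the optimizer stopped at the feasible-interval
#'   edge).
#' @export
fit_sar_error <- function(y, X, weights, lambda = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) stop_param("missing values in y or X")
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 2) stop_param("need n > p + 2 observations")
  W <- weights$W
  stopifnot(nrow(W) == n)
  Xi <- cbind(`(Intercept)` = 1, X)
  if (qr(Xi)$rank < ncol(Xi)) stop_param("singular design matrix")

  ev <- weights_eigenvalues(weights)
  lo <- max(-0.999, 1 / min(ev) + 1e-8)
  hi <- min(0.999, 1 / max(ev) - 1e-8)

  profile <- function(lam) {
    B <- diag(n) - lam * W
    yt <- B %*% y
    Xt <- B %*% Xi
    fit <- stats::lm.fit(Xt, yt)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / n
    ll <- -n / 2 * (log(2 * pi * sigma2) + 1) + sum(log(1 - lam * ev))
    list(ll = ll, fit = fit, sigma2 = sigma2, Xt = Xt)
  }

  boundary <- FALSE
  if (is.null(lambda)) {
    opt <- stats::optimize(function(l) profile(l)$ll, c(lo, hi),
                           maximum = TRUE, tol = 1e-9)
    lambda <- opt$maximum
    boundary <- (lambda - lo) < 1e-4 || (hi - lambda) < 1e-4
  } else if (lambda <= lo || lambda >= hi) {
    stop_param("fixed lambda outside the feasible interval (%.3f, %.3f)",
               lo, hi)
  }
  prof <- profile(lambda)
  beta <- stats::setNames(prof$fit$coefficients, colnames(Xi))
  # conditional (on lambda) ML covariance of beta
  vcov_beta <- prof$sigma2 * solve(crossprod(prof$Xt))
  se <- sqrt(diag(vcov_beta))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))

  ll_null <- as.numeric(stats::logLik(stats::lm(y ~ 1)))
  k <- ncol(Xi) + 2 # slopes + intercept, lambda, sigma^2
  structure(list(
    kind = "SAR_error",
    coefficients = beta[-1],
    intercept = beta[[1]],
    std_errors = se[-1],
    p_values = pval[-1],
    lambda = lambda,
    pseudo_r2 = 1 - exp(-(2 / n) * (prof$ll - ll_null)),
    log_likelihood = prof$ll,
    aic = 2 * k - 2 * prof$ll,
    n = n,
    boundary = boundary
  ), class = "regression_result")
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`; interpreted as the probability that model
#' i is the best of the compared set.
#'
#' @param aics numeric vector of finite AIC values.
#' @return Weights summing to 1.
#' @export
#' @examples
#' aic_weights(c(100, 102, 104))
aic_weights <- function(aics) {
  if (!length(aics) || any(!is.finite(aics))) {
    stop_param("all AIC values must be finite")
  }
  w <- exp(-(aics - min(aics)) / 2)
  w / sum(w)
}

#' Single-variable OLS and SAR regression battery
#'
#' Regresses the (preprocessed) response on each variable separately by
#' OLS and by the SAR spatial error model, reporting standardized
#' coefficients, adjusted r-squared (OLS), Nagelkerke pseudo-r-squared
#' (SAR), and Wald-test significance flags at p < .01 (uncorrected).
#'
#' @param site_table preprocessed (standardized) data.frame.
#' @param response response column name.
#' @param variables predictor column names.
#' @param weights `spatial_weights` for the SAR fits.
#' @return A data.frame with one row per variable: `variable`, `coef_OLS`,
#'   `r2_OLS`, `p_OLS`, `coef_SAR`, `r2_SAR`, `p_SAR`, `lambda_SAR`,
#'   `sig_OLS`, `sig_SAR`.
#' @export
single_variable_table <- function(site_table, response, variables, weights) {
  y <- site_table[[response]]
  rows <- lapply(variables, function(v) {
    X <- as.matrix(site_table[, v, drop = FALSE])
    o <- fit_ols(y, X)
    s <- fit_sar_error(y, X, weights)
    data.frame(variable = v,
               coef_OLS = unname(o$coefficients[1]),
               r2_OLS = o$r2,
               p_OLS = unname(o$p_values[1]),
               coef_SAR = unname(s$coefficients[1]),
               r2_SAR = s$pseudo_r2,
               p_SAR = unname(s$p_values[1]),
               lambda_SAR = s$lambda,
               sig_OLS = unname(o$p_values[1]) < 0.01,
               sig_SAR = unname(s$p_values[1]) < 0.01,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
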