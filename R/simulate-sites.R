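#' Default covariate specification for the site-table simulator
#'
#' One row per covariate: `mean` and `sd` give the covariate's location and
#' scale in its natural units; `scale = "log10"` exponentiates the latent
#' field so the emitted covariate is a positive count-like quantity (as for
#' plant species richness); `round` rounds the emitted values.
#'
#' The defaults emulate an arid/semi-arid temperate study region: mean
#' annual temperature (degC), mean annual precipitation (mm), climate
#' change since the Last Glacial Maximum (degC / mm), plant species
#' richness (counts), and altitudinal range (m).
#'
#' @return A data.frame with columns `name`, `mean`, `sd`, `scale`, `round`.
#' @export
default_covariate_spec <- function() {
  data.frame(
    name  = c("MAT", "MAP", "Change_MAT", "Change_MAP", "SR_plant",
              "ALT_range"),
    mean  = c(2, 250, 7, 30, 2.5, 800),
    sd    = c(2.5, 100, 2, 40, 0.3, 400),
    scale = c("linear", "linear", "linear", "linear", "log10", "linear"),
    round = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate a per-site covariate and richness table
#'
#' Sites are placed on a jittered square grid. Each covariate is generated
#' as a spatially autocorrelated Gaussian field
#' `u = (I - lambda W)^-1 eps` with `eps` i.i.d. standard normal and `W` a
#' row-standardized symmetrized k-nearest-neighbor weights matrix, so
#' spatial-regression recovery is testable. Log richness is a linear
#' function of the standardized latent fields plus Gaussian noise, and
#' richness is emitted as `round(exp(.))` with a floor of 2 (mean pairwise
#' distance needs at least two species per site).
#'
#' For climate variables named in `lgm_pairs`, two Last-Glacial-Maximum
#' reconstruction columns (`<var>_LGM_ccsm`, `<var>_LGM_miroc`) are emitted
#' such that contemporary minus their mean equals the generated change
#' covariate exactly; [derive_lgm_change()] round-trips them.
#'
#' @param n_sites number of sites (>= 4).
#' @param covariate_spec data.frame as returned by
#'   [default_covariate_spec()].
#' @param sar_lambda spatial autocorrelation of the covariate fields, in
#'   (-1, 1).
#' @param beta_vector named numeric vector of effects of the standardized
#'   covariates on log richness; names must appear in `covariate_spec`.
#' @param noise_sd residual sd of log richness (>= 0).
#' @param intercept intercept of log richness (natural-log scale); the
#'   default `log(20)` centers richness near 20 species per site.
#' @param weights_k neighbors used for the spatial field (default 8).
#' @param lgm_pairs named list mapping a contemporary climate variable to
#'   its change variable, e.g. `list(MAT = "Change_MAT")`.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `site_id`, `x`, `y`, `area`, the
#'   covariates (plus LGM reconstruction columns), and `richness`. The
#'   standardized latent fields used in the response are attached as
#'   attribute `"latent"`, the generative coefficients as `"true_beta"`,
#'   and the pre-rounding log richness as `"log_richness"`.
#' @export
#' @examples
#' st <- simulate_site_table(20, beta_vector = c(SR_plant = 0.5), seed = 1)
#' head(st)
simulate_site_table <- function(n_sites,
                                covariate_spec = default_covariate_spec(),
                                sar_lambda = 0.4,
                                beta_vector = c(SR_plant = 0.5,
                                                ALT_range = 0.3),
                                noise_sd = 0.3,
                                intercept = log(20),
                                weights_k = 8,
                                lgm_pairs = list(MAT = "Change_MAT",
                                                 MAP = "Change_MAP"),
                                seed) {
  if (n_sites < 4) stop_param("`n_sites` must be >= 4")
  if (abs(sar_lambda) >= 1) stop_param("`sar_lambda` must satisfy |lambda| < 1")
  if (noise_sd < 0) stop_param("`noise_sd` must be >= 0")
  if (anyDuplicated(covariate_spec$name)) {
    stop_param("covariate names must be unique")
  }
  if (length(beta_vector) &&
      !all(names(beta_vector) %in% covariate_spec$name)) {
    stop_param("beta_vector names not in covariate_spec: %s",
               paste(setdiff(names(beta_vector), covariate_spec$name),
                     collapse = ", "))
  }

  with_seed(seed, {
    g <- ceiling(sqrt(n_sites))
    xy <- expand.grid(x = seq_len(g), y = seq_len(g))[seq_len(n_sites), ]
    xy$x <- xy$x + stats::runif(n_sites, -0.3, 0.3)
    xy$y <- xy$y + stats::runif(n_sites, -0.3, 0.3)

    sw <- build_weights(data.frame(site_id = seq_len(n_sites),
                                   x = xy$x, y = xy$y),
                        k = min(weights_k, n_sites - 1L))
    A <- diag(n_sites) - sar_lambda * sw$W

    latent <- matrix(NA_real_, n_sites, nrow(covariate_spec),
                     dimnames = list(NULL, covariate_spec$name))
    out <- data.frame(site_id = sprintf("site%03d", seq_len(n_sites)),
                      x = xy$x, y = xy$y,
                      area = round(10^stats::runif(n_sites, 2, 4.95)),
                      stringsAsFactors = FALSE)
    for (j in seq_len(nrow(covariate_spec))) {
      u <- solve(A, stats::rnorm(n_sites))
      z <- as.numeric(scale(u))
      latent[, j] <- z
      sp <- covariate_spec[j, ]
      v <- if (sp$scale == "log10") 10^(sp$mean + sp$sd * z)
           else sp$mean + sp$sd * z
      if (isTRUE(sp$round)) v <- pmax(1, round(v))
      out[[sp$name]] <- v
    }

    for (clim in names(lgm_pairs)) {
      chg <- lgm_pairs[[clim]]
      if (all(c(clim, chg) %in% names(out))) {
        lgm_mean <- out[[clim]] - out[[chg]]
        delta <- stats::rnorm(n_sites, 0,
                              0.25 * stats::sd(out[[chg]]))
        out[[paste0(clim, "_LGM_ccsm")]] <- lgm_mean + delta
        out[[paste0(clim, "_LGM_miroc")]] <- lgm_mean - delta
      }
    }

    eta <- rep(intercept, n_sites)
    if (length(beta_vector)) {
      eta <- eta + latent[, names(beta_vector), drop = FALSE] %*%
        beta_vector
    }
    eta <- as.numeric(eta) + stats::rnorm(n_sites, 0, noise_sd)
    out$richness <- pmax(2, round(exp(eta)))

    attr(out, "log_richness") <- eta # pre-rounding linear predictor + noise
    attr(out, "latent") <- latent
    attr(out, "true_beta") <- beta_vector
    out
  })
}
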