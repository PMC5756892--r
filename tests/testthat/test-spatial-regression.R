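test_that("derive_lgm_change averages reconstructions and subtracts", {
  st <- data.frame(site_id = "s1", MAT = 5,
                   MAT_LGM_ccsm = -3, MAT_LGM_miroc = -5,
                   MAP = 100, MAP_LGM_ccsm = 100, MAP_LGM_miroc = 100)
  out <- derive_lgm_change(st)
  expect_equal(out$MAT_LGM, -4)
  expect_equal(out$Change_MAT, 9)
  expect_equal(out$Change_MAP, 0) # contemporary equals both reconstructions
  st2 <- st
  st2$MAP_LGM_ccsm <- st2$MAP_LGM_miroc <- 60 # equal reconstructions
  expect_equal(derive_lgm_change(st2)$MAP_LGM, 60)
  expect_error(derive_lgm_change(st[, -3]), "MAT_LGM_ccsm")
})

test_that("derive_lgm_change round-trips the simulated change fields", {
  st <- simulate_site_table(40, seed = 1)
  truth <- st$Change_MAT
  st$Change_MAT <- NULL
  out <- derive_lgm_change(st)
  expect_equal(out$Change_MAT, truth, tolerance = 1e-10)
})

test_that("preprocess log-transforms then standardizes to mean 0 sd 1", {
  st <- data.frame(site_id = letters[1:3], richness = c(10, 100, 1000),
                   cov = c(1, 2, 6))
  out <- preprocess(st, log_vars = "richness",
                    all_vars = c("richness", "cov"))
  tr <- attr(out, "transforms")
  expect_equal(tr$mean[tr$variable == "richness"], 2) # log10 scale
  expect_equal(mean(out$richness), 0, tolerance = 1e-12)
  expect_equal(stats::sd(out$richness), 1, tolerance = 1e-12)
  expect_equal(mean(out$cov), 0, tolerance = 1e-12)
  expect_equal(stats::sd(out$cov), 1, tolerance = 1e-12)
  # log10(10,100,1000) = 1,2,3 before scaling: equally spaced after
  expect_equal(diff(out$richness)[1], diff(out$richness)[2],
               tolerance = 1e-12)

  expect_error(preprocess(data.frame(v = c(0, 1)), log_vars = "v"),
               "non-positive")
  expect_error(preprocess(data.frame(v = c(1, 1)), all_vars = "v"),
               "constant")
})

test_that("build_weights gives a row-standardized symmetric knn graph", {
  sq <- data.frame(site_id = 1:4, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  w <- build_weights(sq, k = 1)
  expect_s3_class(w, "spatial_weights")
  expect_equal(unname(rowSums(w$W)), rep(1, 4), tolerance = 1e-12)
  expect_identical(w$A, t(w$A)) # symmetric neighbor relation
  expect_equal(diag(w$W), stats::setNames(rep(0, 4), 1:4))

  st <- simulate_site_table(25, seed = 2)
  w2 <- build_weights(st, k = 24) # k = n - 1: fully connected
  expect_true(all(w2$W[upper.tri(w2$W)] == 1 / 24))
  expect_equal(unname(rowSums(build_weights(st, k = 5)$W)), rep(1, 25),
               tolerance = 1e-12)
  expect_error(build_weights(st, k = 25), "k")
  expect_warning(build_weights(data.frame(x = c(0, 0, 1), y = c(0, 0, 1)),
                               k = 1), "duplicate")
})

test_that("fit_ols reproduces closed forms", {
  # perfect fit (lm warns about it; the values are what matters)
  x <- as.numeric(scale(1:20))
  o <- suppressWarnings(fit_ols(x, cbind(x = x)))
  expect_equal(unname(o$coefficients), 1, tolerance = 1e-10)
  expect_equal(o$r2, 1, tolerance = 1e-10)

  # 5-point hand dataset: slope = cov(x, y) / var(x)
  xs <- c(1, 2, 4, 7, 11); ys <- c(2, 1, 5, 9, 8)
  o2 <- fit_ols(ys, cbind(x = xs))
  expect_equal(unname(o2$coefficients), stats::cov(xs, ys) / stats::var(xs),
               tolerance = 1e-12)

  # standardized single-variable slope equals the Pearson correlation
  set.seed(1)
  a <- as.numeric(scale(rnorm(100)))
  b <- as.numeric(scale(a + rnorm(100)))
  o3 <- fit_ols(b, cbind(a = a))
  expect_equal(unname(o3$coefficients), stats::cor(a, b), tolerance = 1e-10)

  # independent noise slope near zero at large n
  set.seed(2)
  o4 <- fit_ols(rnorm(10000), cbind(x = rnorm(10000)))
  expect_lt(abs(unname(o4$coefficients)), 0.05)

  expect_error(fit_ols(rnorm(10), cbind(a = 1:10, b = 2 * (1:10))),
               "collinear")
})

test_that("SAR error model nests OLS and never has lower likelihood", {
  st <- simulate_site_table(100, sar_lambda = 0.5, seed = 3)
  w <- build_weights(st, k = 8)
  y <- attr(st, "log_richness")
  X <- cbind(SR_plant = attr(st, "latent")[, "SR_plant"])
  s0 <- fit_sar_error(y, X, w, lambda = 0)
  o <- fit_ols(y, X)
  expect_equal(s0$coefficients, o$coefficients, tolerance = 1e-8)
  expect_equal(s0$log_likelihood, o$log_likelihood, tolerance = 1e-8)

  s <- fit_sar_error(y, X, w)
  expect_gte(s$log_likelihood, o$log_likelihood - 1e-8)
  expect_lt(abs(s$lambda), 1)
  expect_false(s$boundary)
  expect_true(s$pseudo_r2 <= 1)
})

test_that("aic_weights matches the closed-form Akaike weights", {
  expect_equal(aic_weights(c(100, 100)), c(0.5, 0.5), tolerance = 1e-14)
  expect_equal(aic_weights(42), 1)
  e <- exp(-1)
  expect_equal(aic_weights(c(100, 102)), c(1 / (1 + e), e / (1 + e)),
               tolerance = 1e-14)
  w <- aic_weights(c(210.3, 212.3, 214.3))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, aic_weights(c(210.3, 212.3, 214.3) + 57), # shift invariant
               tolerance = 1e-12)
  expect_error(aic_weights(c(1, Inf)), "finite")
})

test_that("single-variable battery recovers generative signs", {
  st <- simulate_site_table(300, sar_lambda = 0.3,
                            beta_vector = c(SR_plant = 0.6,
                                            ALT_range = 0.4,
                                            MAT = -0.4),
                            noise_sd = 0.3, seed = 5)
  pp <- preprocess(st, log_vars = c("richness", "SR_plant", "area"),
                   all_vars = c("richness", "SR_plant", "ALT_range",
                                "MAT", "MAP", "area"))
  w <- build_weights(pp, k = 8)
  tab <- single_variable_table(pp, "richness",
                               c("SR_plant", "ALT_range", "MAT", "MAP"), w)
  expect_gt(tab$coef_OLS[tab$variable == "SR_plant"], 0)
  expect_gt(tab$coef_OLS[tab$variable == "ALT_range"], 0)
  expect_lt(tab$coef_OLS[tab$variable == "MAT"], 0)
  expect_true(all(c("coef_SAR", "r2_SAR", "sig_OLS") %in% names(tab)))
  # OLS and SAR coefficients point the same way for the strong signals
  expect_gt(tab$coef_SAR[tab$variable == "SR_plant"], 0)
})
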