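#' Default end-to-end run configuration
#'
#' Self-contained "simulate" mode emulating the study design: a 112-tip
#' resident species pool, a pseudo-posterior sample around it, 86 county
#' sites, assemblages with mild phylogenetic clustering, spatially
#' autocorrelated covariates, and a log-linear richness response driven by
#' plant richness and altitudinal range. Every field can be overridden via
#' the `config` YAML or the `...` of [run_all()].
#'
#' @param master_seed integer master seed; all stage seeds derive from it.
#' @param outdir output directory.
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function(master_seed = 1, outdir = "commphylo_run") {
  structure(list(
    mode = "simulate",
    outdir = outdir,
    master_seed = master_seed,
    # analysis settings
    n_null = 999,
    pool = "tree",
    weights_k = 8,
    n_splits = 1000,
    n_trees = 500,
    top_k = 6,
    response = "richness",
    log_vars = c("richness", "SR_plant", "area"),
    table1_vars = c("area", "MAT", "MAP", "Change_MAT", "Change_MAP",
                    "SR_plant", "ALT_range", "NRI"),
    table2_vars = c("NRI", "Change_MAT", "SR_plant", "ALT_range", "MAP",
                    "MAT", "Change_MAP"),
    # ingest-mode paths (unused in simulate mode)
    tree_path = NULL, communities_path = NULL, sites_path = NULL,
    # simulation settings
    simulation = list(
      n_tips = 112, n_sites = 86,
      birth_rate = 1, death_rate = 0.2,
      n_posterior = 1000, subsample = 500,
      jitter_sd = 0.1, topology_swap_prob = 0.2,
      assembly_alpha = -2,
      sar_lambda = 0.4,
      beta_vector = c(SR_plant = 0.5, ALT_range = 0.3),
      noise_sd = 0.3
    )
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; `simulation` sub-fields merge likewise.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_param("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  sim <- cfg$simulation
  for (nm in names(user)) {
    if (nm == "simulation") {
      for (s in names(user$simulation)) sim[[s]] <- user$simulation[[s]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  if (!is.null(sim$beta_vector)) sim$beta_vector <- unlist(sim$beta_vector)
  cfg$simulation <- sim
  class(cfg) <- "run_config"
  cfg
}

#' Validate pipeline inputs
#'
#' Cross-checks, in ingest mode, the community matrix against the tree
#' tips, site IDs between the community matrix and the site table, and
#' positivity of variables slated for log transformation. Simulate-mode
#' configs validate their simulation parameters instead.
#'
#' @param config `run_config` list.
#' @return A data.frame of issues (`component`, `issue`); zero rows means
#'   the inputs are consistent.
#' @export
validate_inputs <- function(config) {
  issues <- data.frame(component = character(), issue = character(),
                       stringsAsFactors = FALSE)
  add <- function(component, issue) {
    rbind(issues, data.frame(component = component, issue = issue,
                             stringsAsFactors = FALSE))
  }
  if (identical(config$mode, "simulate")) {
    sim <- config$simulation
    if (sim$n_tips < 3) issues <- add("simulation", "n_tips must be >= 3")
    if (sim$n_sites < 4) issues <- add("simulation", "n_sites must be >= 4")
    if (abs(sim$sar_lambda) >= 1) {
      issues <- add("simulation", "|sar_lambda| must be < 1")
    }
    return(issues)
  }
  for (p in c("tree_path", "communities_path", "sites_path")) {
    if (is.null(config[[p]]) || !file.exists(config[[p]])) {
      issues <- add(p, sprintf("missing file: %s",
                               config[[p]] %||% "<unset>"))
    }
  }
  if (nrow(issues)) return(issues)
  trees <- read_trees(config$tree_path)
  comm <- as.matrix(utils::read.csv(config$communities_path,
                                    row.names = 1, check.names = FALSE))
  sites <- utils::read.csv(config$sites_path, stringsAsFactors = FALSE)
  tips <- trees[[1]]$tip.label
  for (sp in setdiff(colnames(comm), tips)) {
    issues <- add("communities", sprintf("unknown species %s", sp))
  }
  for (dup in unique(sites$site_id[duplicated(sites$site_id)])) {
    issues <- add("sites", sprintf("duplicate site %s", dup))
  }
  if (!setequal(rownames(comm), sites$site_id)) {
    issues <- add("sites", "site_id sets differ between communities and sites")
  }
  for (v in intersect(config$log_vars, names(sites))) {
    if (any(sites[[v]] <= 0)) {
      issues <- add("sites", sprintf("non-positive values in log variable %s", v))
    }
  }
  issues
}

#' Run the full pipeline
#'
#' Simulate (or ingest) a tree sample, community matrix and site table;
#' build the maximum clade credibility tree; compute per-site NRI; merge,
#' derive LGM climate change, log-transform and standardize; fit the
#' single-variable OLS/SAR battery; and rank covariate combinations by
#' random-forest predictive correlation. Writes `mcc.nwk`, `nri.csv`,
#' `merged_sites.csv`, `table1.csv`, `table2.csv`, `run.log` and
#' `manifest.csv` into the configured output directory. Identical inputs
#' and master seed give identical tables.
#'
#' @param config a `run_config` list, or a path to a YAML config.
#' @param ... individual config fields to override.
#' @return The output directory path, invisibly; the in-memory results
#'   (`mcc`, `nri`, `merged`, `table1`, `table2`) are attached as the
#'   attribute `"results"`.
#' @export
run_all <- function(config = default_run_config(), ...) {
  if (is.character(config)) config <- read_run_config(config)
  dots <- list(...)
  for (nm in names(dots)) config[[nm]] <- dots[[nm]]
  issues <- validate_inputs(config)
  if (nrow(issues)) {
    stop_param("invalid inputs:\n%s",
               paste(sprintf("  [%s] %s", issues$component, issues$issue),
                     collapse = "\n"))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_lines <- c(sprintf("commphylo %s | R %s.%s",
                         as.character(utils::packageVersion("commphylo")),
                         R.version$major, R.version$minor),
                 sprintf("master_seed: %d", config$master_seed))
  seed_for <- function(stage) stage_seed(config$master_seed, stage)

  if (identical(config$mode, "simulate")) {
    sim <- config$simulation
    tree <- simulate_tree(sim$n_tips, sim$birth_rate, sim$death_rate,
                          seed = seed_for("tree"))
    posterior <- simulate_posterior_sample(
      tree, sim$n_posterior, sim$jitter_sd, sim$topology_swap_prob,
      seed = seed_for("posterior"))
    sites <- simulate_site_table(
      sim$n_sites, sar_lambda = sim$sar_lambda,
      beta_vector = sim$beta_vector, noise_sd = sim$noise_sd,
      weights_k = config$weights_k, seed = seed_for("sites"))
    comm <- simulate_assemblages(
      tree, pmin(sites$richness, sim$n_tips), sim$assembly_alpha,
      seed = seed_for("assemblages"))
    rownames(comm) <- sites$site_id
    utils::write.csv(cbind(site_id = rownames(comm), as.data.frame(comm)),
                     file.path(outdir, "communities.csv"),
                     row.names = FALSE)
    log_lines <- c(log_lines,
                   sprintf("simulated %d tips, %d posterior trees, %d sites",
                           sim$n_tips, sim$n_posterior, sim$n_sites))
  } else {
    posterior <- read_trees(config$tree_path)
    comm <- as.matrix(utils::read.csv(config$communities_path,
                                      row.names = 1, check.names = FALSE))
    sites <- utils::read.csv(config$sites_path, stringsAsFactors = FALSE)
    sim <- list(subsample = length(posterior))
  }

  n_keep <- min(sim$subsample %||% length(posterior), length(posterior))
  kept <- if (n_keep < length(posterior)) {
    subsample_posterior(posterior, n_keep, seed = seed_for("subsample"))
  } else posterior
  mcc <- mcc_tree(kept)
  write_trees(mcc, file.path(outdir, "mcc.nwk"))
  log_lines <- c(log_lines,
                 sprintf("mcc over %d trees; log clade credibility %.4f",
                         n_keep, attr(mcc, "log_clade_credibility")))

  D <- patristic_distances(mcc)
  nri_df <- nri(comm, D, n_null = config$n_null, seed = seed_for("nri"),
                pool = config$pool)
  utils::write.csv(nri_df, file.path(outdir, "nri.csv"), row.names = FALSE)
  n_excl <- sum(nri_df$flag != "")
  log_lines <- c(log_lines,
                 sprintf("nri: %d sites, %d excluded (%s)", nrow(nri_df),
                         n_excl, "fewer than 2 species or degenerate null"))

  merged <- merge(sites, nri_df[, c("site_id", "n_species", "mpd_obs", "nri")],
                  by = "site_id", sort = TRUE)
  merged <- merged[order(merged$site_id), ]
  names(merged)[names(merged) == "nri"] <- "NRI"
  if (all(c("MAT_LGM_ccsm", "MAT_LGM_miroc") %in% names(merged))) {
    merged <- derive_lgm_change(merged)
  }
  utils::write.csv(merged, file.path(outdir, "merged_sites.csv"),
                   row.names = FALSE)

  analysis <- merged[!is.na(merged$NRI), ]
  std_vars <- unique(c(config$response, config$table1_vars))
  analysis <- preprocess(analysis,
                         log_vars = intersect(config$log_vars, std_vars),
                         all_vars = std_vars)
  weights <- build_weights(analysis, k = min(config$weights_k,
                                             nrow(analysis) - 1L))

  table1 <- single_variable_table(analysis, config$response,
                                  config$table1_vars, weights)
  utils::write.csv(table1, file.path(outdir, "table1.csv"),
                   row.names = FALSE)

  table2 <- rank_combinations(analysis, config$response, config$table2_vars,
                              n_splits = config$n_splits,
                              top_k = config$top_k,
                              n_trees = config$n_trees, weights = weights,
                              seed = seed_for("selection"))
  utils::write.csv(table2, file.path(outdir, "table2.csv"),
                   row.names = FALSE)

  log_lines <- c(log_lines,
                 sprintf("elapsed: %.1f s",
                         as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log_lines, file.path(outdir, "run.log"))

  artifacts <- file.path(outdir, c("mcc.nwk", "nri.csv", "merged_sites.csv",
                                   "table1.csv", "table2.csv"))
  artifacts <- artifacts[file.exists(artifacts)]
  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)

  invisible(structure(outdir,
                      results = list(mcc = mcc, nri = nri_df,
                                     merged = merged, table1 = table1,
                                     table2 = table2)))
}
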