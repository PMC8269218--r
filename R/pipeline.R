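#' Run the full analysis battery
#'
#' Orchestrates every stage on a complete dataset: network descriptors,
#' modularity and significance, node roles, per-coral assemblage statistics,
#' the beta-diversity correlation grids (2 metrics x 3 rarefaction depths x
#' all/HT/VT corals), the PGLS battery of assemblage metrics against
#' taxon-BRI per transmission subnetwork, the PLR battery against
#' transmission mode and high/low BRI thirds, PANOVA over categorical
#' groupings, Pagel's lambda estimates, permutation tests of phylogenetic
#' distances within versus between modules, and the sensitivity re-analyses
#' (metahaplotype collapse, sampling intensity, depth subsets). Raw p-values
#' are reported alongside Benjamini-Hochberg adjusted columns within each
#' battery. Stage failures are caught and recorded; downstream stages that
#' depend on them are skipped with the cause noted.
#'
#' @param data list with `interactions`, `coral_traits`, `symbiont_traits`,
#'   `coral_tree`, `symbiont_tree`, and optionally `variant_map` (the shape
#'   returned by [simulate_network()]).
#' @param config an [analysis_config()].
#' @param outdir optional output directory; when given, every table is
#'   written as CSV and a JSON run manifest records the config and seeds.
#' @return list of stage results (also written to `outdir` when set).
#' @export
run_full <- function(data, config = analysis_config(), outdir = NULL) {
  seeds <- derive_seeds(config$seed, 20)
  res <- list(config = config)
  errors <- list()
  step <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
    res[[name]] <<- out
    out
  }

  res$validation <- validate_dataset(data$interactions, data$coral_traits,
                                     data$symbiont_traits, data$coral_tree,
                                     data$symbiont_tree)

  net <- step("network", build_network(data$interactions))
  step("descriptors", list(
    connectance = connectance(net),
    web_asymmetry = as.numeric(web_asymmetry(net)),
    n_corals = length(net$corals), n_phylotypes = length(net$phylotypes),
    n_links = sum(net$counts > 0), n_records = sum(net$counts)))

  step("centrality", {
    list(coral = eigenvector_centrality(
           one_mode_projection(net, "coral", rule = config$projection_rule)),
         phylotype = eigenvector_centrality(
           one_mode_projection(net, "phylotype", rule = config$projection_rule)))
  })
  step("phylotype_transmission",
       classify_phylotype_transmission(net, data$coral_traits,
                                       threshold = config$vt_threshold))

  fnet <- step("filtered_network",
               filter_for_modularity(net, config$min_records_modularity))
  part <- step("partition", {
    optimize_modules_best(fnet, n_restarts = config$n_restarts,
                          n_stitches = config$n_stitches, seed = seeds[1],
                          matrix = config$modularity_matrix)
  })
  if (!is.null(part)) {
    step("modularity_significance",
         modularity_zscore(fnet, part, n_null = config$n_null_networks,
                           seed = seeds[2], null_stitches = config$null_stitches,
                           matrix = config$modularity_matrix))
    step("roles", {
      sc <- replicate_roles(fnet, n_runs = config$n_role_runs, seed = seeds[3],
                            n_stitches = config$null_stitches * 10,
                            matrix = config$modularity_matrix)
      classify_roles(sc, role_thresholds(fnet, permute = FALSE))
    })
  }

  stats_tab <- step("assemblage_stats",
                    assemblage_stats(net, data$coral_traits, data$symbiont_traits,
                                     depths = config$rarefaction_depths,
                                     tt_bin_edges = config$tt_bin_edges,
                                     bri_rule = config$bri_third_rule,
                                     bri_n = config$bri_third_n))

  step("beta_grid", beta_correlation_grid(data, config, seeds[4]))
  step("pgls_battery", pgls_battery(net, stats_tab, data, config))
  step("plr_battery", plr_battery(stats_tab, data))
  step("panova", panova_battery(data, config, seeds[5]))
  step("lambda_estimates", lambda_battery(stats_tab, data))
  if (!is.null(part)) {
    step("distance_tests", distance_test_battery(part, data, config, seeds[6]))
  }
  step("sensitivity", sensitivity_battery(data, config))

  res$errors <- errors
  res$manifest <- list(
    package_version = as.character(utils::packageVersion("symbionet")),
    seed = config$seed, stage_seeds = seeds,
    config = unclass(config), timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    failed_stages = names(errors))

  if (!is.null(outdir)) write_run_outputs(res, outdir)
  res
}

subnet_corals <- function(data, subnetwork) {
  tr <- data$coral_traits
  switch(subnetwork,
         all = tr$coral,
         HT = tr$coral[tr$transmission_mode == "HT"],
         VT = tr$coral[tr$transmission_mode == "VT"])
}

beta_correlation_grid <- function(data, config, seed) {
  subs <- depth_subsets(data$interactions, config$rarefaction_depths)
  rows <- list()
  seeds <- derive_seeds(seed, length(subs) * 6)
  si <- 0
  for (d in names(subs)) {
    net_d <- build_network(subs[[d]])
    mats <- pairwise_matrices(net_d, data$coral_tree, data$coral_traits,
                              data$symbiont_tree)
    for (metric in c("bray_curtis", "unifrac")) {
      for (grp in c("all", "HT", "VT")) {
        si <- si + 1
        taxa <- intersect(rownames(mats[[metric]]), subnet_corals(data, grp))
        r_bri <- tryCatch(matrix_correlation(mats[[metric]], mats$delta_bri,
                                             subset = taxa,
                                             n_perm = config$n_perm_distance,
                                             seed = seeds[si]),
                          error = function(e) list(r = NA, p = NA))
        r_pd <- tryCatch(matrix_correlation(mats[[metric]], mats$phylo_distance,
                                            subset = taxa,
                                            n_perm = config$n_perm_distance,
                                            seed = seeds[si] + 1),
                         error = function(e) list(r = NA, p = NA))
        rows[[length(rows) + 1L]] <- data.frame(
          depth = d, metric = metric, group = grp, n_corals = length(taxa),
          r_delta_bri = r_bri$r, p_delta_bri = r_bri$p,
          r_phylo_distance = r_pd$r, p_phylo_distance = r_pd$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_delta_bri_bh <- stats::p.adjust(out$p_delta_bri, "BH")
  out$p_phylo_distance_bh <- stats::p.adjust(out$p_phylo_distance, "BH")
  out
}

metric_columns <- function(stats_tab) {
  setdiff(names(stats_tab)[vapply(stats_tab, is.numeric, logical(1))],
          c("n_records", "taxon_BRI"))
}

pgls_battery <- function(net, stats_tab, data, config) {
  rows <- list()
  cent <- eigenvector_centrality(one_mode_projection(net, "coral",
                                                     rule = config$projection_rule))
  stats_tab$centrality <- cent[stats_tab$coral]
  bri <- stats::setNames(stats_tab$taxon_BRI, stats_tab$coral)
  aid <- 0
  for (grp in c("all", "HT", "VT")) {
    corals <- intersect(stats_tab$coral, subnet_corals(data, grp))
    for (m in metric_columns(stats_tab)) {
      x <- stats::setNames(stats_tab[[m]], stats_tab$coral)[corals]
      aid <- aid + 1
      fit <- tryCatch(pgls(bri[corals], x, data$coral_tree),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = paste0("PGLS no. ", aid), response = "taxon_BRI",
        predictor = m, subnetwork = grp,
        estimate = if (is.null(fit)) NA else fit$coefficients$estimate[2],
        R = if (is.null(fit)) NA else fit$R,
        p = if (is.null(fit)) NA else fit$coefficients$p[2],
        lambda = if (is.null(fit)) NA else fit$lambda,
        n = if (is.null(fit)) NA else fit$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, "BH")
  out
}

plr_battery <- function(stats_tab, data) {
  rows <- list()
  mode01 <- stats::setNames(as.numeric(stats_tab$transmission_mode == "VT"),
                            stats_tab$coral)
  grp <- stats_tab$bri_group
  hilo <- stats::setNames(ifelse(grp == "high", 1, ifelse(grp == "low", 0, NA)),
                          stats_tab$coral)
  aid <- 0
  for (resp in c("transmission_mode_VT", "high_vs_low_BRI")) {
    y <- if (resp == "transmission_mode_VT") mode01 else hilo
    for (m in metric_columns(stats_tab)) {
      x <- stats::setNames(stats_tab[[m]], stats_tab$coral)
      aid <- aid + 1
      fit <- tryCatch(phylo_logistic(y, x, data$coral_tree),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = paste0("PLR no. ", aid), response = resp, predictor = m,
        estimate = if (is.null(fit)) NA else fit$coefficients$estimate[2],
        p = if (is.null(fit)) NA else fit$coefficients$p[2],
        no_signal = if (is.null(fit)) NA else fit$no_signal,
        n = if (is.null(fit)) NA else fit$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, "BH")
  out
}

panova_battery <- function(data, config, seed) {
  tr <- data$coral_traits
  bri <- stats::setNames(tr$taxon_BRI, tr$coral)
  groupings <- list(transmission_mode = tr$transmission_mode,
                    ocean = tr$ocean, life_history = tr$life_history)
  seeds <- derive_seeds(seed, length(groupings))
  rows <- list()
  for (i in seq_along(groupings)) {
    g <- stats::setNames(groupings[[i]], tr$coral)
    fit <- tryCatch(phylo_anova(bri, g, data$coral_tree,
                                n_sim = min(config$n_null_networks, 1000L),
                                seed = seeds[i]),
                    error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = paste0("PANOVA no. ", i), response = "taxon_BRI",
      grouping = names(groupings)[i],
      F = if (is.null(fit)) NA else fit$F,
      p = if (is.null(fit)) NA else fit$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, "BH")
  out
}

lambda_battery <- function(stats_tab, data) {
  rows <- list()
  bri <- stats::setNames(stats_tab$taxon_BRI, stats_tab$coral)
  tt <- stats::setNames(data$symbiont_traits$TT, data$symbiont_traits$phylotype)
  cases <- list(
    list(id = 1, trait = "taxon_BRI", tree = data$coral_tree, x = bri, sub = "all"),
    list(id = 2, trait = "taxon_BRI", tree = data$coral_tree,
         x = bri[intersect(names(bri), stats_tab$coral[stats_tab$transmission_mode == "HT"])],
         sub = "HT"),
    list(id = 3, trait = "taxon_BRI", tree = data$coral_tree,
         x = bri[intersect(names(bri), stats_tab$coral[stats_tab$transmission_mode == "VT"])],
         sub = "VT"),
    list(id = 4, trait = "TT", tree = data$symbiont_tree, x = tt, sub = "all"))
  rows <- lapply(cases, function(cs) {
    fit <- tryCatch(pagel_lambda_ml(cs$x, cs$tree), error = function(e) NULL)
    data.frame(analysis = paste0("lambda no. ", cs$id), trait = cs$trait,
               subnetwork = cs$sub,
               lambda = if (is.null(fit)) NA else fit$lambda,
               p_lrt = if (is.null(fit)) NA else fit$p_lrt,
               n = if (is.null(fit)) NA else fit$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

distance_test_battery <- function(part, data, config, seed) {
  seeds <- derive_seeds(seed, 3)
  rows <- list()
  run1 <- function(id, D, labels, sd_) {
    fit <- tryCatch(permutation_distance_test(D, labels,
                                              n_perm = config$n_perm_distance,
                                              seed = sd_),
                    error = function(e) NULL)
    data.frame(test = id,
               t = if (is.null(fit)) NA else fit$t,
               p = if (is.null(fit)) NA else fit$p, stringsAsFactors = FALSE)
  }
  ctaxa <- intersect(names(part$coral_modules), data$coral_tree$tip.label)
  Dc <- pairwise_phylo_distance(prune_tree(data$coral_tree, ctaxa))
  rows[[1]] <- run1("coral within vs between module", Dc,
                    part$coral_modules[ctaxa], seeds[1])
  ptaxa <- intersect(names(part$phylotype_modules), data$symbiont_tree$tip.label)
  Dp <- pairwise_phylo_distance(prune_tree(data$symbiont_tree, ptaxa))
  rows[[2]] <- run1("phylotype within vs between module", Dp,
                    part$phylotype_modules[ptaxa], seeds[2])
  mode <- stats::setNames(data$coral_traits$transmission_mode, data$coral_traits$coral)
  rows[[3]] <- run1("coral same vs different transmission mode", Dc,
                    mode[ctaxa], seeds[3])
  do.call(rbind, rows)
}

sensitivity_battery <- function(data, config) {
  out <- list()
  if (!is.null(data$variant_map) && nrow(data$variant_map)) {
    mh <- metahaplotype_collapse(data$interactions, data$variant_map)
    out$metahaplotype_report <- mh$report
    net_mh <- build_network(mh$interactions)
    out$metahaplotype_descriptors <- list(
      connectance = connectance(net_mh),
      n_phylotypes = length(net_mh$phylotypes))
  }
  intensity <- sampling_intensity(data$interactions)
  net <- build_network(data$interactions)
  st <- assemblage_stats(net, data$coral_traits, NULL,
                         depths = config$rarefaction_depths)
  rows <- list()
  for (m in c(paste0("RD", config$rarefaction_depths), "dprime")) {
    v <- stats::setNames(st[[m]], st$coral)
    fit <- tryCatch(regress_metric_on_intensity(v, intensity, data$coral_tree),
                    error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m,
      estimate = if (is.null(fit)) NA else fit$coefficients$estimate[2],
      R = if (is.null(fit)) NA else fit$R,
      p = if (is.null(fit)) NA else fit$coefficients$p[2], stringsAsFactors = FALSE)
  }
  out$intensity_regressions <- do.call(rbind, rows)
  subs <- depth_subsets(data$interactions, config$rarefaction_depths)
  out$depth_subset_counts <- attr(subs, "n_corals")
  out
}

write_run_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, nm) {
    if (is.data.frame(x)) utils::write.csv(x, file.path(outdir, paste0(nm, ".csv")),
                                           row.names = FALSE)
  }
  wr(res$beta_grid, "beta_grid")
  wr(res$pgls_battery, "pgls_battery")
  wr(res$plr_battery, "plr_battery")
  wr(res$panova, "panova")
  wr(res$lambda_estimates, "lambda_estimates")
  wr(res$distance_tests, "distance_tests")
  wr(res$assemblage_stats, "assemblage_stats")
  wr(res$roles, "roles")
  wr(as.data.frame(res$validation), "validation")
  if (!is.null(res$sensitivity$intensity_regressions)) {
    wr(res$sensitivity$intensity_regressions, "intensity_regressions")
  }
  if (!is.null(res$partition)) {
    part_df <- data.frame(
      node = c(names(res$partition$coral_modules), names(res$partition$phylotype_modules)),
      type = c(rep("coral", length(res$partition$coral_modules)),
               rep("phylotype", length(res$partition$phylotype_modules))),
      module = c(res$partition$coral_modules, res$partition$phylotype_modules),
      stringsAsFactors = FALSE)
    wr(part_df, "partition")
  }
  if (!is.null(res$network)) write_edgelist(res$network, file.path(outdir, "edgelist.csv"))
  manifest <- res$manifest
  manifest$descriptors <- res$descriptors
  if (!is.null(res$partition)) {
    manifest$modularity <- list(Q = res$partition$Q, n_modules = res$partition$n_modules)
  }
  if (!is.null(res$modularity_significance)) {
    manifest$modularity_z <- res$modularity_significance$z
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(outdir)
}
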