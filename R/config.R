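#' Analysis configuration
#'
#' Collects every tunable knob shared by the pipeline stages. Defaults follow
#' the published analysis protocol: rarefaction depths 10/15/20 records,
#' thermotolerance bin edges at 10/20/30/40 percentile points, 10,000
#' permutations for distance tests, 1,000 null networks for modularity
#' significance, 1,000 optimizer restarts of 10^6 stitches each, and a
#' minimum of 3 records for a phylotype to enter the modularity analysis.
#'
#' @param seed integer master seed; every stochastic stage derives its own
#'   stream from it.
#' @param rarefaction_depths increasing integer vector of rarefaction depths.
#' @param tt_bin_edges strictly increasing thermotolerance bin edges; the
#'   bins are `[0, e1], (e1, e2], ..., (ek, 100]`.
#' @param n_perm_distance permutations for distance-based tests.
#' @param n_null_networks marginal-preserving null networks for modularity
#'   significance and role thresholds.
#' @param n_restarts modularity optimizer restarts.
#' @param n_stitches random stitches per optimizer run.
#' @param null_stitches reduced stitch budget used when re-optimizing null
#'   networks.
#' @param min_records_modularity minimum phylotype record count for inclusion
#'   in the modularity analysis.
#' @param n_role_runs partition replicates over which c/z scores are averaged.
#' @param vt_threshold share of a phylotype's records on vertically
#'   transmitting hosts above which it is classed VT (below `1 - threshold`,
#'   HT; otherwise mixed-mode).
#' @param modularity_matrix which link matrix enters the modularity formula:
#'   per-coral frequency weights (default) or raw counts.
#' @param projection_rule one-mode projection edge rule: product (default,
#'   sum over shared partners of the two weight products) or minimum.
#' @param bri_third_rule size rule for the high/low bleaching-response thirds.
#' @param bri_third_n fixed third size when `bri_third_rule = "fixed"`.
#' @return an object of class `symbionet_config` (a named list).
#' @export
analysis_config <- function(seed = 1L,
                            rarefaction_depths = c(10L, 15L, 20L),
                            tt_bin_edges = c(10, 20, 30, 40),
                            n_perm_distance = 10000L,
                            n_null_networks = 1000L,
                            n_restarts = 1000L,
                            n_stitches = 1e6,
                            null_stitches = 1e4,
                            min_records_modularity = 3L,
                            n_role_runs = 100L,
                            vt_threshold = 0.95,
                            modularity_matrix = c("weights", "counts"),
                            projection_rule = c("product", "minimum"),
                            bri_third_rule = c("ceil", "floor", "fixed"),
                            bri_third_n = NULL) {
  modularity_matrix <- match.arg(modularity_matrix)
  projection_rule <- match.arg(projection_rule)
  bri_third_rule <- match.arg(bri_third_rule)
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    all(rarefaction_depths >= 1), !is.unsorted(rarefaction_depths, strictly = TRUE),
    !is.unsorted(tt_bin_edges, strictly = TRUE),
    n_perm_distance >= 1, n_null_networks >= 1, n_restarts >= 1,
    n_stitches >= 1, null_stitches >= 1,
    min_records_modularity >= 1, n_role_runs >= 1,
    vt_threshold > 0.5, vt_threshold <= 1
  )
  structure(list(
    seed = as.integer(seed),
    rarefaction_depths = as.integer(rarefaction_depths),
    tt_bin_edges = as.numeric(tt_bin_edges),
    n_perm_distance = as.integer(n_perm_distance),
    n_null_networks = as.integer(n_null_networks),
    n_restarts = as.integer(n_restarts),
    n_stitches = as.numeric(n_stitches),
    null_stitches = as.numeric(null_stitches),
    min_records_modularity = as.integer(min_records_modularity),
    n_role_runs = as.integer(n_role_runs),
    vt_threshold = vt_threshold,
    modularity_matrix = modularity_matrix,
    projection_rule = projection_rule,
    bri_third_rule = bri_third_rule,
    bri_third_n = bri_third_n
  ), class = "symbionet_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected so typos fail before any computation.
#'
#' @param path YAML file whose keys match the arguments of
#'   [analysis_config()].
#' @return a `symbionet_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(analysis_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' @export
print.symbionet_config <- function(x, ...) {
  cat("symbionet analysis configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
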