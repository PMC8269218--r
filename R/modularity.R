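#' Barber modularity of a weighted bipartite partition
#'
#' Q = (1/F) * sum_ij (A_ij - k_i d_j / F) * delta(g_i, g_j) over
#' coral-phylotype pairs, with A the link matrix entering the modularity
#' analysis (per-coral frequency weights by default, raw counts optionally),
#' k/d its row and column sums, and F its total. Corals and phylotypes share
#' one module id space.
#'
#' @param net a `bipartite_net`.
#' @param partition a `module_partition` or a list with named integer
#'   vectors `coral_modules` and `phylotype_modules`.
#' @param matrix `"weights"` (default) or `"counts"`.
#' @return Q as a single number.
#' @export
barber_modularity <- function(net, partition, matrix = c("weights", "counts")) {
  matrix <- match.arg(matrix)
  A <- net[[matrix]]
  gc <- partition$coral_modules[net$corals]
  gp <- partition$phylotype_modules[net$phylotypes]
  if (anyNA(gc) || anyNA(gp)) stop("partition does not cover all network nodes")
  F_ <- sum(A)
  k <- rowSums(A)
  d <- colSums(A)
  sum((A - outer(k, d) / F_) * outer(gc, gp, "==")) / F_
}

make_partition <- function(net, gc, gp, matrix = "weights", meta = list()) {
  labs <- sort(unique(c(gc, gp)))
  gc <- match(gc, labs)
  gp <- match(gp, labs)
  part <- list(coral_modules = stats::setNames(gc, net$corals),
               phylotype_modules = stats::setNames(gp, net$phylotypes),
               n_modules = length(labs))
  part$Q <- barber_modularity(net, part, matrix = matrix)
  part$meta <- c(meta, list(matrix = matrix))
  structure(part, class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module partition: %d modules, Q = %.4f (%d corals, %d phylotypes)\n",
              x$n_modules, x$Q, length(x$coral_modules), length(x$phylotype_modules)))
  invisible(x)
}

#' Filter rarely recorded phylotypes before modularity analysis
#'
#' Phylotypes with fewer than `min_records` association records in total are
#' removed (they stay in all other analyses); per-coral weights are
#' re-normalised on the remaining links and corals left without records drop
#' out with a warning.
#'
#' @param net a `bipartite_net`.
#' @param min_records minimum total records (default 3).
#' @return a filtered `bipartite_net`.
#' @export
filter_for_modularity <- function(net, min_records = 3L) {
  stopifnot(min_records >= 1)
  keep <- colSums(net$counts) >= min_records
  if (!any(keep)) stop("all phylotypes removed by the record filter")
  A <- net$counts[, keep, drop = FALSE]
  idx <- which(A > 0, arr.ind = TRUE)
  build_network(interaction_table(rownames(A)[idx[, 1]],
                                  colnames(A)[idx[, 2]],
                                  A[idx]))
}

net_edgelist <- function(net, matrix) {
  M <- net[[matrix]]
  idx <- which(M > 0, arr.ind = TRUE)
  list(ec = as.integer(idx[, 1] - 1L), ep = as.integer(idx[, 2] - 1L),
       ew = as.numeric(M[idx]))
}

#' Optimize the module partition by random stitches
#'
#' Stochastic hill-climb: phylotypes start in singleton modules and each
#' coral is seeded into the module of its strongest-weight phylotype; then
#' `n_stitches` random proposals (move a node into a neighbouring module, or
#' merge the two endpoint modules of a link) are applied, accepting a
#' proposal iff Q does not decrease. The returned Q is recomputed from
#' scratch with [barber_modularity()].
#'
#' @param net a (typically filtered) `bipartite_net`.
#' @param n_stitches number of random proposals (default 1e6).
#' @param seed RNG seed for reproducibility.
#' @param matrix link matrix entering Q (`"weights"` default).
#' @param merge_prob fraction of proposals that are module merges.
#' @return a `module_partition` with fields `coral_modules`,
#'   `phylotype_modules`, `n_modules`, `Q` and run metadata.
#' @export
optimize_modules <- function(net, n_stitches = 1e6, seed = NULL,
                             matrix = c("weights", "counts"), merge_prob = 0.1) {
  matrix <- match.arg(matrix)
  el <- net_edgelist(net, matrix)
  nc <- length(net$corals); np <- length(net$phylotypes)
  # singleton phylotype modules; corals seeded by their strongest link
  init <- integer(nc + np)
  init[nc + seq_len(np)] <- nc + seq_len(np) - 1L
  M <- net[[matrix]]
  init[seq_len(nc)] <- nc + max.col(M, ties.method = "first") - 1L
  res <- with_seed(seed, stitch_optimize_cpp(el$ec, el$ep, el$ew, nc, np,
                                             n_stitches, init, merge_prob))
  memb <- res$membership
  make_partition(net, memb[seq_len(nc)], memb[nc + seq_len(np)], matrix = matrix,
                 meta = list(n_stitches = n_stitches, seed = seed,
                             merge_prob = merge_prob))
}

#' Select a partition from repeated optimizer runs
#'
#' Among the runs attaining the minimum number of modules, returns the run
#' with the largest Q; remaining ties break to the lowest run index.
#'
#' @param runs list of `module_partition` objects.
#' @export
select_partition <- function(runs) {
  if (!length(runs)) stop("empty run list")
  k <- vapply(runs, function(r) r$n_modules, numeric(1))
  q <- vapply(runs, function(r) r$Q, numeric(1))
  cand <- which(k == min(k))
  best <- cand[which.max(q[cand])]
  out <- runs[[best]]
  out$meta$selected_run <- best
  out$meta$n_runs <- length(runs)
  out
}

#' Run the optimizer repeatedly and select per the minimum-module rule
#'
#' @inheritParams optimize_modules
#' @param n_restarts number of independent optimizer runs (default 1000).
#' @param all_runs return all runs alongside the selection?
#' @export
optimize_modules_best <- function(net, n_restarts = 1000L, n_stitches = 1e6,
                                  seed = NULL, matrix = c("weights", "counts"),
                                  merge_prob = 0.1, all_runs = FALSE) {
  matrix <- match.arg(matrix)
  seeds <- derive_seeds(seed %||% 0, n_restarts)
  runs <- lapply(seq_len(n_restarts), function(i) {
    optimize_modules(net, n_stitches = n_stitches, seed = seeds[i],
                     matrix = matrix, merge_prob = merge_prob)
  })
  best <- select_partition(runs)
  if (all_runs) list(best = best, runs = runs) else best
}

null_networks <- function(net, n_null, seed) {
  # Patefield: random tables preserving the count matrix margins
  with_seed(seed, stats::r2dtable(n_null, rowSums(net$counts), colSums(net$counts)))
}

null_to_net <- function(tab, corals, phylotypes) {
  dimnames(tab) <- list(corals, phylotypes)
  idx <- which(tab > 0, arr.ind = TRUE)
  build_network(interaction_table(corals[idx[, 1]], phylotypes[idx[, 2]], tab[idx]))
}

#' Modularity significance against marginal-preserving null networks
#'
#' Generates null count matrices preserving the row and column totals
#' (Patefield algorithm), re-optimizes each with a reduced stitch budget,
#' and reports the z-score of the observed Q against the null distribution.
#'
#' @param net the (filtered) `bipartite_net` whose partition was optimized.
#' @param partition the observed `module_partition`.
#' @param n_null number of null networks (default 1000, min 2).
#' @param seed RNG seed.
#' @param null_stitches stitch budget per null re-optimization.
#' @param matrix link matrix entering Q.
#' @return list with `z`, `null_mean`, `null_sd`, `null_Q` and a
#'   `degenerate` flag (TRUE when the null sd is zero and z infinite).
#' @export
modularity_zscore <- function(net, partition, n_null = 1000L, seed = NULL,
                              null_stitches = 1e4, matrix = c("weights", "counts")) {
  matrix <- match.arg(matrix)
  if (n_null < 2) stop("n_null must be at least 2")
  tabs <- null_networks(net, n_null, seed)
  seeds <- derive_seeds((seed %||% 0) + 1, n_null)
  qs <- vapply(seq_len(n_null), function(i) {
    nn <- null_to_net(tabs[[i]], net$corals, net$phylotypes)
    optimize_modules(nn, n_stitches = null_stitches, seed = seeds[i],
                     matrix = matrix)$Q
  }, numeric(1))
  mu <- mean(qs); sdev <- stats::sd(qs)
  degenerate <- sdev == 0
  z <- if (degenerate) Inf * sign(partition$Q - mu) else (partition$Q - mu) / sdev
  list(z = z, null_mean = mu, null_sd = sdev, null_Q = qs, degenerate = degenerate)
}

#' Within-module degree (z) and among-module connectivity (c) of phylotypes
#'
#' For phylotype i with strength s_it to the corals of module t, the
#' participation score is c_i = 1 - sum_t (s_it / s_i)^2 and the
#' within-module degree z_i standardises i's strength into its own module
#' against the other phylotypes of that module (z = 0 where the module sd is
#' zero). Strengths use frequency weights by default; binary degrees are
#' available behind `binary`.
#'
#' @param net a `bipartite_net`.
#' @param partition a `module_partition` covering the network.
#' @param matrix link matrix for strengths.
#' @param binary use 0/1 links instead of weights?
#' @return data frame `phylotype`, `c`, `z`, `module`.
#' @export
participation_scores <- function(net, partition, matrix = c("weights", "counts"),
                                 binary = FALSE) {
  matrix <- match.arg(matrix)
  M <- net[[matrix]]
  if (binary) M <- (M > 0) * 1
  gc <- partition$coral_modules[net$corals]
  gp <- partition$phylotype_modules[net$phylotypes]
  if (anyNA(gc) || anyNA(gp)) stop("partition does not cover all network nodes")
  s_i <- colSums(M)
  if (any(s_i == 0)) {
    stop("phylotypes with zero strength: ",
         paste(net$phylotypes[s_i == 0], collapse = ", "))
  }
  mods <- sort(unique(c(gc, gp)))
  # strength of each phylotype into each coral module
  S <- t(rowsum(M, group = gc, reorder = TRUE))     # phylotype x coral-module
  cm <- as.integer(colnames(S))
  c_score <- 1 - rowSums((S / s_i)^2)
  own <- S[cbind(seq_along(gp), match(gp, cm))]
  own[is.na(own)] <- 0  # module has no corals
  z_score <- numeric(length(gp))
  for (g in unique(gp)) {
    idx <- which(gp == g)
    mu <- mean(own[idx]); sdev <- stats::sd(own[idx])
    z_score[idx] <- if (length(idx) < 2 || is.na(sdev) || sdev == 0) 0 else
      (own[idx] - mu) / sdev
  }
  data.frame(phylotype = net$phylotypes, c = as.numeric(c_score),
             z = z_score, module = as.integer(gp), stringsAsFactors = FALSE)
}

#' Average c/z scores over repeated partition optimizations
#'
#' Because the optimizer is stochastic, roles are averaged over `n_runs`
#' independent partitions; the mean and SD of c and z per phylotype are
#' returned.
#'
#' @inheritParams optimize_modules
#' @param n_runs partition replicates (default 100).
#' @return data frame `phylotype`, `c`, `z`, `c_sd`, `z_sd`.
#' @export
replicate_roles <- function(net, n_runs = 100L, seed = NULL, n_stitches = 1e5,
                            matrix = c("weights", "counts")) {
  matrix <- match.arg(matrix)
  stopifnot(n_runs >= 1)
  seeds <- derive_seeds(seed %||% 0, n_runs)
  cs <- zs <- matrix(NA_real_, length(net$phylotypes), n_runs)
  for (i in seq_len(n_runs)) {
    part <- optimize_modules(net, n_stitches = n_stitches, seed = seeds[i],
                             matrix = matrix)
    sc <- participation_scores(net, part, matrix = matrix)
    cs[, i] <- sc$c; zs[, i] <- sc$z
  }
  data.frame(phylotype = net$phylotypes,
             c = rowMeans(cs), z = rowMeans(zs),
             c_sd = apply(cs, 1, stats::sd), z_sd = apply(zs, 1, stats::sd),
             stringsAsFactors = FALSE)
}

#' Significance thresholds for c and z
#'
#' With `permute = TRUE`, thresholds are the chosen percentile (default
#' 95th) of the c and z scores pooled over marginal-preserving null
#' networks, each re-optimized; with permutation disabled the conventional
#' defaults (c* = 0.6, z* = 2) are returned.
#'
#' @inheritParams modularity_zscore
#' @param n_perm null networks (default 1000).
#' @param percentile percentile in (0, 100].
#' @param permute run the permutation or fall back to the defaults?
#' @return named vector `c(c = c_star, z = z_star)`.
#' @export
role_thresholds <- function(net, n_perm = 1000L, percentile = 95, seed = NULL,
                            permute = TRUE, null_stitches = 1e4,
                            matrix = c("weights", "counts")) {
  matrix <- match.arg(matrix)
  if (!permute) return(c(c = 0.6, z = 2.0))
  tabs <- null_networks(net, n_perm, seed)
  seeds <- derive_seeds((seed %||% 0) + 2, n_perm)
  cz <- lapply(seq_len(n_perm), function(i) {
    nn <- null_to_net(tabs[[i]], net$corals, net$phylotypes)
    part <- optimize_modules(nn, n_stitches = null_stitches, seed = seeds[i],
                             matrix = matrix)
    sc <- participation_scores(nn, part, matrix = matrix)
    cbind(sc$c, sc$z)
  })
  pooled <- do.call(rbind, cz)
  c(c = as.numeric(stats::quantile(pooled[, 1], percentile / 100)),
    z = as.numeric(stats::quantile(pooled[, 2], percentile / 100)))
}

#' Classify node roles from c/z scores
#'
#' Quadrants of the (c, z) plane: peripheral (low c, low z), module hub
#' (low c, high z), connector (high c, low z), network hub (high c, high z).
#'
#' @param scores data frame with columns `c` and `z` (e.g. from
#'   [replicate_roles()]).
#' @param thresholds named vector `c(c = ..., z = ...)`.
#' @return `scores` with a `role` column added.
#' @export
classify_roles <- function(scores, thresholds = c(c = 0.6, z = 2.0)) {
  hi_c <- scores$c >= thresholds[["c"]]
  hi_z <- scores$z >= thresholds[["z"]]
  scores$role <- ifelse(hi_c & hi_z, "network hub",
                 ifelse(hi_c, "connector",
                 ifelse(hi_z, "module hub", "peripheral")))
  scores
}

#' Normalized mutual information between two partitions
#'
#' NMI with sqrt normalisation, used to score recovery of planted modules.
#' Both inputs are label vectors over the same nodes.
#'
#' @param a,b integer/character label vectors of equal length.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj)[nz]))
  hx <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hy <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  mi / sqrt(hx * hy)
}
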