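#' Per-coral assemblage profile
#'
#' The raw counts, frequency weights and total record count of one coral's
#' Symbiodiniaceae assemblage, extracted from the network.
#'
#' @param net a `bipartite_net`.
#' @param coral coral label.
#' @return an `assemblage_profile`: list with named `counts`, `weights`
#'   (nonzero entries only) and total `N`.
#' @export
assemblage_profile <- function(net, coral) {
  i <- match(coral, net$corals)
  if (is.na(i)) stop("unknown coral: ", coral)
  cnt <- net$counts[i, ]
  nz <- cnt > 0
  structure(list(coral = coral, counts = cnt[nz], weights = net$weights[i, nz],
                 N = sum(cnt)), class = "assemblage_profile")
}

#' Rarefied phylotype richness of one assemblage
#'
#' Expected number of distinct phylotypes in a random subsample of `depth`
#' records. The analytic mode is the hypergeometric expectation
#' E\[S\] = S - sum_j C(N - N_j, depth) / C(N, depth); the Monte Carlo mode
#' averages distinct phylotypes over resamples without replacement and is
#' kept for fidelity to resampling-based protocols. Corals with fewer than
#' `depth` records are excluded: the function returns `NA`.
#'
#' @param profile an `assemblage_profile` (or a bare positive count vector).
#' @param depth rarefaction depth (records).
#' @param method `"analytic"` (default) or `"monte_carlo"`.
#' @param seed RNG seed for the Monte Carlo mode.
#' @param n_resample Monte Carlo resamples.
#' @return expected richness, or `NA` when `N < depth`.
#' @export
rarefied_richness <- function(profile, depth, method = c("analytic", "monte_carlo"),
                              seed = NULL, n_resample = 1000L) {
  method <- match.arg(method)
  counts <- if (inherits(profile, "assemblage_profile")) profile$counts else profile
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < depth) return(NA_real_)
  if (method == "analytic") {
    # rarefy's "smallest count" advisory does not apply to the expectation
    withCallingHandlers(
      as.numeric(vegan::rarefy(matrix(counts, nrow = 1), sample = depth)),
      warning = function(w) {
        if (grepl("most observed count data", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  } else {
    pool <- rep(seq_along(counts), counts)
    with_seed(seed, mean(vapply(seq_len(n_resample), function(i) {
      length(unique(sample(pool, depth)))
    }, numeric(1))))
  }
}

fill_by_order <- function(a, caps, ord) {
  alloc <- numeric(length(caps))
  remaining <- a
  for (j in ord) {
    take <- min(remaining, caps[j])
    alloc[j] <- take
    remaining <- remaining - take
    if (remaining <= 0) break
  }
  alloc
}

# Maximum KL specialization d attainable by a node with total `a` against
# partner availabilities `avail_counts` (allocations capped by the partner
# totals; any capped allocation extends to a full marginal-preserving table).
# d is convex in the allocation, so the maximum sits at a vertex of the
# capped simplex, and every vertex is a fill-to-cap prefix of some partner
# ordering: small problems are solved exactly by enumerating orderings,
# large ones by a candidate set (each partner first, remainder by ascending
# availability, plus the two monotone orders).
dprime_max <- function(a, avail_counts) {
  q <- avail_counts / sum(avail_counts)
  m <- length(avail_counts)
  score <- function(alloc) kl_divergence(alloc / a, q)
  if (m <= 7) {
    orders <- perm_all(m)
    return(max(vapply(orders, function(o) score(fill_by_order(a, avail_counts, o)),
                      numeric(1))))
  }
  asc <- order(avail_counts)
  cand <- c(list(asc, rev(asc)),
            lapply(seq_len(m), function(j) c(j, setdiff(asc, j))))
  max(vapply(cand, function(o) score(fill_by_order(a, avail_counts, o)),
             numeric(1)))
}

perm_all <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (j in seq_len(m)) {
    for (rest in perm_all(m - 1L)) {
      out[[length(out) + 1L]] <- c(j, setdiff(seq_len(m), j)[rest])
    }
  }
  out
}

kl_divergence <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Bluethgen standardized specialization d'
#'
#' d = sum_j p'_j ln(p'_j / q_j), with p' the node's interaction proportions
#' and q the availability of each partner (marginal totals over the grand
#' total); d' = d / d_max rescales by the most specialised distribution
#' achievable given the marginals (vertex search over capped fill orders),
#' so d' runs from 0 (node uses partners in proportion to availability) to
#' 1 (exclusive use of the rarest achievable partner set).
#'
#' @param net a `bipartite_net`.
#' @param node coral or phylotype label.
#' @param side `"coral"` or `"phylotype"`.
#' @return d' in \[0, 1\].
#' @export
specificity_dprime <- function(net, node, side = c("coral", "phylotype")) {
  side <- match.arg(side)
  A <- if (side == "coral") net$counts else t(net$counts)
  i <- match(node, rownames(A))
  if (is.na(i)) stop("unknown ", side, ": ", node)
  row <- A[i, ]
  a <- sum(row)
  if (a == 0) stop(side, " has no records: ", node)
  avail <- colSums(A)
  q <- avail / sum(avail)
  d <- kl_divergence(row / a, q)
  dmax <- dprime_max(a, avail)
  if (dmax <= 0) return(0)
  min(1, max(0, d / dmax))
}

#' Bray-Curtis dissimilarity between two assemblages
#'
#' 1 - 2 * sum_j min(p_aj, p_bj) / (sum p_a + sum p_b) on frequency weights.
#'
#' @param a,b `assemblage_profile`s or named frequency vectors.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  wa <- if (inherits(a, "assemblage_profile")) a$weights else a
  wb <- if (inherits(b, "assemblage_profile")) b$weights else b
  u <- union(names(wa), names(wb))
  pa <- stats::setNames(numeric(length(u)), u); pa[names(wa)] <- wa
  pb <- stats::setNames(numeric(length(u)), u); pb[names(wb)] <- wb
  1 - 2 * sum(pmin(pa, pb)) / (sum(pa) + sum(pb))
}

unifrac_edge_presence <- function(tree, tipsets) {
  # indicator: does any tip of each set descend from each edge's child node?
  nt <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- nt + tr$Nnode
  flags <- matrix(FALSE, nnode, length(tipsets))
  for (s in seq_along(tipsets)) {
    flags[match(tipsets[[s]], tr$tip.label), s] <- TRUE
  }
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    flags[par, ] <- flags[par, ] | flags[child, ]
  }
  list(tree = tr, presence = flags[tr$edge[, 2], , drop = FALSE],
       lengths = tr$edge.length)
}

#' Unweighted UniFrac distance between two assemblages
#'
#' Presence/absence on the symbiont tree: the fraction of the branch length
#' spanned by either community that is unique to one of them. Branches with
#' no present tip below them contribute nothing, so the tree need not be
#' pruned; presence means any nonzero frequency.
#'
#' @param a,b `assemblage_profile`s or named frequency vectors.
#' @param symbiont_tree [ape::phylo] covering all present phylotypes.
#' @return distance in \[0, 1\].
#' @export
unweighted_unifrac <- function(a, b, symbiont_tree) {
  wa <- if (inherits(a, "assemblage_profile")) a$weights else a
  wb <- if (inherits(b, "assemblage_profile")) b$weights else b
  ta <- names(wa)[wa > 0]; tb <- names(wb)[wb > 0]
  u <- union(ta, tb)
  missing <- setdiff(u, symbiont_tree$tip.label)
  if (length(missing)) {
    stop("phylotypes absent from symbiont tree: ", paste(missing, collapse = ", "))
  }
  if (setequal(ta, tb)) return(0)
  ep <- unifrac_edge_presence(symbiont_tree, list(ta, tb))
  inA <- ep$presence[, 1]; inB <- ep$presence[, 2]
  either <- inA | inB
  unique_len <- sum(ep$lengths[xor(inA, inB)])
  total_len <- sum(ep$lengths[either])
  unique_len / total_len
}

tt_known <- function(profile, symbiont_traits) {
  tt <- symbiont_traits$TT[match(names(profile$weights), symbiont_traits$phylotype)]
  keep <- !is.na(tt)
  list(w = profile$weights[keep], tt = tt[keep])
}

#' Frequency-weighted mean thermotolerance of an assemblage
#'
#' Weighted mean of partner TT scores over TT-known phylotypes only
#' (weights renormalised on the known subset); `NA` when no partner has a
#' known score.
#'
#' @param profile an `assemblage_profile`.
#' @param symbiont_traits a `symbiont_traits` table.
#' @export
mean_tt <- function(profile, symbiont_traits) {
  k <- tt_known(profile, symbiont_traits)
  if (!length(k$w)) return(NA_real_)
  sum(k$w * k$tt) / sum(k$w)
}

#' Standard error of the frequency-weighted mean thermotolerance
#'
#' Unbiased weighted variance s^2 = sum w~_j (TT_j - mean)^2 / (1 - sum
#' w~_j^2) with w~ the renormalised TT-known weights, divided by the
#' effective sample size n_eff = 1 / sum w~^2; SE = sqrt(s^2 / n_eff).
#' `NA` with fewer than two TT-known partners.
#'
#' @inheritParams mean_tt
#' @export
stderror_mean_tt <- function(profile, symbiont_traits) {
  k <- tt_known(profile, symbiont_traits)
  if (length(k$w) < 2) return(NA_real_)
  wt <- k$w / sum(k$w)
  mu <- sum(wt * k$tt)
  denom <- 1 - sum(wt^2)
  if (denom <= 0) return(NA_real_)  # one partner carries all weight
  s2 <- sum(wt * (k$tt - mu)^2) / denom
  n_eff <- 1 / sum(wt^2)
  sqrt(s2 / n_eff)
}

#' Frequency mass of an assemblage per thermotolerance bin
#'
#' Sums frequency weights of TT-known phylotypes into half-open bins
#' `[0, e1], (e1, e2], ..., (ek, 100]` (defaults: 10/20/30/40). Weights are
#' not renormalised, so the bins total the TT-known frequency mass.
#'
#' @inheritParams mean_tt
#' @param edges strictly increasing internal bin edges.
#' @return named numeric vector, one entry per bin.
#' @export
tt_bin_frequencies <- function(profile, symbiont_traits, edges = c(10, 20, 30, 40)) {
  stopifnot(!is.unsorted(edges, strictly = TRUE))
  k <- tt_known(profile, symbiont_traits)
  breaks <- c(-Inf, edges, Inf)
  labs <- c(paste0("TT<=", edges[1]),
            paste0("TT", edges[-length(edges)], "-", edges[-1]),
            paste0("TT>", edges[length(edges)]))
  out <- stats::setNames(numeric(length(labs)), labs)
  if (length(k$w)) {
    bin <- cut(k$tt, breaks = breaks, labels = labs, right = TRUE)
    agg <- tapply(k$w, bin, sum)
    out[names(agg)] <- ifelse(is.na(agg), 0, agg)
  }
  out
}

#' Bleaching-response thirds
#'
#' Ranks corals by taxon-BRI and labels the top third `high`, the bottom
#' third `low` and the remainder `mid`. The third size defaults to
#' ceiling(n/3) and is configurable (floor, or a fixed count); ties break by
#' stable sort order and a fully tied table is flagged.
#'
#' @param coral_traits a `coral_traits` table.
#' @param rule `"ceil"`, `"floor"` or `"fixed"`.
#' @param n_fixed third size when `rule = "fixed"`.
#' @return `coral_traits` rows with a `bri_group` column (`NA` where BRI is
#'   missing).
#' @export
bri_groups <- function(coral_traits, rule = c("ceil", "floor", "fixed"),
                       n_fixed = NULL) {
  rule <- match.arg(rule)
  has <- !is.na(coral_traits$taxon_BRI)
  n <- sum(has)
  size <- switch(rule,
                 ceil = ceiling(n / 3),
                 floor = floor(n / 3),
                 fixed = { stopifnot(!is.null(n_fixed)); min(n_fixed, floor(n / 2)) })
  grp <- rep(NA_character_, nrow(coral_traits))
  if (n) {
    bri <- coral_traits$taxon_BRI[has]
    rk <- order(order(bri))  # stable ranks, ties by table order
    g <- rep("mid", n)
    g[rk <= size] <- "low"
    g[rk > n - size] <- "high"
    grp[has] <- g
    if (length(unique(bri)) == 1L) {
      attr(grp, "fully_tied") <- TRUE
      warning("all taxon_BRI values tied; groups assigned by table order")
    }
  }
  out <- coral_traits
  out$bri_group <- as.character(grp)
  out
}

#' Pairwise coral matrices: beta diversity, phylogenetic distance, delta-BRI
#'
#' Four symmetric zero-diagonal matrices on the common coral set:
#' Bray-Curtis dissimilarity and unweighted UniFrac distance between
#' symbiont assemblages, patristic distance on the coral tree, and the
#' absolute taxon-BRI difference.
#'
#' @param net a `bipartite_net`.
#' @param coral_tree coral phylogeny covering the network's corals.
#' @param coral_traits a `coral_traits` table (for BRI).
#' @param symbiont_tree symbiont phylogeny covering the network's phylotypes.
#' @return list of matrices `bray_curtis`, `unifrac`, `phylo_distance`,
#'   `delta_bri` (the latter with `NA` where BRI is missing).
#' @export
pairwise_matrices <- function(net, coral_tree, coral_traits, symbiont_tree) {
  corals <- intersect(net$corals, coral_tree$tip.label)
  if (length(corals) < 2) stop("fewer than two corals shared with the tree")
  W <- net$weights[corals, , drop = FALSE]
  bc <- as.matrix(vegan::vegdist(W, method = "bray"))
  uf <- unifrac_matrix(W, symbiont_tree)
  pd <- as.matrix(stats::cophenetic(prune_tree(coral_tree, corals)))[corals, corals]
  bri <- coral_traits$taxon_BRI[match(corals, coral_traits$coral)]
  db <- abs(outer(bri, bri, "-"))
  dimnames(db) <- list(corals, corals)
  diag(db) <- ifelse(is.na(bri), NA, 0)
  list(bray_curtis = bc[corals, corals], unifrac = uf[corals, corals],
       phylo_distance = pd, delta_bri = db)
}

unifrac_matrix <- function(presence_weights, symbiont_tree) {
  # all-pairs unweighted UniFrac via shared/total branch length algebra
  tips <- colnames(presence_weights)[colSums(presence_weights) > 0]
  missing <- setdiff(tips, symbiont_tree$tip.label)
  if (length(missing)) {
    stop("phylotypes absent from symbiont tree: ", paste(missing, collapse = ", "))
  }
  sets <- apply(presence_weights > 0, 1, function(r)
    intersect(colnames(presence_weights)[r], tips), simplify = FALSE)
  ep <- unifrac_edge_presence(symbiont_tree, sets)
  P <- ep$presence * 1
  lens <- ep$lengths
  shared <- t(P * lens) %*% P           # branch length present in both
  tot <- colSums(P * lens)
  either <- outer(tot, tot, "+") - shared
  U <- 1 - shared / either
  U[either == 0] <- 0
  diag(U) <- 0
  dimnames(U) <- list(rownames(presence_weights), rownames(presence_weights))
  U
}

#' Pearson correlation between two distance matrices with Mantel permutation
#'
#' Correlates the upper triangles and assesses significance by jointly
#' permuting the rows and columns of the second matrix (two-sided empirical
#' p with the +1 correction). Entries missing in either matrix are dropped
#' pairwise.
#'
#' @param M1,M2 symmetric matrices on the same taxa.
#' @param subset optional taxon subset (e.g. HT or VT corals only).
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return list `r`, `p`, `n_perm`, `n_taxa`, `seed`.
#' @export
matrix_correlation <- function(M1, M2, subset = NULL, n_perm = 10000L, seed = NULL) {
  stopifnot(all(dim(M1) == dim(M2)))
  taxa <- rownames(M1) %||% as.character(seq_len(nrow(M1)))
  if (!is.null(subset)) {
    keep <- match(intersect(subset, taxa), taxa)
    M1 <- M1[keep, keep, drop = FALSE]
    M2 <- M2[keep, keep, drop = FALSE]
  }
  n <- nrow(M1)
  if (n < 3) stop("need at least three taxa")
  ut <- upper.tri(M1)
  r_of <- function(perm) {
    x <- M1[ut]; y <- M2[perm, perm][ut]
    ok <- is.finite(x) & is.finite(y)
    stats::cor(x[ok], y[ok])
  }
  r_obs <- r_of(seq_len(n))
  exceed <- with_seed(seed, sum(vapply(seq_len(n_perm), function(i) {
    abs(r_of(sample.int(n))) >= abs(r_obs)
  }, logical(1))))
  list(r = r_obs, p = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, n_taxa = n, seed = seed)
}

#' Per-coral assemblage statistics table
#'
#' One row per coral: rarefied richness at each configured depth, d',
#' mean-TT, stderror mean-TT, TT-bin frequency masses, frequencies of named
#' phylotypes, total records, and the BRI third.
#'
#' @param net a `bipartite_net`.
#' @param coral_traits,symbiont_traits trait tables.
#' @param depths rarefaction depths (default 10, 15, 20).
#' @param tt_bin_edges thermotolerance bin edges.
#' @param named_phylotypes phylotype labels whose individual frequency is
#'   reported (e.g. `c("D1-4", "C3")`).
#' @param bri_rule,bri_n third-size rule passed to [bri_groups()].
#' @return data frame, one row per coral.
#' @export
assemblage_stats <- function(net, coral_traits = NULL, symbiont_traits = NULL,
                             depths = c(10L, 15L, 20L),
                             tt_bin_edges = c(10, 20, 30, 40),
                             named_phylotypes = NULL,
                             bri_rule = "ceil", bri_n = NULL) {
  profs <- lapply(net$corals, assemblage_profile, net = net)
  out <- data.frame(coral = net$corals, n_records = vapply(profs, `[[`, numeric(1), "N"),
                    stringsAsFactors = FALSE)
  for (d in depths) {
    out[[paste0("RD", d)]] <- vapply(profs, rarefied_richness, numeric(1), depth = d)
  }
  out$dprime <- vapply(net$corals, function(cc)
    specificity_dprime(net, cc, side = "coral"), numeric(1))
  if (!is.null(symbiont_traits)) {
    out$mean_TT <- vapply(profs, mean_tt, numeric(1), symbiont_traits = symbiont_traits)
    out$stderror_mean_TT <- vapply(profs, stderror_mean_tt, numeric(1),
                                   symbiont_traits = symbiont_traits)
    bins <- t(vapply(profs, tt_bin_frequencies, numeric(length(tt_bin_edges) + 1),
                     symbiont_traits = symbiont_traits, edges = tt_bin_edges))
    colnames(bins) <- paste0("freq_", colnames(bins))
    out <- cbind(out, as.data.frame(bins))
  }
  for (ph in named_phylotypes) {
    j <- match(ph, net$phylotypes)
    out[[paste0("freq_", gsub("[^A-Za-z0-9]", "_", ph))]] <-
      if (is.na(j)) 0 else as.numeric(net$weights[, j])
  }
  if (!is.null(coral_traits)) {
    grp <- bri_groups(coral_traits, rule = bri_rule, n_fixed = bri_n)
    m <- match(out$coral, grp$coral)
    out$taxon_BRI <- grp$taxon_BRI[m]
    out$bri_group <- grp$bri_group[m]
    out$transmission_mode <- grp$transmission_mode[m]
  }
  rownames(out) <- NULL
  out
}
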