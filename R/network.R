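#' Build the frequency-weighted bipartite network
#'
#' Rows are corals, columns phylotypes. `counts[i, j]` holds the number of
#' association records for the pair; `weights[i, j]` is that count divided
#' by the coral's total records, so the weights of all links leaving a coral
#' sum to one — link weight measures the frequency of interaction with each
#' symbiont from the host's point of view.
#'
#' @param interactions an `interaction_table`.
#' @return an object of class `bipartite_net`: a list with integer matrix
#'   `counts`, row-stochastic matrix `weights`, and the `corals` /
#'   `phylotypes` label vectors.
#' @export
build_network <- function(interactions) {
  stopifnot(nrow(interactions) > 0)
  corals <- sort(unique(interactions$coral))
  phylos <- sort(unique(interactions$phylotype))
  A <- matrix(0L, length(corals), length(phylos),
              dimnames = list(corals, phylos))
  A[cbind(match(interactions$coral, corals),
          match(interactions$phylotype, phylos))] <- as.integer(interactions$count)
  rs <- rowSums(A)
  if (any(rs == 0)) {
    warning("excluding corals with zero records: ",
            paste(corals[rs == 0], collapse = ", "))
    A <- A[rs > 0, , drop = FALSE]
    corals <- rownames(A)
    rs <- rowSums(A)
  }
  W <- A / rs
  structure(list(counts = A, weights = W, corals = corals, phylotypes = phylos),
            class = "bipartite_net")
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat(sprintf("frequency-weighted bipartite network: %d corals x %d phylotypes, %d links, %d records\n",
              length(x$corals), length(x$phylotypes),
              sum(x$counts > 0), sum(x$counts)))
  invisible(x)
}

#' Whole-network descriptors
#'
#' `connectance` is the realized fraction of possible coral-phylotype links;
#' `web_asymmetry` is (corals − phylotypes) / (corals + phylotypes), negative
#' when phylotypes outnumber corals (the sign convention is recorded in the
#' result's attributes).
#'
#' @param net a `bipartite_net`.
#' @return a single number.
#' @export
connectance <- function(net) {
  sum(net$counts > 0) / (length(net$corals) * length(net$phylotypes))
}

#' @rdname connectance
#' @export
web_asymmetry <- function(net) {
  nc <- length(net$corals); np <- length(net$phylotypes)
  structure((nc - np) / (nc + np), convention = "coral-minus-symbiont")
}

#' One-mode projection of the bipartite network
#'
#' Projects onto one side: two corals (or two phylotypes) are joined when
#' they share at least one partner. The default edge weight is the sum over
#' shared partners of the product of the two endpoints' frequency weights;
#' a `"minimum"` rule (sum of pairwise minima) is available for sensitivity
#' checks. No self-loops.
#'
#' @param net a `bipartite_net`.
#' @param side `"coral"` or `"phylotype"`.
#' @param rule `"product"` (default) or `"minimum"`.
#' @return a symmetric weighted adjacency matrix with zero diagonal and a
#'   `rule` attribute.
#' @export
one_mode_projection <- function(net, side = c("coral", "phylotype"),
                                rule = c("product", "minimum")) {
  side <- match.arg(side)
  rule <- match.arg(rule)
  W <- if (side == "coral") net$weights else t(net$weights)
  P <- if (rule == "product") {
    tcrossprod(W)
  } else {
    n <- nrow(W)
    M <- matrix(0, n, n, dimnames = list(rownames(W), rownames(W)))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) M[i, j] <- sum(pmin(W[i, ], W[j, ]))
    }
    M
  }
  diag(P) <- 0
  attr(P, "rule") <- rule
  P
}

#' Eigenvector centrality of a one-mode projection
#'
#' Leading eigenvector of the weighted adjacency, computed per connected
#' component and rescaled so the maximum over the whole node set is 1 within
#' each component; isolated nodes score 0. Invariant to uniform rescaling of
#' the edge weights.
#'
#' @param projection symmetric weighted adjacency matrix.
#' @return named numeric vector of scores in \[0, 1\].
#' @export
eigenvector_centrality <- function(projection) {
  stopifnot(is.matrix(projection), nrow(projection) == ncol(projection))
  if (!any(projection > 0)) stop("projection has no edges")
  if (is.null(rownames(projection))) {
    rownames(projection) <- colnames(projection) <- paste0("node", seq_len(nrow(projection)))
  }
  g <- igraph::graph_from_adjacency_matrix(projection, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  scores <- stats::setNames(numeric(nrow(projection)), rownames(projection))
  for (k in seq_len(comp$no)) {
    idx <- which(comp$membership == k)
    if (length(idx) == 1L) next  # isolated node scores 0
    sub <- igraph::induced_subgraph(g, idx)
    ev <- igraph::eigen_centrality(sub, weights = igraph::E(sub)$weight)$vector
    scores[igraph::V(sub)$name] <- ev
  }
  scores
}

#' Classify phylotypes by host transmission mode
#'
#' A phylotype's VT share is the fraction of its association records whose
#' host transmits symbionts vertically. Shares at or above `threshold` are
#' classed VT, at or below `1 - threshold` HT, and anything in between
#' mixed-mode (MMT).
#'
#' @param net a `bipartite_net`.
#' @param coral_traits a `coral_traits` table covering the network's corals.
#' @param threshold VT-share cutoff (default 0.95).
#' @return data frame with `phylotype`, `vt_share`, `transmission_class`.
#' @export
classify_phylotype_transmission <- function(net, coral_traits, threshold = 0.95) {
  mode <- coral_traits$transmission_mode[match(net$corals, coral_traits$coral)]
  if (anyNA(mode)) {
    stop("corals without transmission mode: ",
         paste(net$corals[is.na(mode)], collapse = ", "))
  }
  tot <- colSums(net$counts)
  if (any(tot == 0)) {
    stop("phylotypes with zero records: ",
         paste(net$phylotypes[tot == 0], collapse = ", "))
  }
  vt <- colSums(net$counts[mode == "VT", , drop = FALSE])
  share <- vt / tot
  cls <- ifelse(share >= threshold, "VT",
                ifelse(share <= 1 - threshold, "HT", "MMT"))
  data.frame(phylotype = net$phylotypes, vt_share = as.numeric(share),
             transmission_class = cls, stringsAsFactors = FALSE)
}

#' Export the network as an edge list
#'
#' @param net a `bipartite_net`.
#' @param path output CSV path.
#' @export
write_edgelist <- function(net, path) {
  idx <- which(net$counts > 0, arr.ind = TRUE)
  df <- data.frame(coral = net$corals[idx[, 1]],
                   phylotype = net$phylotypes[idx[, 2]],
                   count = net$counts[idx],
                   weight = net$weights[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(df$coral, df$phylotype), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
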