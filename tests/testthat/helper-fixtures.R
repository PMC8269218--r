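# Shared fixtures and brute-force oracles, all built in code.

toy_net <- function() {
  # 3 corals x 3 phylotypes with uneven counts
  build_network(interaction_table(
    c("A", "A", "B", "B", "C"),
    c("p1", "p2", "p2", "p3", "p3"),
    c(1, 3, 5, 3, 6)))
}

identity_net <- function() {
  build_network(interaction_table(c("A", "B"), c("p1", "p2"), c(1, 1)))
}

balanced_4tip_tree <- function() {
  ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
}

# all set partitions of n elements as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (g in seq_len(k + 1L)) rec(c(labels, g), max(k, g))
  }
  rec(integer(), 0L)
  out
}

# exhaustive maximum Barber Q over every partition of the network's nodes
exhaustive_max_Q <- function(net, matrix = "weights") {
  nc <- length(net$corals)
  np <- length(net$phylotypes)
  A <- net[[matrix]]
  F_ <- sum(A)
  k <- rowSums(A)
  d <- colSums(A)
  B <- A - outer(k, d) / F_
  best <- -Inf
  for (part in all_partitions(nc + np)) {
    gc <- part[seq_len(nc)]
    gp <- part[nc + seq_len(np)]
    q <- sum(B * outer(gc, gp, "==")) / F_
    if (q > best) best <- q
  }
  best
}

# brute-force one-mode projection by an explicit double loop
brute_projection <- function(net, side = "coral") {
  W <- if (side == "coral") net$weights else t(net$weights)
  n <- nrow(W)
  M <- matrix(0, n, n, dimnames = list(rownames(W), rownames(W)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) for (s in seq_len(ncol(W))) M[i, j] <- M[i, j] + W[i, s] * W[j, s]
  }
  M
}

# brute-force patristic distances by enumerating root-to-tip paths
brute_patristic <- function(tree) {
  nt <- length(tree$tip.label)
  parent <- function(node) {
    e <- which(tree$edge[, 2] == node)
    if (!length(e)) NULL else c(tree$edge[e, 1], tree$edge.length[e])
  }
  path_to_root <- function(tip) {
    nodes <- c(); lens <- c(); cur <- tip
    repeat {
      p <- parent(cur)
      if (is.null(p)) break
      nodes <- c(nodes, p[1]); lens <- c(lens, p[2]); cur <- p[1]
    }
    list(nodes = nodes, lens = lens)
  }
  paths <- lapply(seq_len(nt), path_to_root)
  D <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (i == j) next
    anc_i <- c(i, paths[[i]]$nodes)
    anc_j <- c(j, paths[[j]]$nodes)
    mrca <- anc_i[anc_i %in% anc_j][1]
    di <- sum(paths[[i]]$lens[seq_len(which(paths[[i]]$nodes == mrca))])
    dj <- sum(paths[[j]]$lens[seq_len(which(paths[[j]]$nodes == mrca))])
    D[i, j] <- di + dj
  }
  D
}

# enumerate every 3x3 nonnegative integer table with the given margins and
# return the maximum KL specialization d attainable by the focal row
exhaustive_dmax_3x3 <- function(rows, cols, focal = 1) {
  stopifnot(length(rows) == 3, length(cols) == 3, sum(rows) == sum(cols))
  q <- cols / sum(cols)
  best <- -Inf
  for (a11 in 0:min(rows[1], cols[1])) for (a12 in 0:min(rows[1] - a11, cols[2])) {
    a13 <- rows[1] - a11 - a12
    if (a13 > cols[3]) next
    for (a21 in 0:min(rows[2], cols[1] - a11)) {
      for (a22 in 0:min(rows[2] - a21, cols[2] - a12)) {
        a23 <- rows[2] - a21 - a22
        if (a23 > cols[3] - a13) next
        a31 <- cols[1] - a11 - a21
        a32 <- cols[2] - a12 - a22
        a33 <- cols[3] - a13 - a23
        if (a31 < 0 || a32 < 0 || a33 < 0 || a31 + a32 + a33 != rows[3]) next
        tab <- rbind(c(a11, a12, a13), c(a21, a22, a23), c(a31, a32, a33))
        p <- tab[focal, ] / rows[focal]
        nz <- p > 0
        d <- sum(p[nz] * log(p[nz] / q[nz]))
        if (d > best) best <- d
      }
    }
  }
  best
}

small_sim <- function(seed = 7, mu = 0.05, ...) {
  simulate_network(synthetic_spec(n_corals = 24, n_phylotypes = 48,
                                  target_total_records = 2400, n_modules = 3,
                                  mu = mu, seed = seed, ...))
}
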