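test_that("Barber Q matches hand evaluation on the 2x2 identity network", {
  net <- identity_net()
  paired <- list(coral_modules = c(A = 1, B = 2),
                 phylotype_modules = c(p1 = 1, p2 = 2))
  expect_equal(barber_modularity(net, paired), 0.5)
  lumped <- list(coral_modules = c(A = 1, B = 1),
                 phylotype_modules = c(p1 = 1, p2 = 1))
  expect_equal(barber_modularity(net, lumped), 0)

  # one module covering everything is always Q = 0
  net2 <- toy_net()
  all1 <- list(coral_modules = stats::setNames(rep(1, 3), net2$corals),
               phylotype_modules = stats::setNames(rep(1, 3), net2$phylotypes))
  expect_equal(barber_modularity(net2, all1), 0, tolerance = 1e-12)
})

test_that("record filter removes rare phylotypes and renormalises weights", {
  it <- interaction_table(c("A", "A", "B", "B"), c("p1", "p2", "p1", "p3"),
                          c(5, 2, 4, 3))
  net <- build_network(it)
  f <- filter_for_modularity(net, 3)
  expect_false("p2" %in% f$phylotypes)   # 2 records < 3
  expect_true(all(c("p1", "p3") %in% f$phylotypes))
  expect_equal(unname(rowSums(f$weights)), rep(1, 2), tolerance = 1e-12)

  expect_identical(filter_for_modularity(net, 1)$counts, net$counts)
  expect_error(filter_for_modularity(net, 100), "removed")

  # survivor count equals the brute-force count on a synthetic network
  sim <- small_sim()
  net2 <- build_network(sim$interactions)
  f2 <- filter_for_modularity(net2, 3)
  expect_equal(length(f2$phylotypes), sum(colSums(net2$counts) >= 3))
})

test_that("optimizer attains the exhaustive-search maximum Q on small instances", {
  # planted 2-block 4x4, mu = 0
  it <- interaction_table(
    c("c1", "c1", "c2", "c2", "c3", "c3", "c4", "c4"),
    c("q1", "q2", "q1", "q2", "q3", "q4", "q3", "q4"),
    c(3, 1, 2, 2, 1, 3, 2, 2))
  net <- build_network(it)
  best_Q <- exhaustive_max_Q(net)
  opt <- optimize_modules(net, n_stitches = 2e4, seed = 1)
  expect_equal(opt$Q, best_Q, tolerance = 1e-12)

  # 5x5 with an uneven planted structure (Bell(10) = 115975 partitions)
  it2 <- interaction_table(
    c("c1", "c1", "c2", "c3", "c3", "c4", "c4", "c5", "c5", "c1"),
    c("q1", "q2", "q2", "q3", "q4", "q4", "q5", "q5", "q3", "q3"),
    c(4, 2, 5, 3, 2, 2, 3, 4, 1, 1))
  net2 <- build_network(it2)
  best_Q2 <- exhaustive_max_Q(net2)
  runs <- lapply(1:5, function(s) optimize_modules(net2, n_stitches = 2e4, seed = s))
  expect_equal(max(vapply(runs, `[[`, numeric(1), "Q")), best_Q2, tolerance = 1e-12)
})

test_that("optimizer is deterministic under a fixed seed and Q is recomputable", {
  sim <- small_sim()
  net <- build_network(sim$interactions)
  a <- optimize_modules(net, n_stitches = 5e4, seed = 99)
  b <- optimize_modules(net, n_stitches = 5e4, seed = 99)
  expect_identical(a$coral_modules, b$coral_modules)
  expect_identical(a$phylotype_modules, b$phylotype_modules)
  expect_equal(a$Q, b$Q)
  # stored Q always equals a from-scratch recomputation
  expect_equal(a$Q, barber_modularity(net, a), tolerance = 1e-12)

  # single-coral network collapses to one module with Q = 0
  one <- build_network(interaction_table(rep("A", 2), c("p1", "p2"), c(1, 1)))
  po <- optimize_modules(one, n_stitches = 5e3, seed = 1)
  expect_equal(po$n_modules, 1)
  expect_equal(po$Q, 0, tolerance = 1e-12)
})

test_that("optimizer never falls below its initial partition's Q", {
  for (seed in 1:3) {
    sim <- small_sim(seed = seed)
    net <- build_network(sim$interactions)
    # reconstruct the optimizer's start: singleton phylotypes, corals seeded
    # by their strongest-weight phylotype
    strongest <- max.col(net$weights, ties.method = "first")
    init <- list(
      coral_modules = stats::setNames(strongest, net$corals),
      phylotype_modules = stats::setNames(seq_along(net$phylotypes), net$phylotypes))
    q0 <- barber_modularity(net, init)
    opt <- optimize_modules(net, n_stitches = 5e4, seed = seed)
    expect_gte(opt$Q, q0 - 1e-12)
  }
})

test_that("partition selection: fewest modules first, then highest Q, then order", {
  mk <- function(k, q) structure(list(n_modules = k, Q = q), class = "module_partition")
  runs <- list(mk(7, 0.56), mk(7, 0.57), mk(9, 0.60))
  expect_equal(select_partition(runs)$Q, 0.57)
  expect_equal(select_partition(runs)$meta$selected_run, 2)
  expect_equal(select_partition(runs[3])$Q, 0.60)
  same <- list(mk(5, 0.5), mk(5, 0.5))
  expect_equal(select_partition(same)$meta$selected_run, 1)
  expect_error(select_partition(list()), "empty")
})

test_that("null-model Q under random partitions is centred on zero", {
  sim <- small_sim()
  net <- filter_for_modularity(build_network(sim$interactions), 3)
  set.seed(5)
  tabs <- stats::r2dtable(100, rowSums(net$counts), colSums(net$counts))
  qs <- vapply(tabs, function(tab) {
    dimnames(tab) <- list(net$corals, net$phylotypes)
    idx <- which(tab > 0, arr.ind = TRUE)
    nn <- build_network(interaction_table(net$corals[idx[, 1]],
                                          net$phylotypes[idx[, 2]], tab[idx]))
    part <- list(
      coral_modules = stats::setNames(sample(1:4, length(nn$corals), TRUE), nn$corals),
      phylotype_modules = stats::setNames(sample(1:4, length(nn$phylotypes), TRUE),
                                          nn$phylotypes))
    barber_modularity(nn, part)
  }, numeric(1))
  expect_lt(abs(mean(qs)), 0.02)
})

test_that("modularity z-score separates planted structure from shuffled networks", {
  sim <- small_sim(mu = 0.02)
  net <- filter_for_modularity(build_network(sim$interactions), 3)
  part <- optimize_modules(net, n_stitches = 5e4, seed = 2)
  z <- modularity_zscore(net, part, n_null = 30, seed = 3, null_stitches = 5e4)
  expect_gt(z$z, 3)
  expect_error(modularity_zscore(net, part, n_null = 1), "n_null")

  # a marginal-preserving shuffle of the same network scores |z| small
  set.seed(11)
  tab <- stats::r2dtable(1, rowSums(net$counts), colSums(net$counts))[[1]]
  dimnames(tab) <- list(net$corals, net$phylotypes)
  idx <- which(tab > 0, arr.ind = TRUE)
  rnet <- build_network(interaction_table(net$corals[idx[, 1]],
                                          net$phylotypes[idx[, 2]], tab[idx]))
  rpart <- optimize_modules(rnet, n_stitches = 5e4, seed = 4)
  rz <- modularity_zscore(rnet, rpart, n_null = 30, seed = 5, null_stitches = 5e4)
  expect_lt(abs(rz$z), 3)
})

test_that("participation c and within-module z follow their formulas", {
  # all links in one module -> c = 0
  it <- interaction_table(c("A", "B"), c("p1", "p1"), c(2, 2))
  net <- build_network(it)
  part <- list(coral_modules = c(A = 1, B = 1), phylotype_modules = c(p1 = 1))
  sc <- participation_scores(net, part)
  expect_equal(sc$c, 0)

  # strength equally split over two modules -> c = 1 - 2 (1/2)^2 = 0.5
  it2 <- interaction_table(c("A", "B"), c("px", "px"), c(1, 1))
  net2 <- build_network(it2)
  part2 <- list(coral_modules = c(A = 1, B = 2), phylotype_modules = c(px = 1))
  expect_equal(participation_scores(net2, part2)$c, 0.5)

  # equal split over t modules -> c = 1 - 1/t
  for (t in 2:4) {
    corals <- paste0("c", seq_len(t))
    itt <- interaction_table(corals, rep("px", t), rep(1, t))
    nett <- build_network(itt)
    partt <- list(coral_modules = stats::setNames(seq_len(t), corals),
                  phylotype_modules = c(px = 1))
    expect_equal(participation_scores(nett, partt)$c, 1 - 1 / t, tolerance = 1e-12)
  }

  # equal within-module strengths -> all z = 0 (sd-zero rule)
  it3 <- interaction_table(c("A", "A", "B", "B"), c("p1", "p2", "p1", "p2"),
                           c(1, 1, 1, 1))
  net3 <- build_network(it3)
  part3 <- list(coral_modules = c(A = 1, B = 1),
                phylotype_modules = c(p1 = 1, p2 = 1))
  expect_equal(participation_scores(net3, part3)$z, c(0, 0))

  # c and z are invariant under module relabeling
  sim <- small_sim()
  net4 <- build_network(sim$interactions)
  p4 <- optimize_modules(net4, n_stitches = 5e4, seed = 6)
  relab <- p4
  perm <- sample(seq_len(p4$n_modules))
  relab$coral_modules[] <- perm[p4$coral_modules]
  relab$phylotype_modules[] <- perm[p4$phylotype_modules]
  s1 <- participation_scores(net4, p4)
  s2 <- participation_scores(net4, relab)
  expect_equal(s1$c, s2$c, tolerance = 1e-12)
  expect_equal(s1$z, s2$z, tolerance = 1e-12)
})

test_that("role replication averages runs and degenerate runs give zero SD", {
  sim <- small_sim(mu = 0, dirichlet_conc = 200, tail_exponent = 50)
  net <- filter_for_modularity(build_network(sim$interactions), 3)
  rr <- replicate_roles(net, n_runs = 5, seed = 4, n_stitches = 5e4)
  expect_equal(nrow(rr), length(net$phylotypes))
  # mu = 0 planted blocks: every run should find the same partition
  expect_true(all(rr$c_sd < 1e-9))
  expect_true(all(rr$z_sd < 1e-9))

  one <- replicate_roles(net, n_runs = 1, seed = 9, n_stitches = 5e4)
  single <- participation_scores(net, optimize_modules(net, n_stitches = 5e4,
                                                       seed = symbionet:::derive_seeds(9, 1)[1]))
  expect_equal(one$c, single$c)
})

test_that("role thresholds default to (0.6, 2) and classification is quadrant-based", {
  expect_equal(role_thresholds(NULL, permute = FALSE), c(c = 0.6, z = 2.0))

  sc <- data.frame(phylotype = c("a", "b", "c", "d"),
                   c = c(0.1, 0.3, 0.7, 0.7), z = c(-0.5, 2.5, 0.4, 2.5))
  roles <- classify_roles(sc)$role
  expect_equal(roles, c("peripheral", "module hub", "connector", "network hub"))
})

test_that("NMI scores identical, independent and degenerate partitions correctly", {
  a <- rep(1:3, each = 10)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, sample(3, 30, TRUE)), nmi(sample(3, 30, TRUE), a),
               tolerance = 1)  # symmetric in distribution; both in [0,1]
  expect_equal(nmi(rep(1, 10), rep(1, 10)), 1)
  expect_equal(nmi(rep(1, 10), rep(1:2, 5)), 0)
  b <- a; b[1] <- 3
  expect_gt(nmi(a, b), 0.8)
})
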