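test_that("rarefied richness matches the hypergeometric expectation", {
  expect_equal(rarefied_richness(c(5), 3), 1)            # monodominant
  expect_equal(rarefied_richness(c(2, 1), 2), 2 - 1 / 3) # hand case 5/3
  expect_true(is.na(rarefied_richness(c(3, 2), 10)))     # below depth: excluded

  # Monte Carlo agrees with the analytic expectation within 3 SEs
  set.seed(8)
  for (i in 1:3) {
    counts <- rpois(6, 3) + 1
    depth <- sum(counts) - sample(3, 1)
    ana <- rarefied_richness(counts, depth)
    n_res <- 4000
    mc <- rarefied_richness(counts, depth, method = "monte_carlo",
                            seed = i, n_resample = n_res)
    # SE of the MC mean is below the sd of a bounded count / sqrt(n)
    expect_lt(abs(mc - ana), 3 * length(counts) / sqrt(n_res) + 0.05)
  }

  # monotone nondecreasing in depth, bounded by observed richness
  counts <- c(8, 4, 2, 1, 1)
  vals <- vapply(2:10, function(k) rarefied_richness(counts, k), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals <= 5 + 1e-12))
})

test_that("d' is 0 for availability-proportional use and 1 for exclusive rarest pairs", {
  # interaction proportions equal to availability
  it <- interaction_table(rep(c("A", "B"), each = 2), rep(c("p1", "p2"), 2),
                          c(2, 2, 2, 2))
  expect_equal(specificity_dprime(build_network(it), "A", "coral"), 0)

  # exclusive pair with the rarest, otherwise unused partner
  it2 <- interaction_table(c("A", "B", "B", "C", "C"),
                           c("p1", "p2", "p3", "p2", "p3"),
                           c(2, 5, 3, 4, 6))
  expect_equal(specificity_dprime(build_network(it2), "A", "coral"), 1)

  # bounds on arbitrary nodes of a synthetic network, both sides
  sim <- small_sim()
  net <- build_network(sim$interactions)
  for (cc in net$corals[1:8]) {
    d <- specificity_dprime(net, cc, "coral")
    expect_gte(d, 0); expect_lte(d, 1)
  }
  for (pp in net$phylotypes[1:8]) {
    d <- specificity_dprime(net, pp, "phylotype")
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("d_max equals the exhaustive 3x3 marginal-preserving search", {
  set.seed(21)
  for (i in 1:20) {
    rows <- rmultinom(1, sample(6:12, 1), c(1, 1, 1))[, 1] + 1
    cols <- rmultinom(1, sum(rows), c(1, 1, 1))[, 1]
    while (any(cols == 0)) cols <- rmultinom(1, sum(rows), c(1, 1, 1))[, 1]
    ex <- exhaustive_dmax_3x3(rows, cols, focal = 1)
    expect_equal(symbionet:::dprime_max(rows[1], cols), ex, tolerance = 1e-9)
  }
})

test_that("Bray-Curtis satisfies identity, disjointness and the hand case", {
  expect_equal(bray_curtis(c(p1 = .5, p2 = .5), c(p1 = .5, p2 = .5)), 0)
  expect_equal(bray_curtis(c(p1 = 1), c(p2 = 1)), 1)
  expect_equal(bray_curtis(c(p1 = .5, p2 = .5), c(p1 = 1)), 0.5)

  # symmetry + range over synthetic profiles; agreement with vegan
  sim <- small_sim()
  net <- build_network(sim$interactions)
  W <- net$weights[1:6, ]
  vg <- as.matrix(vegan::vegdist(W, "bray"))
  for (i in 1:5) for (j in (i + 1):6) {
    a <- W[i, ][W[i, ] > 0]; b <- W[j, ][W[j, ] > 0]
    expect_equal(bray_curtis(a, b), vg[i, j], tolerance = 1e-12)
    expect_equal(bray_curtis(a, b), bray_curtis(b, a))
  }
})

test_that("unweighted UniFrac matches the worked cases and picante", {
  tr <- balanced_4tip_tree()
  expect_equal(unweighted_unifrac(c(t1 = .5, t2 = .5), c(t1 = 1), tr), 1 / 3)
  expect_equal(unweighted_unifrac(c(t1 = .5, t2 = .5), c(t3 = .5, t4 = .5), tr), 1)
  expect_equal(unweighted_unifrac(c(t1 = .3, t2 = .7), c(t2 = .2, t1 = .8), tr), 0)
  expect_error(unweighted_unifrac(c(t9 = 1), c(t1 = 1), tr), "t9")

  set.seed(14)
  tr2 <- ape::rphylo(12, 1, 0)
  comm <- matrix(rbinom(48, 1, 0.5), 4, 12,
                 dimnames = list(paste0("s", 1:4), tr2$tip.label))
  comm[rowSums(comm) == 0, 1] <- 1
  pic <- as.matrix(picante::unifrac(comm, tr2))
  for (i in 1:3) for (j in (i + 1):4) {
    a <- stats::setNames(comm[i, ], colnames(comm))
    b <- stats::setNames(comm[j, ], colnames(comm))
    expect_equal(unweighted_unifrac(a, b, tr2), pic[paste0("s", i), paste0("s", j)],
                 tolerance = 1e-12)
  }
})

test_that("mean-TT and its standard error follow the weighted formulas", {
  st <- symbiont_traits(data.frame(phylotype = c("p1", "p2", "p3"),
                                   TT = c(20, 40, NA)))
  prof1 <- structure(list(weights = c(p1 = 1), counts = c(p1 = 3), N = 3),
                     class = "assemblage_profile")
  st1 <- symbiont_traits(data.frame(phylotype = "p1", TT = 50))
  expect_equal(mean_tt(prof1, st1), 50)

  prof <- structure(list(weights = c(p1 = 0.25, p2 = 0.75), N = 4),
                    class = "assemblage_profile")
  expect_equal(mean_tt(prof, st), 35)

  # missing-TT partner excluded with renormalisation
  prof2 <- structure(list(weights = c(p3 = 0.6, p1 = 0.4), N = 5),
                     class = "assemblage_profile")
  st2 <- symbiont_traits(data.frame(phylotype = c("p1", "p3"), TT = c(30, NA)))
  expect_equal(mean_tt(prof2, st2), 30)
  expect_true(is.na(mean_tt(prof2, symbiont_traits(
    data.frame(phylotype = c("p1", "p3"), TT = c(NA, NA))))))

  # equal weights, TT 20/40: n_eff = 2, s^2 = 200, SE = 10
  prof3 <- structure(list(weights = c(p1 = 0.5, p2 = 0.5), N = 2),
                     class = "assemblage_profile")
  expect_equal(stderror_mean_tt(prof3, st), 10)
  # equal TT -> SE 0; single known partner -> missing
  st_eq <- symbiont_traits(data.frame(phylotype = c("p1", "p2"), TT = c(30, 30)))
  expect_equal(stderror_mean_tt(prof3, st_eq), 0)
  expect_true(is.na(stderror_mean_tt(prof2, st2)))
})

test_that("TT bins are left-open right-closed with the documented edges", {
  st <- symbiont_traits(data.frame(phylotype = paste0("p", 1:4),
                                   TT = c(5, 10, 40.0001, NA)))
  prof <- structure(list(weights = c(p1 = 0.4, p2 = 0.3, p3 = 0.2, p4 = 0.1),
                         N = 10), class = "assemblage_profile")
  bins <- tt_bin_frequencies(prof, st)
  expect_equal(unname(bins["TT<=10"]), 0.7)   # 5 and the boundary value 10
  expect_equal(unname(bins["TT>40"]), 0.2)    # 40.0001 is above the last edge
  expect_equal(unname(bins[c("TT10-20", "TT20-30", "TT30-40")]), c(0, 0, 0))
  # bins total the TT-known frequency mass
  expect_equal(sum(bins), 0.9, tolerance = 1e-12)
})

test_that("BRI thirds use the configurable size rule with stable tie-breaks", {
  tr <- coral_traits(data.frame(coral = paste0("c", 1:3),
                                transmission_mode = "HT", ocean = "Atlantic",
                                life_history = "weedy", taxon_BRI = c(1, 2, 3)))
  g <- bri_groups(tr)
  expect_equal(g$bri_group, c("low", "mid", "high"))

  n <- 152
  tr2 <- coral_traits(data.frame(coral = sprintf("c%03d", 1:n),
                                 transmission_mode = "HT", ocean = "Atlantic",
                                 life_history = "weedy",
                                 taxon_BRI = seq(0, 100, length.out = n)))
  g2 <- bri_groups(tr2)                       # default ceil(152/3) = 51
  expect_equal(sum(g2$bri_group == "high"), 51)
  expect_equal(sum(g2$bri_group == "low"), 51)
  g3 <- bri_groups(tr2, rule = "floor")
  expect_equal(sum(g3$bri_group == "high"), 50)
  g4 <- bri_groups(tr2, rule = "fixed", n_fixed = 56)
  expect_equal(sum(g4$bri_group == "high"), 56)

  tied <- tr
  tied$taxon_BRI <- rep(5, 3)
  expect_warning(bri_groups(tied), "tied")
})

test_that("pairwise matrices are symmetric with zero diagonals", {
  sim <- small_sim()
  net <- build_network(sim$interactions)
  m <- pairwise_matrices(net, sim$coral_tree, sim$coral_traits, sim$symbiont_tree)
  for (nm in names(m)) {
    M <- m[[nm]]
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_true(all(abs(diag(M)) < 1e-12 | is.na(diag(M))))
  }
  expect_true(all(m$bray_curtis >= 0 & m$bray_curtis <= 1))
  expect_true(all(m$unifrac >= 0 & m$unifrac <= 1 + 1e-12))
  bri <- sim$coral_traits$taxon_BRI[match(rownames(m$delta_bri), sim$coral_traits$coral)]
  i <- 2; j <- 5
  expect_equal(m$delta_bri[i, j], abs(bri[i] - bri[j]))
})

test_that("matrix correlation: perfect, anti-ordered, and p lower bound", {
  set.seed(3)
  D1 <- as.matrix(dist(runif(8)))
  dimnames(D1) <- list(letters[1:8], letters[1:8])
  M2 <- 2 * D1 + 1; diag(M2) <- 0
  r <- matrix_correlation(D1, M2, n_perm = 99, seed = 1)
  expect_equal(r$r, 1)
  expect_gte(r$p, 1 / 100)

  anti <- max(D1) - D1; diag(anti) <- 0
  expect_lt(matrix_correlation(D1, anti, n_perm = 49, seed = 2)$r, 0)

  expect_error(matrix_correlation(D1[1:2, 1:2], D1[1:2, 1:2]), "three")
})

test_that("assemblage statistics table is complete and internally consistent", {
  sim <- small_sim()
  net <- build_network(sim$interactions)
  st <- assemblage_stats(net, sim$coral_traits, sim$symbiont_traits,
                         named_phylotypes = net$phylotypes[1])
  expect_equal(nrow(st), length(net$corals))
  expect_true(all(c("RD10", "RD15", "RD20", "dprime", "mean_TT",
                    "stderror_mean_TT", "bri_group") %in% names(st)))
  # rarefied richness nondecreasing with depth where defined
  ok <- !is.na(st$RD20)
  expect_true(all(st$RD20[ok] >= st$RD15[ok] - 1e-9))
  expect_true(all(st$RD15[!is.na(st$RD15)] >= st$RD10[!is.na(st$RD15)] - 1e-9))
  # TT bin mass + unknown mass accounts for all frequency weight
  bins <- rowSums(st[, grep("^freq_TT", names(st))])
  known <- vapply(st$coral, function(cc) {
    pr <- assemblage_profile(net, cc)
    k <- symbionet:::tt_known(pr, sim$symbiont_traits)
    sum(k$w)
  }, numeric(1))
  expect_equal(unname(bins), unname(known), tolerance = 1e-12)
})
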