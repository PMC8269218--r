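test_that("phylogenetic covariance encodes shared branch lengths", {
  star <- ape::stree(4, "star")
  star$edge.length <- rep(1, 4)
  C <- phylo_covariance(star)
  expect_equal(C, diag(4), ignore_attr = TRUE)

  tr <- ape::read.tree(text = "((a:1,b:1):2,c:0.5);")
  C2 <- phylo_covariance(tr)
  expect_equal(C2["a", "b"], 2)
  expect_equal(C2["a", "a"], 3)

  # lambda = 0 is diagonal on any tree; PSD across lambda
  set.seed(2)
  big <- ape::rphylo(30, 1, 0)
  C0 <- phylo_covariance(big, lambda = 0)
  expect_equal(C0, diag(diag(C0)), ignore_attr = TRUE)
  for (lam in c(0, 0.3, 0.7, 1)) {
    Cl <- phylo_covariance(big, lambda = lam)
    expect_silent(chol(Cl + diag(1e-10, 30)))
  }
})

test_that("lambda ML matches an independent implementation and endpoint logic", {
  set.seed(31)
  tr <- ape::rphylo(60, 1, 0)
  x <- simulate_traits(tr, sigma2 = 2, lambda = 0.6, bounds = NULL, seed = 5)
  fit <- pagel_lambda_ml(x, tr)
  ps <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(fit$lambda, ps$lambda, tolerance = 1e-3)
  expect_equal(fit$logL, ps$logL, tolerance = 1e-6)

  # optimum beats both endpoints by construction
  C <- phylo_covariance(tr)
  ll <- function(lam) symbionet:::gls_profile(
    x[tr$tip.label], matrix(1, 60, 1), symbionet:::lambda_transform(C, lam))$logL
  expect_gte(fit$logL, ll(0) - 1e-8)
  expect_gte(fit$logL, ll(1) - 1e-8)

  # star tree: unidentifiable, returned as lambda = 0 with a flag
  star <- ape::stree(12, "star")
  star$edge.length <- rep(1, 12)
  xs <- stats::setNames(rnorm(12), star$tip.label)
  fs <- pagel_lambda_ml(xs, star)
  expect_true(fs$unidentifiable)
  expect_equal(fs$lambda, 0)

  expect_error(pagel_lambda_ml(stats::setNames(rep(1, 60), tr$tip.label), tr),
               "constant")
})

test_that("likelihoods via Cholesky match brute-force determinant evaluation", {
  set.seed(7)
  tr <- ape::rphylo(8, 1, 0)
  x <- simulate_traits(tr, 1, 0.8, bounds = NULL, seed = 3)
  C <- phylo_covariance(tr)
  for (lam in c(0.2, 0.9)) {
    V <- symbionet:::lambda_transform(C, lam)
    f <- symbionet:::gls_profile(x[tr$tip.label], matrix(1, 8, 1), V)
    # brute force: profile mu and sigma2 with solve() and det()
    Vi <- solve(V)
    one <- rep(1, 8)
    mu <- drop(crossprod(one, Vi %*% x[tr$tip.label]) / crossprod(one, Vi %*% one))
    r <- x[tr$tip.label] - mu
    s2 <- drop(crossprod(r, Vi %*% r)) / 8
    ll <- -0.5 * (8 * log(2 * pi * s2) + log(det(V)) + 8)
    expect_equal(f$logL, ll, tolerance = 1e-8)
  }
})

test_that("PGLS reduces to OLS at lambda 0 and matches nlme under ML lambda", {
  set.seed(12)
  tr <- ape::rphylo(40, 1, 0)
  x <- simulate_traits(tr, 1, 1, bounds = NULL, seed = 2)
  y <- 1 + 2 * x + simulate_traits(tr, 0.5, 1, bounds = NULL, seed = 9)
  f0 <- pgls(y, x, tr, lambda_mode = "fixed", lambda = 0)
  ols <- stats::lm(y[tr$tip.label] ~ x[tr$tip.label])
  expect_equal(f0$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(f0$coefficients$se,
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-8)

  fml <- pgls(y, x, tr)
  d <- data.frame(y = y[tr$tip.label], x = x[tr$tip.label])
  ref <- suppressWarnings(nlme::gls(y ~ x, data = d, method = "ML",
                                    correlation = ape::corPagel(0.5, tr, form = ~1)))
  expect_equal(fml$coefficients$estimate, unname(coef(ref)), tolerance = 1e-2)
  expect_equal(fml$lambda,
               min(max(unname(coef(ref$modelStruct$corStruct)), 0), 1),
               tolerance = 0.02)
  expect_lte(abs(fml$R), 1)
  expect_equal(sign(fml$R), sign(fml$coefficients$estimate[2]))

  expect_error(pgls(y, cbind(x = x[tr$tip.label], x2 = x[tr$tip.label]), tr),
               "singular")
})

test_that("PGLS recovers a known slope under Brownian noise", {
  set.seed(44)
  tr <- ape::rphylo(80, 1, 0)
  betas <- vapply(1:25, function(i) {
    x <- simulate_traits(tr, 1, 1, bounds = NULL, seed = 100 + i)
    y <- 2 * x + simulate_traits(tr, 1, 1, bounds = NULL, seed = 900 + i)
    pgls(y, x, tr)$coefficients$estimate[2]
  }, numeric(1))
  expect_gt(mean(betas), 1.85)
  expect_lt(mean(betas), 2.15)
})

test_that("phylogenetic ANOVA: F agrees with aov and planted shifts are detected", {
  set.seed(17)
  tr <- ape::rphylo(40, 1, 0)
  x <- simulate_traits(tr, 1, 1, bounds = NULL, seed = 4)
  g <- stats::setNames(sample(c("a", "b", "c"), 40, TRUE), tr$tip.label)
  expect_equal(symbionet:::oneway_F(x, g),
               stats::anova(stats::lm(x ~ g))$`F value`[1], tolerance = 1e-12)

  fit <- phylo_anova(x, g, tr, n_sim = 99, seed = 5)
  expect_gte(fit$p, 1 / 100)

  x2 <- x
  x2[g == "a"] <- x2[g == "a"] + 4 * stats::sd(x)
  fit2 <- phylo_anova(x2, g, tr, n_sim = 199, seed = 6)
  expect_lt(fit2$p, 0.05)

  expect_error(phylo_anova(x, stats::setNames(c("a", rep("b", 39)), tr$tip.label),
                           tr, n_sim = 10), "two members")
  expect_error(phylo_anova(x, g, tr, n_sim = 0), "positive")
})

test_that("phylogenetic logistic regression handles boundaries and recovers signs", {
  set.seed(23)
  star <- ape::stree(40, "star")
  star$edge.length <- rep(1, 40)
  xs <- stats::setNames(rnorm(40), star$tip.label)
  ys <- stats::setNames(rbinom(40, 1, stats::plogis(xs)), star$tip.label)
  fit <- phylo_logistic(ys, xs, star)
  firth <- symbionet:::firth_logistic(as.numeric(ys[star$tip.label]),
                                      cbind(1, as.numeric(xs[star$tip.label])))
  expect_true(fit$no_signal)
  expect_equal(fit$coefficients$estimate, unname(firth$beta), tolerance = 1e-6)

  expect_error(phylo_logistic(stats::setNames(rep(1, 40), star$tip.label), xs, star),
               "constant")

  # complete separation stays finite and is flagged
  xsep <- stats::setNames(c(rep(-2, 20), rep(2, 20)), star$tip.label)
  ysep <- stats::setNames(c(rep(0, 20), rep(1, 20)), star$tip.label)
  fsep <- phylo_logistic(ysep, xsep, star)
  expect_true(all(is.finite(fsep$coefficients$estimate)))

  # sign recovery with phylogenetically clustered predictor
  tr <- ape::rphylo(60, 1, 0)
  hits <- 0; reps <- 20
  for (i in 1:reps) {
    x <- simulate_traits(tr, 1, 1, bounds = NULL, seed = 300 + i)
    y <- stats::setNames(rbinom(60, 1, stats::plogis(-0.3 + 2 * x[tr$tip.label])),
                         tr$tip.label)
    f <- phylo_logistic(y, x, tr)
    if (f$coefficients$estimate[2] > 0) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("patristic distances match brute-force path enumeration", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(pairwise_phylo_distance(tr)["a", "b"], 2)

  set.seed(9)
  for (i in 1:3) {
    big <- ape::rphylo(10, 1, 0)
    expect_equal(pairwise_phylo_distance(big),
                 brute_patristic(big)[big$tip.label, big$tip.label],
                 tolerance = 1e-10)
  }
  # ultrametric: all pairs through the root are equidistant
  big <- ape::rphylo(12, 1, 0)
  D <- pairwise_phylo_distance(big)
  root_children <- big$edge[big$edge[, 1] == 13, 2]
  lhs <- ape::extract.clade(big, root_children[1])$tip.label
  if (root_children[2] <= 12) {
    rhs <- big$tip.label[root_children[2]]
  } else {
    rhs <- ape::extract.clade(big, root_children[2])$tip.label
  }
  expect_lt(diff(range(D[lhs, rhs])), 1e-8)
})

test_that("permutation distance test: p floor, planted clades, empty groups", {
  set.seed(13)
  tr <- ape::rphylo(20, 1, 0)
  D <- pairwise_phylo_distance(tr)
  lab <- stats::setNames(rep(1:2, 10), tr$tip.label)
  r <- permutation_distance_test(D, lab, n_perm = 10, seed = 1)
  expect_gte(r$p, 1 / 11)

  # labels = two clades of the tree: strongly significant
  root_kids <- tr$edge[tr$edge[, 1] == 21, 2]
  clade <- if (root_kids[1] > 20) ape::extract.clade(tr, root_kids[1])$tip.label
           else tr$tip.label[root_kids[1]]
  lab2 <- stats::setNames(ifelse(tr$tip.label %in% clade, "in", "out"), tr$tip.label)
  if (length(unique(lab2)) == 2 && min(table(lab2)) >= 2) {
    r2 <- permutation_distance_test(D, lab2, n_perm = 999, seed = 2)
    expect_lt(r2$p, 0.05)
  }

  expect_error(permutation_distance_test(D, stats::setNames(rep(1, 20), tr$tip.label),
                                         n_perm = 9), "empty")
})
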