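#' Brownian phylogenetic covariance with Pagel's lambda transform
#'
#' C\[a, b\] is the shared root-to-tip branch length of taxa a and b (the
#' tip depth on the diagonal); the lambda transform scales the off-diagonal
#' entries by `lambda`, so `lambda = 0` gives independence and `lambda = 1`
#' the full Brownian expectation.
#'
#' @param tree an [ape::phylo].
#' @param taxa optional taxon subset (tree is pruned first).
#' @param lambda Pagel's lambda in \[0, 1\].
#' @return covariance matrix ordered by the (pruned) tree's tip labels.
#' @export
phylo_covariance <- function(tree, taxa = NULL, lambda = 1) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (!is.null(taxa)) tree <- prune_tree(tree, taxa)
  C <- ape::vcv.phylo(tree)
  if (any(diag(C) <= 0)) stop("zero-depth tips in tree")
  lambda_transform(C, lambda)
}

lambda_transform <- function(C, lambda) {
  if (lambda == 1) return(C)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Profile ML of a Gaussian phylogenetic regression: given correlation V,
# returns the GLS fit and the maximised log-likelihood (sigma^2 profiled out).
gls_profile <- function(y, X, V) {
  n <- length(y)
  U <- chol(V)
  ys <- backsolve(U, y, transpose = TRUE)
  Xs <- backsolve(U, X, transpose = TRUE)
  qr_ <- qr(Xs)
  if (qr_$rank < ncol(Xs)) stop("singular design matrix")
  beta <- qr.coef(qr_, ys)
  resid <- ys - Xs %*% beta
  rss <- sum(resid^2)
  # guard the degenerate perfect-fit case so the profile logL stays finite
  sigma2_ml <- max(rss, 1e-300) / n
  logL <- -n / 2 * log(2 * pi * sigma2_ml) - sum(log(diag(U))) - n / 2
  XtX_inv <- chol2inv(qr.R(qr_))
  list(beta = beta, rss = rss, sigma2_ml = sigma2_ml, logL = logL,
       XtX_inv = XtX_inv, n = n, p = ncol(X))
}

match_trait <- function(trait, tree) {
  if (is.null(names(trait))) stop("trait vector must be named by taxon")
  taxa <- intersect(tree$tip.label, names(trait)[!is.na(trait)])
  if (length(taxa) < 3) stop("fewer than three taxa with trait values on the tree")
  list(trait = trait[taxa], taxa = taxa)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Profile ML over lambda in \[0, 1\] of the multivariate-normal likelihood
#' with mean mu and covariance sigma^2 C(lambda), plus a likelihood-ratio
#' test against lambda = 0 (chi-square with 1 df; the boundary makes it
#' conservative). On a star phylogeny lambda is unidentifiable and the
#' function returns 0 with a flag.
#'
#' @param trait named numeric vector (names = tip labels).
#' @param tree an [ape::phylo].
#' @param tol optimizer tolerance.
#' @return list `lambda`, `sigma2`, `logL`, `logL0`, `p_lrt`,
#'   `unidentifiable`, `n`.
#' @export
pagel_lambda_ml <- function(trait, tree, tol = 1e-6) {
  m <- match_trait(trait, tree)
  if (stats::sd(m$trait) == 0) stop("constant trait: lambda is undefined")
  C <- phylo_covariance(tree, m$taxa)
  n <- length(m$trait)
  X <- matrix(1, n, 1)
  off <- C[upper.tri(C)]
  if (all(off < 1e-12 * max(diag(C)))) {
    fit <- gls_profile(m$trait, X, lambda_transform(C, 0))
    return(list(lambda = 0, sigma2 = fit$sigma2_ml, logL = fit$logL,
                logL0 = fit$logL, p_lrt = 1, unidentifiable = TRUE, n = n))
  }
  nll <- function(lam) -gls_profile(m$trait, X, lambda_transform(C, lam))$logL
  opt <- stats::optimize(nll, interval = c(0, 1), tol = tol)
  # the optimum can sit at an endpoint; compare explicitly
  cand <- c(0, opt$minimum, 1)
  vals <- vapply(cand, nll, numeric(1))
  lam <- cand[which.min(vals)]
  fit <- gls_profile(m$trait, X, lambda_transform(C, lam))
  logL0 <- -nll(0)
  lrt <- 2 * (fit$logL - logL0)
  list(lambda = lam, sigma2 = fit$sigma2_ml, logL = fit$logL, logL0 = logL0,
       p_lrt = stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
       unidentifiable = FALSE, n = n)
}

#' Phylogenetic generalized least squares
#'
#' GLS regression with error covariance sigma^2 C(lambda); lambda is
#' estimated jointly by ML (default) or fixed. The signed effect size
#' R = sign(focal slope) * sqrt(R^2_GLS) uses the V-weighted R^2 against
#' the V-weighted intercept-only model; the focal slope is the first
#' predictor column.
#'
#' @param y named numeric response (names = tip labels).
#' @param X named numeric vector, matrix or data frame of predictors (rows
#'   matched to taxa by name); an intercept is added internally.
#' @param tree an [ape::phylo].
#' @param lambda_mode `"ml"` or `"fixed"`.
#' @param lambda value used when `lambda_mode = "fixed"`.
#' @return list with the coefficient table (`estimate`, `se`, `t`, `p`),
#'   `lambda`, `R2`, `R`, `logL`, `n`, `df_residual`.
#' @export
pgls <- function(y, X, tree, lambda_mode = c("ml", "fixed"), lambda = 1) {
  lambda_mode <- match.arg(lambda_mode)
  if (is.vector(X) && !is.list(X)) X <- matrix(X, dimnames = list(names(X), "x"))
  X <- as.matrix(X)
  taxa <- Reduce(intersect, list(tree$tip.label, names(y)[!is.na(y)],
                                 rownames(X)[stats::complete.cases(X)]))
  p <- ncol(X)
  if (length(taxa) < p + 2) stop("too few complete cases for PGLS")
  yv <- y[taxa]
  Xd <- cbind(`(Intercept)` = 1, X[taxa, , drop = FALSE])
  C <- phylo_covariance(tree, taxa)
  n <- length(taxa)
  if (lambda_mode == "ml") {
    nll <- function(lam) -gls_profile(yv, Xd, lambda_transform(C, lam))$logL
    opt <- stats::optimize(nll, interval = c(0, 1), tol = 1e-6)
    cand <- c(0, opt$minimum, 1)
    lambda <- cand[which.min(vapply(cand, nll, numeric(1)))]
  }
  V <- lambda_transform(C, lambda)
  fit <- gls_profile(yv, Xd, V)
  df <- n - ncol(Xd)
  sigma2 <- fit$rss / df
  se <- sqrt(diag(fit$XtX_inv) * sigma2)
  tval <- drop(fit$beta) / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  null_fit <- gls_profile(yv, Xd[, 1, drop = FALSE], V)
  R2 <- 1 - fit$rss / null_fit$rss
  coef_tab <- data.frame(term = colnames(Xd), estimate = drop(fit$beta),
                         se = se, t = tval, p = pval, stringsAsFactors = FALSE,
                         row.names = NULL)
  list(coefficients = coef_tab, lambda = lambda, R2 = R2,
       R = sign(coef_tab$estimate[2]) * sqrt(max(R2, 0)),
       logL = fit$logL, n = n, df_residual = df)
}

oneway_F <- function(x, g) {
  g <- factor(g)
  ng <- tabulate(g)
  k <- nlevels(g)
  n <- length(x)
  gm <- tapply(x, g, mean)
  ssb <- sum(ng * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Simulation-based phylogenetic ANOVA
#'
#' One-way F statistic on the observed trait, compared to F statistics from
#' Brownian simulations of the trait on the tree (mu and sigma^2 from the
#' observed ML fit), so group differences are judged against what shared
#' ancestry alone produces. Empirical p uses the +1 correction.
#'
#' @param trait named numeric vector.
#' @param groups named group labels (>= 2 groups, each >= 2 members).
#' @param tree an [ape::phylo].
#' @param n_sim Brownian simulations (default 1000).
#' @param seed RNG seed.
#' @return list `F`, `p`, `n_sim`, `F_null`, `seed`.
#' @export
phylo_anova <- function(trait, groups, tree, n_sim = 1000L, seed = NULL) {
  if (n_sim < 1) stop("n_sim must be positive")
  m <- match_trait(trait, tree)
  g <- factor(groups[m$taxa])
  if (anyNA(g)) stop("taxa without group labels")
  if (nlevels(droplevels(g)) < 2 || any(table(droplevels(g)) < 2)) {
    stop("need at least two groups with at least two members each")
  }
  g <- droplevels(g)
  C <- phylo_covariance(tree, m$taxa)
  fit <- gls_profile(m$trait, matrix(1, length(m$taxa), 1), C)
  F_obs <- oneway_F(m$trait, g)
  L <- t(chol(C))
  mu <- drop(fit$beta)
  sig <- sqrt(fit$sigma2_ml)
  F_null <- with_seed(seed, vapply(seq_len(n_sim), function(i) {
    oneway_F(mu + sig * drop(L %*% stats::rnorm(length(m$trait))), g)
  }, numeric(1)))
  list(F = F_obs, p = (1 + sum(F_null >= F_obs)) / (1 + n_sim),
       n_sim = n_sim, F_null = F_null, seed = seed)
}

firth_logistic <- function(y, X, max_iter = 100, tol = 1e-10) {
  # Firth-penalized logistic regression via IRLS with hat-value correction
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    inv <- tryCatch(solve(XtWX), error = function(e) MASS_ginv(XtWX))
    h <- rowSums((XW %*% inv) * XW)
    score <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- inv %*% score
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(XtWX), error = function(e) MASS_ginv(XtWX))
  list(beta = beta, vcov = vcov, converged = it < max_iter, iter = it)
}

MASS_ginv <- function(M) {
  s <- svd(M)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Phylogenetic logistic regression (Firth-type)
#'
#' Binary response regressed on continuous predictors with residual
#' correlation that decays along the tree: the working correlation is
#' exp(-alpha * D) with D the patristic distance scaled to a unit maximum,
#' and alpha is chosen on a grid by the Gaussian working likelihood of the
#' IRLS pseudo-response. Large alpha means the signal decays immediately;
#' when the best alpha sits at that boundary the fit falls back to standard
#' Firth logistic regression exactly and is flagged `no_signal`. Firth's
#' hat-value correction keeps estimates finite under complete separation
#' (flagged `separation`).
#'
#' @param y named binary (0/1) response.
#' @param X named numeric vector, matrix or data frame of predictors.
#' @param tree an [ape::phylo].
#' @param alpha_grid candidate decay rates, increasing; the largest value is
#'   the no-signal boundary.
#' @return list with the coefficient table, `alpha`, `no_signal`,
#'   `separation`, `n`.
#' @export
phylo_logistic <- function(y, X, tree,
                           alpha_grid = c(0.25, 0.5, 1, 2, 4, 8, 16, Inf)) {
  if (is.vector(X) && !is.list(X)) X <- matrix(X, dimnames = list(names(X), "x"))
  X <- as.matrix(X)
  taxa <- Reduce(intersect, list(tree$tip.label, names(y)[!is.na(y)],
                                 rownames(X)[stats::complete.cases(X)]))
  if (length(taxa) < ncol(X) + 2) stop("too few complete cases")
  yv <- as.numeric(y[taxa])
  if (!all(yv %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(yv)) < 2) stop("response is constant")
  Xd <- cbind(`(Intercept)` = 1, X[taxa, , drop = FALSE])
  D <- pairwise_phylo_distance(prune_tree(tree, taxa))[taxa, taxa]
  D <- D / max(D)
  n <- length(yv)

  fit_alpha <- function(alpha) {
    if (!is.finite(alpha)) {
      f <- firth_logistic(yv, Xd)
      return(list(beta = f$beta, vcov = f$vcov, work_logL = -Inf, firth = f))
    }
    R <- exp(-alpha * D)
    Ri <- tryCatch(solve(R), error = function(e) NULL)
    if (is.null(Ri)) return(NULL)
    beta <- rep(0, ncol(Xd))
    for (it in seq_len(50)) {
      eta <- drop(Xd %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-8)
      # Firth-type hat correction on the GLM part
      XW <- Xd * sqrt(w)
      inv0 <- tryCatch(solve(crossprod(XW)), error = function(e) MASS_ginv(crossprod(XW)))
      h <- rowSums((XW %*% inv0) * XW)
      z <- eta + (yv - mu + h * (0.5 - mu)) / w
      # GLS step under working covariance W^-1/2 R W^-1/2
      A <- (sqrt(w) %o% sqrt(w)) * Ri          # = W^1/2 R^-1 W^1/2
      XtA <- crossprod(Xd, A)
      M <- XtA %*% Xd
      Minv <- tryCatch(solve(M), error = function(e) MASS_ginv(M))
      beta_new <- drop(Minv %*% (XtA %*% z))
      if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
      beta <- beta_new
    }
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (yv - mu) / w
    r <- sqrt(w) * (z - eta)
    qf <- drop(crossprod(r, Ri %*% r))
    s2 <- qf / n
    work_logL <- -n / 2 * log(s2) - 0.5 * determinant(R)$modulus
    A <- (sqrt(w) %o% sqrt(w)) * Ri
    Minv <- tryCatch(solve(crossprod(Xd, A) %*% Xd), error = function(e) NULL)
    list(beta = beta, vcov = if (is.null(Minv)) MASS_ginv(crossprod(Xd, A) %*% Xd) else Minv,
         work_logL = as.numeric(work_logL))
  }

  finite <- alpha_grid[is.finite(alpha_grid)]
  fits <- lapply(finite, fit_alpha)
  ok <- !vapply(fits, is.null, logical(1))
  best_idx <- if (any(ok)) which(ok)[which.max(vapply(fits[ok], `[[`, numeric(1), "work_logL"))] else 0L
  boundary <- best_idx == 0L || finite[best_idx] == max(finite)
  if (boundary) {
    f <- firth_logistic(yv, Xd)
    beta <- f$beta; vcov <- f$vcov; alpha <- Inf
  } else {
    beta <- fits[[best_idx]]$beta; vcov <- fits[[best_idx]]$vcov
    alpha <- finite[best_idx]
  }
  se <- sqrt(pmax(diag(vcov), 0))
  zval <- beta / se
  separation <- any(abs(drop(Xd %*% beta)) > 15)
  coef_tab <- data.frame(term = colnames(Xd), estimate = beta, se = se,
                         z = zval, p = 2 * stats::pnorm(-abs(zval)),
                         stringsAsFactors = FALSE, row.names = NULL)
  list(coefficients = coef_tab, alpha = alpha, no_signal = !is.finite(alpha),
       separation = separation, n = n)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree an [ape::phylo].
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_phylo_distance <- function(tree) {
  as.matrix(stats::cophenetic(tree))
}

welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  (mean(x) - mean(y)) / sqrt(stats::var(x) / nx + stats::var(y) / ny)
}

#' Permutation t test on grouped pairwise distances
#'
#' Splits the tip pairs of a distance matrix into two sets by node labels —
#' within-group versus between-group pairs (e.g. same module, or same
#' transmission mode) — and compares their means with a Welch t statistic.
#' The null distribution permutes the node labels (node-level
#' exchangeability) and recomputes t; the empirical two-sided p uses the +1
#' correction and is therefore at least 1/(n_perm + 1).
#'
#' @param distance_matrix symmetric distance matrix with taxon dimnames.
#' @param labels named vector of group labels covering the matrix taxa.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return list `t`, `p`, `n_perm`, `n_within`, `n_between`, `null_mean`,
#'   `null_sd`, `seed`.
#' @export
permutation_distance_test <- function(distance_matrix, labels, n_perm = 10000L,
                                      seed = NULL) {
  if (n_perm < 1) stop("n_perm must be positive")
  taxa <- rownames(distance_matrix)
  lab <- labels[taxa]
  if (anyNA(lab)) stop("labels missing for: ", paste(taxa[is.na(lab)], collapse = ", "))
  ut <- which(upper.tri(distance_matrix), arr.ind = TRUE)
  d <- distance_matrix[upper.tri(distance_matrix)]
  t_for <- function(lab) {
    same <- lab[ut[, 1]] == lab[ut[, 2]]
    if (!any(same) || all(same)) return(NA_real_)
    welch_t(d[same], d[!same])
  }
  t_obs <- t_for(lab)
  if (is.na(t_obs)) stop("a pair set (within or between) is empty")
  t_null <- with_seed(seed, vapply(seq_len(n_perm),
                                   function(i) t_for(sample(lab)), numeric(1)))
  t_null <- t_null[!is.na(t_null)]
  p <- (1 + sum(abs(t_null) >= abs(t_obs))) / (1 + length(t_null))
  same <- lab[ut[, 1]] == lab[ut[, 2]]
  list(t = t_obs, p = p, n_perm = n_perm,
       n_within = sum(same), n_between = sum(!same),
       null_mean = mean(t_null), null_sd = stats::sd(t_null), seed = seed)
}
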