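#' Specification for a synthetic coral-symbiont dataset
#'
#' Defaults emulate the scale and shape of the global coral-Symbiodiniaceae
#' compilation this package targets: 152 corals, 385 phylotypes, ~16,000
#' association records spread very unevenly across hosts, a heavy-tailed
#' phylotype degree distribution with a few generalists, seven planted
#' modules partially aligned with transmission mode, ~30% vertically
#' transmitting corals, thermotolerance known only for the commonest ~19%
#' of phylotypes, and Brownian traits with substantial phylogenetic signal.
#'
#' @param n_corals,n_phylotypes taxon pool sizes.
#' @param target_total_records total association records aimed for.
#' @param n_modules planted modules.
#' @param mu mixing: fraction of a coral's record mass placed outside its
#'   module (0 = perfectly block-diagonal, 1 = no module signal).
#' @param frac_vt fraction of vertically transmitting corals.
#' @param align probability a coral's transmission mode follows its module's
#'   designation rather than an independent coin flip.
#' @param tail_exponent Pareto tail exponent of phylotype attractiveness
#'   (smaller = heavier tail, more extreme generalists).
#' @param attract_cap cap on the attractiveness ratio.
#' @param dirichlet_conc total Dirichlet concentration of each coral's
#'   phylotype frequencies; small values give specialised, variable
#'   assemblages (and hence variable d').
#' @param records_sdlog log-normal sd of per-coral record totals.
#' @param min_records floor on per-coral records.
#' @param sigma2_bri,lambda_bri,sigma2_tt,lambda_tt Brownian rate and
#'   Pagel's lambda of the latent bleaching-response and thermotolerance
#'   traits (lambda acts on the latent scale; the map to \[0,100\] is
#'   affine).
#' @param tt_known_frac fraction of phylotypes (the most recorded ones)
#'   with a known TT score.
#' @param vt_bri_richness_effect planted slope (latent-trait SDs per SD of
#'   log assemblage richness) added to the BRI of VT corals only; 0 plants
#'   no effect.
#' @param n_variants,n_variant_ancestors size of the planted intragenomic
#'   variant map used by the metahaplotype sensitivity analysis.
#' @param seed default RNG seed for [simulate_network()].
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_corals = 152L, n_phylotypes = 385L,
                           target_total_records = 16000L, n_modules = 7L,
                           mu = 0.25, frac_vt = 0.3, align = 0.8,
                           tail_exponent = 2.0, attract_cap = 100,
                           dirichlet_conc = 3, records_sdlog = 1.0,
                           min_records = 10L,
                           sigma2_bri = 1, lambda_bri = 0.7,
                           sigma2_tt = 1, lambda_tt = 0.7,
                           tt_known_frac = 0.19,
                           vt_bri_richness_effect = 0,
                           n_variants = 30L, n_variant_ancestors = 6L,
                           seed = 1L) {
  stopifnot(mu >= 0, mu <= 1, lambda_bri >= 0, lambda_bri <= 1,
            lambda_tt >= 0, lambda_tt <= 1,
            n_corals >= 2, n_phylotypes >= 2, target_total_records > 0,
            n_modules >= 1, tail_exponent > 1, is.finite(sigma2_bri),
            is.finite(sigma2_tt))
  if (n_modules > n_corals || n_modules > n_phylotypes) {
    stop("more modules than corals or phylotypes")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Simulate Yule phylogenies for corals and phylotypes
#'
#' Pure-birth trees with the requested tip counts; tips are labelled
#' `coral_###` / `phy_###` to match the taxa of [simulate_network()].
#'
#' @param n_corals,n_phylotypes tip counts (>= 2).
#' @param seed RNG seed.
#' @return list `coral_tree`, `symbiont_tree`.
#' @export
simulate_trees <- function(n_corals, n_phylotypes, seed = NULL) {
  stopifnot(n_corals >= 2, n_phylotypes >= 2)
  with_seed(seed, {
    ct <- ape::rphylo(n_corals, birth = 1, death = 0)
    st <- ape::rphylo(n_phylotypes, birth = 1, death = 0)
    ct$tip.label <- sprintf("coral_%03d", seq_len(n_corals))
    st$tip.label <- sprintf("phy_%03d", seq_len(n_phylotypes))
    list(coral_tree = ct, symbiont_tree = st)
  })
}

#' Simulate a trait with tunable phylogenetic signal
#'
#' One draw from a multivariate normal with covariance sigma^2 C(lambda)
#' (off-diagonal shared branch lengths scaled by lambda), optionally mapped
#' affinely onto `bounds`. With `bounds = NULL` the latent Brownian-scale
#' values are returned; the bounded values carry the latent draw in the
#' `latent` attribute.
#'
#' @param tree an [ape::phylo].
#' @param sigma2 Brownian rate.
#' @param lambda Pagel's lambda in \[0, 1\].
#' @param bounds length-2 numeric or NULL.
#' @param seed RNG seed.
#' @return named numeric vector over the tips.
#' @export
simulate_traits <- function(tree, sigma2 = 1, lambda = 1, bounds = c(0, 100),
                            seed = NULL) {
  stopifnot(is.finite(sigma2), sigma2 >= 0, lambda >= 0, lambda <= 1)
  C <- phylo_covariance(tree, lambda = lambda)
  L <- t(chol(C + diag(1e-10, nrow(C))))
  z <- with_seed(seed, stats::rnorm(nrow(C)))
  latent <- stats::setNames(sqrt(sigma2) * drop(L %*% z), tree$tip.label)
  if (is.null(bounds)) return(latent)
  rng <- range(latent)
  scaled <- if (diff(rng) == 0) rep(mean(bounds), length(latent)) else
    (latent - rng[1]) / diff(rng) * diff(bounds) + bounds[1]
  structure(stats::setNames(scaled, tree$tip.label), latent = latent)
}

#' Simulate a complete dataset with planted structure
#'
#' Corals and phylotypes are assigned to planted modules; transmission mode
#' follows the module designation with probability `align`; phylotype
#' "attractiveness" is Pareto-tailed so a few generalists dominate;
#' per-coral record totals are log-normal; and each coral's phylotype
#' frequencies are Dirichlet-multinomial with mass `1 - mu` inside its own
#' module. BRI and TT evolve on the simulated trees with the requested
#' Pagel's lambda, and an optional richness effect on BRI is planted in VT
#' corals only. The planted partition, the variant map and the latent traits
#' are returned for ground-truth scoring and are never used by the analysis
#' stages.
#'
#' @param spec a [synthetic_spec()].
#' @param trees optional list `coral_tree`/`symbiont_tree` (simulated when
#'   NULL).
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return list `interactions`, `coral_traits`, `symbiont_traits`,
#'   `coral_tree`, `symbiont_tree`, `planted` (module labels), and
#'   `variant_map`.
#' @export
simulate_network <- function(spec = synthetic_spec(), trees = NULL,
                             seed = spec$seed) {
  sds <- derive_seeds(seed, 8)
  if (is.null(trees)) trees <- simulate_trees(spec$n_corals, spec$n_phylotypes, sds[1])
  nc <- spec$n_corals; np <- spec$n_phylotypes; k <- spec$n_modules
  corals <- trees$coral_tree$tip.label
  phylos <- trees$symbiont_tree$tip.label

  st <- with_seed(sds[2], {
    coral_mod <- sample(rep(seq_len(k), length.out = nc))
    phylo_mod <- sample(rep(seq_len(k), length.out = np))
    vt_modules <- seq_len(max(1L, round(k * spec$frac_vt)))
    aligned <- stats::runif(nc) < spec$align
    mode <- ifelse(aligned,
                   ifelse(coral_mod %in% vt_modules, "VT", "HT"),
                   ifelse(stats::runif(nc) < spec$frac_vt, "VT", "HT"))
    ocean_mod <- coral_mod <= ceiling(k / 2)
    ocean <- ifelse(stats::runif(nc) < 0.7,
                    ifelse(ocean_mod, "Atlantic", "Indo-Pacific"),
                    sample(c("Atlantic", "Indo-Pacific"), nc, replace = TRUE))
    life <- sample(c("competitive", "weedy", "stress-tolerant", "generalist"),
                   nc, replace = TRUE)
    attract <- pmin((1 - stats::runif(np))^(-1 / (spec$tail_exponent - 1)),
                    spec$attract_cap)
    raw <- stats::rlnorm(nc, 0, spec$records_sdlog)
    n_rec <- pmax(spec$min_records,
                  round(spec$target_total_records * raw / sum(raw)))
    list(coral_mod = coral_mod, phylo_mod = phylo_mod, mode = mode,
         ocean = ocean, life = life, attract = attract, n_rec = n_rec)
  })

  counts <- with_seed(sds[3], {
    # a coral's records split (1 - mu)/mu between its own module and the
    # rest; within each side, frequencies are Dirichlet-multinomial with
    # concentration proportional to phylotype attractiveness
    dirmult_draw <- function(n, shapes) {
      if (n == 0 || !length(shapes)) return(integer(length(shapes)))
      g <- stats::rgamma(length(shapes), shape = shapes)
      probs <- if (sum(g) > 0) g / sum(g) else shapes / sum(shapes)
      drop(stats::rmultinom(1, n, probs))
    }
    # every phylotype is anchored to a primary host inside its module with
    # 1-2 seeded records: a phylotype enters a compiled dataset only because
    # it was recorded in at least one host, so all of the pool is observed
    primary_host <- vapply(seq_len(np), function(j) {
      cands <- which(st$coral_mod == st$phylo_mod[j])
      if (!length(cands)) sample.int(nc, 1) else cands[sample.int(length(cands), 1)]
    }, integer(1))
    seed_cnt <- sample(1:2, np, replace = TRUE)
    seeded <- matrix(0, nc, np)
    seeded[cbind(primary_host, seq_len(np))] <- seed_cnt
    lst <- vector("list", nc)
    for (i in seq_len(nc)) {
      inm <- which(st$phylo_mod == st$coral_mod[i])
      outm <- which(st$phylo_mod != st$coral_mod[i])
      n_free <- max(0L, st$n_rec[i] - sum(seeded[i, ]))
      n_out <- if (length(outm)) stats::rbinom(1, n_free, spec$mu) else 0L
      if (!length(inm)) n_out <- n_free
      cnt <- seeded[i, ]
      cnt[inm] <- cnt[inm] +
        dirmult_draw(n_free - n_out,
                     spec$dirichlet_conc * st$attract[inm] / sum(st$attract[inm]))
      # leakage is diffuse: plain multinomial by attractiveness, so the
      # planted phylotype labels stay consistent with the generated records
      if (n_out > 0) {
        cnt[outm] <- cnt[outm] +
          drop(stats::rmultinom(1, n_out, st$attract[outm] / sum(st$attract[outm])))
      }
      nz <- which(cnt > 0)
      lst[[i]] <- data.frame(coral = corals[i], phylotype = phylos[nz],
                             count = cnt[nz], stringsAsFactors = FALSE)
    }
    do.call(rbind, lst)
  })
  interactions <- interaction_table(counts$coral, counts$phylotype, counts$count)

  # planted VT-only richness effect enters the latent BRI before bounding
  latent_bri <- simulate_traits(trees$coral_tree, spec$sigma2_bri,
                                spec$lambda_bri, bounds = NULL, seed = sds[4])
  if (spec$vt_bri_richness_effect != 0) {
    # tie the planted effect to rarefied richness at depth 10: the quantity
    # the analysis measures (raw richness mostly reflects sampling effort)
    cnts <- split(interactions$count, interactions$coral)
    rich <- vapply(cnts, rarefied_richness, numeric(1), depth = 10L)
    rich[is.na(rich)] <- 1
    zrich <- (rich - mean(rich)) / stats::sd(rich)
    vt <- st$mode[match(names(latent_bri), corals)] == "VT"
    latent_bri[vt] <- latent_bri[vt] +
      spec$vt_bri_richness_effect * sqrt(spec$sigma2_bri) *
      zrich[names(latent_bri)[vt]]
  }
  rng <- range(latent_bri)
  bri <- (latent_bri - rng[1]) / diff(rng) * 100

  tt_all <- simulate_traits(trees$symbiont_tree, spec$sigma2_tt,
                            spec$lambda_tt, bounds = c(0, 100), seed = sds[5])
  rec_by_phy <- stats::setNames(numeric(np), phylos)
  agg <- tapply(interactions$count, interactions$phylotype, sum)
  rec_by_phy[names(agg)] <- agg
  n_known <- max(2L, round(spec$tt_known_frac * np))
  known <- names(sort(rec_by_phy, decreasing = TRUE))[seq_len(n_known)]
  tt <- ifelse(phylos %in% known, tt_all[phylos], NA_real_)

  # phylotype ocean occurrence follows its hosts
  host_ocean <- split(st$ocean[match(interactions$coral, corals)],
                      interactions$phylotype)
  occ <- vapply(phylos, function(p) {
    o <- unique(host_ocean[[p]])
    if (is.null(o)) NA_character_ else if (length(o) > 1) "both" else o
  }, character(1))

  coral_tr <- coral_traits(data.frame(
    coral = corals, transmission_mode = st$mode, ocean = st$ocean,
    life_history = st$life, taxon_BRI = as.numeric(bri),
    stringsAsFactors = FALSE))
  symb_tr <- symbiont_traits(data.frame(
    phylotype = phylos, TT = as.numeric(tt), ocean_occurrence = occ,
    stringsAsFactors = FALSE))

  variant_map <- with_seed(sds[6], {
    observed <- names(rec_by_phy)[rec_by_phy > 0]
    anc <- names(sort(rec_by_phy, decreasing = TRUE))[seq_len(min(spec$n_variant_ancestors, length(observed)))]
    rare <- setdiff(observed[rec_by_phy[observed] <= stats::quantile(rec_by_phy[observed], 0.5)], anc)
    nv <- min(spec$n_variants, length(rare))
    if (nv > 0) {
      data.frame(variant = sample(rare, nv),
                 ancestor = sample(anc, nv, replace = TRUE),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variant = character(), ancestor = character(),
                 stringsAsFactors = FALSE)
    }
  })

  list(interactions = interactions, coral_traits = coral_tr,
       symbiont_traits = symb_tr, coral_tree = trees$coral_tree,
       symbiont_tree = trees$symbiont_tree,
       planted = list(coral_modules = stats::setNames(st$coral_mod, corals),
                      phylotype_modules = stats::setNames(st$phylo_mod, phylos)),
       variant_map = variant_map, spec = spec, seed = seed)
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the file formats the readers consume (CSV tables, Newick
#' trees, YAML spec) plus the planted truth as a separate JSON that no
#' analysis stage reads.
#'
#' @param sim result of [simulate_network()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_interactions(sim$interactions, file.path(dir, "interactions.csv"))
  write_traits(sim$coral_traits, file.path(dir, "coral_traits.csv"))
  write_traits(sim$symbiont_traits, file.path(dir, "symbiont_traits.csv"))
  ape::write.tree(sim$coral_tree, file.path(dir, "coral_tree.nwk"))
  ape::write.tree(sim$symbiont_tree, file.path(dir, "symbiont_tree.nwk"))
  utils::write.csv(sim$variant_map, file.path(dir, "variant_map.csv"),
                   row.names = FALSE)
  spec <- sim$spec
  class(spec) <- NULL
  yaml::write_yaml(spec, file.path(dir, "spec.yml"))
  jsonlite::write_json(list(coral_modules = as.list(sim$planted$coral_modules),
                            phylotype_modules = as.list(sim$planted$phylotype_modules),
                            seed = sim$seed),
                       file.path(dir, "planted_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
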