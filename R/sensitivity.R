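#' Validate an intragenomic-variant map
#'
#' The map assigns putative intragenomic variants (IGVs) to ancestral
#' phylotypes. No variant may map to two ancestors and no ancestor may
#' itself be listed as a variant.
#'
#' @param map data frame with columns `variant`, `ancestor`.
#' @return the normalised map.
#' @export
variant_map <- function(map) {
  stopifnot(all(c("variant", "ancestor") %in% names(map)))
  map$variant <- normalize_label(map$variant)
  map$ancestor <- normalize_label(map$ancestor)
  dup <- map$variant[duplicated(map$variant)]
  if (length(dup)) stop("variant mapped to two ancestors: ", paste(unique(dup), collapse = ", "))
  bad <- intersect(map$variant, map$ancestor)
  if (length(bad)) stop("taxa listed as both variant and ancestor: ", paste(bad, collapse = ", "))
  map
}

#' Collapse intragenomic variants into host-specific metahaplotypes
#'
#' Within each coral, a variant co-occurring with its ancestral phylotype is
#' merged with the ancestor's records into a host-specific node named
#' `"<ancestor>@<coral>"`. A variant's records in hosts where the ancestor
#' is absent are dropped (set `keep_lone_variants = TRUE` to keep them as
#' ordinary nodes instead); variants never observed co-occurring with their
#' ancestor in any host are thereby eliminated entirely. With the default
#' rule the operation is idempotent. The report counts merged and dropped
#' associations and the fraction of unique associations removed.
#'
#' @param interactions an `interaction_table`.
#' @param map a variant-to-ancestor map (see [variant_map()]).
#' @param keep_lone_variants keep a variant's records in hosts without the
#'   ancestor (default FALSE drops them).
#' @return list `interactions` (collapsed table), `report`.
#' @export
metahaplotype_collapse <- function(interactions, map, keep_lone_variants = FALSE) {
  map <- variant_map(map)
  df <- as.data.frame(interactions)
  if (!nrow(map)) {
    return(list(interactions = interactions,
                report = list(n_merged = 0L, n_eliminated_variants = 0L,
                              n_dropped_pairs = 0L, frac_associations_removed = 0)))
  }
  anc_of <- stats::setNames(map$ancestor, map$variant)
  is_var <- df$phylotype %in% map$variant
  # does this variant co-occur with its ancestor in this coral?
  key <- paste(df$coral, df$phylotype, sep = "\r")
  cooc <- is_var &
    paste(df$coral, anc_of[df$phylotype], sep = "\r") %in% key
  drop_var <- if (keep_lone_variants) {
    # keep lone occurrences of variants that co-occur somewhere; eliminate
    # variants with no ancestral co-occurrence at all
    is_var & !cooc & !(df$phylotype %in% unique(df$phylotype[cooc]))
  } else {
    is_var & !cooc
  }
  # ancestor rows absorbed into a metahaplotype in that coral
  anc_merged <- df$phylotype %in% map$ancestor &
    paste(df$coral, df$phylotype) %in%
      paste(df$coral, anc_of[df$phylotype])[cooc]
  out <- df[!drop_var, , drop = FALSE]
  cooc_out <- cooc[!drop_var]
  anc_out <- anc_merged[!drop_var]
  new_phy <- out$phylotype
  new_phy[cooc_out] <- paste0(anc_of[out$phylotype[cooc_out]], "@", out$coral[cooc_out])
  new_phy[anc_out] <- paste0(out$phylotype[anc_out], "@", out$coral[anc_out])
  collapsed <- interaction_table(out$coral, new_phy, out$count)
  report <- list(
    n_merged = sum(cooc),
    n_eliminated_variants = length(setdiff(unique(df$phylotype[is_var]),
                                           unique(df$phylotype[cooc]))),
    n_dropped_pairs = sum(drop_var),
    frac_associations_removed = 1 - nrow(collapsed) / nrow(df)
  )
  list(interactions = collapsed, report = report)
}

#' Per-coral sampling intensity
#'
#' Number of association records for each coral.
#'
#' @param interactions an `interaction_table`.
#' @return named integer vector.
#' @export
sampling_intensity <- function(interactions) {
  v <- tapply(interactions$count, interactions$coral, sum)
  stats::setNames(as.integer(v), names(v))
}

#' Regress an assemblage metric on sampling intensity
#'
#' PGLS of the metric on (log) record count, used to check that assemblage
#' metrics are not artefacts of unequal sampling across coral species.
#'
#' @param metric named numeric vector over corals.
#' @param intensity named record counts (e.g. [sampling_intensity()]).
#' @param tree coral phylogeny.
#' @param log_intensity regress on log10 records (default TRUE).
#' @param ... passed to [pgls()].
#' @return a [pgls()] result.
#' @export
regress_metric_on_intensity <- function(metric, intensity, tree,
                                        log_intensity = TRUE, ...) {
  x <- if (log_intensity) log10(intensity) else intensity
  pgls(metric, stats::setNames(as.numeric(x), names(intensity)), tree, ...)
}

#' Coral subsets by minimum record depth
#'
#' `subset_k` keeps the corals with at least k records, so downstream
#' analyses can be re-run on increasingly well-sampled species sets.
#'
#' @param interactions an `interaction_table`.
#' @param depths increasing integer depths (default 10, 15, 20).
#' @return named list of `interaction_table`s, one per depth, with an
#'   attribute `n_corals` giving the per-depth coral counts.
#' @export
depth_subsets <- function(interactions, depths = c(10L, 15L, 20L)) {
  stopifnot(!is.unsorted(depths, strictly = TRUE))
  n <- sampling_intensity(interactions)
  out <- lapply(depths, function(d) {
    keep <- names(n)[n >= d]
    if (!length(keep)) stop("no corals with at least ", d, " records")
    sub <- interactions[interactions$coral %in% keep, , drop = FALSE]
    structure(sub, class = c("interaction_table", "data.frame"))
  })
  names(out) <- paste0("RD", depths)
  attr(out, "n_corals") <- vapply(out, function(s) length(unique(s$coral)), integer(1))
  out
}
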