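#' @title Reading and validating interaction records, traits, and trees
#' @name symbionet-io
#' @details
#' Tables are CSV or TSV (RFC-4180 quoting, delimiter chosen by file
#' extension with a comma fallback). Taxon labels are normalised at read
#' time: leading/trailing whitespace trimmed and internal runs collapsed to
#' a single space, because real datasets mix genus names ("Cladocopium C3")
#' and codes ("D1-4"). Missing trait values stay missing; nothing is
#' imputed.
NULL

normalize_label <- function(x) {
  gsub("[[:space:]]+", " ", trimws(as.character(x)))
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE, na.strings = c("NA", ""))
  if (ncol(df) == 1L && sep == ",") {
    df <- utils::read.csv(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  }
  df
}

find_col <- function(df, candidates, what, required = TRUE) {
  hit <- which(tolower(names(df)) %in% candidates)
  if (!length(hit)) {
    if (required) stop("no column for ", what, " (looked for: ",
                       paste(candidates, collapse = ", "), ")")
    return(NA_integer_)
  }
  hit[1L]
}

#' Build an interaction table from coral/phylotype/count vectors
#'
#' One row per (coral, phylotype) pair with a positive integer count of
#' association records; duplicate pairs are summed.
#'
#' @param coral,phylotype character vectors of taxon labels.
#' @param count positive integer record counts (default 1 per row).
#' @return an `interaction_table` data frame with columns `coral`,
#'   `phylotype`, `count`.
#' @export
interaction_table <- function(coral, phylotype, count = rep(1L, length(coral))) {
  coral <- normalize_label(coral)
  phylotype <- normalize_label(phylotype)
  if (length(coral) != length(phylotype) || length(coral) != length(count)) {
    stop("coral, phylotype and count must have equal length")
  }
  if (!length(coral)) stop("empty interaction table")
  bad <- which(!is.finite(count) | count < 1 | count != round(count))
  if (length(bad)) {
    stop("nonpositive or non-integer counts at rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  agg <- stats::aggregate(list(count = as.integer(count)),
                          by = list(coral = coral, phylotype = phylotype), FUN = sum)
  agg <- agg[order(agg$coral, agg$phylotype), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("interaction_table", "data.frame"))
}

#' Read interaction records from CSV/TSV
#'
#' Expects header columns naming the coral, the phylotype and (optionally)
#' the count; without a count column each row is one record and duplicate
#' rows accumulate.
#'
#' @param path file path.
#' @return an `interaction_table`.
#' @export
read_interactions <- function(path) {
  df <- read_delim_auto(path)
  if (!nrow(df)) stop("empty interaction table: ", path)
  ci <- find_col(df, c("coral", "coral_id", "coral_species", "host"), "coral")
  pi_ <- find_col(df, c("phylotype", "phylotype_id", "symbiont", "symbiont_id"),
                  "phylotype")
  ki <- find_col(df, c("count", "records", "n_records"), "count", required = FALSE)
  cnt <- if (is.na(ki)) rep(1L, nrow(df)) else {
    v <- suppressWarnings(as.numeric(df[[ki]]))
    bad <- which(!is.finite(v) | v < 1 | v != round(v))
    if (length(bad)) {
      stop("malformed counts in ", path, " at data rows: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    as.integer(v)
  }
  miss <- which(is.na(df[[ci]]) | is.na(df[[pi_]]))
  if (length(miss)) {
    stop("missing coral/phylotype label in ", path, " at data rows: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  interaction_table(df[[ci]], df[[pi_]], cnt)
}

#' @rdname read_interactions
#' @param x an `interaction_table`.
#' @export
write_interactions <- function(x, path) {
  stopifnot(inherits(x, "interaction_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Total number of association records in a table
#' @param x an `interaction_table`.
#' @export
total_records <- function(x) sum(x$count)

coral_levels <- list(
  transmission_mode = c("HT", "VT"),
  ocean = c("Atlantic", "Indo-Pacific"),
  life_history = c("competitive", "weedy", "stress-tolerant", "generalist")
)

#' Read a coral or symbiont trait table
#'
#' Coral tables carry `transmission_mode` (HT/VT), `ocean`
#' (Atlantic/Indo-Pacific), `life_history` (competitive/weedy/
#' stress-tolerant/generalist) and an optional bleaching response index
#' `taxon_BRI` in \[0,100\]. Symbiont tables carry an optional
#' thermotolerance percentile `TT` in \[0,100\] and `ocean_occurrence`
#' (Atlantic/Indo-Pacific/both). Unknown categorical levels, duplicate taxa
#' and out-of-range scores are rejected.
#'
#' @param path file path (CSV/TSV).
#' @param kind `"coral"` or `"symbiont"`.
#' @return a data frame of class `coral_traits` or `symbiont_traits`.
#' @export
read_traits <- function(path, kind = c("coral", "symbiont")) {
  kind <- match.arg(kind)
  df <- read_delim_auto(path)
  if (kind == "coral") {
    ci <- find_col(df, c("coral", "coral_id", "coral_species"), "coral")
    out <- data.frame(
      coral = normalize_label(df[[ci]]),
      transmission_mode = normalize_label(df[[find_col(df, "transmission_mode", "transmission_mode")]]),
      ocean = normalize_label(df[[find_col(df, "ocean", "ocean")]]),
      life_history = normalize_label(df[[find_col(df, "life_history", "life_history")]]),
      taxon_BRI = {
        i <- find_col(df, c("taxon_bri", "bri"), "taxon_BRI", required = FALSE)
        if (is.na(i)) rep(NA_real_, nrow(df)) else as.numeric(df[[i]])
      },
      stringsAsFactors = FALSE
    )
    coral_traits(out)
  } else {
    pi_ <- find_col(df, c("phylotype", "phylotype_id", "symbiont"), "phylotype")
    out <- data.frame(
      phylotype = normalize_label(df[[pi_]]),
      TT = {
        i <- find_col(df, "tt", "TT", required = FALSE)
        if (is.na(i)) rep(NA_real_, nrow(df)) else as.numeric(df[[i]])
      },
      ocean_occurrence = {
        i <- find_col(df, "ocean_occurrence", "ocean_occurrence", required = FALSE)
        if (is.na(i)) rep(NA_character_, nrow(df)) else normalize_label(df[[i]])
      },
      stringsAsFactors = FALSE
    )
    symbiont_traits(out)
  }
}

#' @rdname read_traits
#' @param df data frame with columns `coral`, `transmission_mode`, `ocean`,
#'   `life_history`, `taxon_BRI`.
#' @export
coral_traits <- function(df) {
  stopifnot(all(c("coral", "transmission_mode", "ocean", "life_history") %in% names(df)))
  if (is.null(df$taxon_BRI)) df$taxon_BRI <- NA_real_
  df$coral <- normalize_label(df$coral)
  dup <- df$coral[duplicated(df$coral)]
  if (length(dup)) stop("duplicate coral ids: ", paste(unique(dup), collapse = ", "))
  for (fld in names(coral_levels)) {
    bad <- setdiff(stats::na.omit(unique(df[[fld]])), coral_levels[[fld]])
    if (length(bad)) stop("unknown ", fld, " level(s): ", paste(bad, collapse = ", "))
  }
  out_of_range <- which(!is.na(df$taxon_BRI) & (df$taxon_BRI < 0 | df$taxon_BRI > 100))
  if (length(out_of_range)) {
    stop("taxon_BRI outside [0,100] for: ",
         paste(df$coral[out_of_range], collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, class = c("coral_traits", "data.frame"))
}

#' @rdname read_traits
#' @export
symbiont_traits <- function(df) {
  stopifnot("phylotype" %in% names(df))
  if (is.null(df$TT)) df$TT <- NA_real_
  if (is.null(df$ocean_occurrence)) df$ocean_occurrence <- NA_character_
  df$phylotype <- normalize_label(df$phylotype)
  dup <- df$phylotype[duplicated(df$phylotype)]
  if (length(dup)) stop("duplicate phylotype ids: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(stats::na.omit(unique(df$ocean_occurrence)),
                 c("Atlantic", "Indo-Pacific", "both"))
  if (length(bad)) stop("unknown ocean_occurrence level(s): ", paste(bad, collapse = ", "))
  out_of_range <- which(!is.na(df$TT) & (df$TT < 0 | df$TT > 100))
  if (length(out_of_range)) {
    stop("TT outside [0,100] for: ", paste(df$phylotype[out_of_range], collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, class = c("symbiont_traits", "data.frame"))
}

#' @rdname read_traits
#' @param x a traits table.
#' @export
write_traits <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' @param path Newick file.
#' @return an [ape::phylo] tree; tip labels are normalised like table labels.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick tree: ", path)
  tr$tip.label <- normalize_label(tr$tip.label)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels in ", path)
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch lengths in ", path)
  }
  tr
}

#' Prune a tree to a taxon set
#'
#' Retains only the requested tips; unary nodes created by pruning are
#' collapsed with their branch lengths summed, so pairwise tip-to-tip path
#' lengths among retained tips are preserved.
#'
#' @param tree an [ape::phylo].
#' @param taxa tip labels to keep.
#' @export
prune_tree <- function(tree, taxa) {
  taxa <- unique(normalize_label(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  }
  if (length(taxa) < 2L) stop("need at least two taxa to keep a tree")
  ape::keep.tip(tree, taxa)
}

#' Cross-validate a complete dataset
#'
#' Cross-references the taxon sets of the interaction table, both trait
#' tables and both trees, and returns a report listing taxa that lack
#' traits, tree tips, BRI or TT scores. Nothing fails here; stages that
#' require tree coverage raise their own errors.
#'
#' @param interactions an `interaction_table`.
#' @param coral_traits,symbiont_traits trait tables (or NULL).
#' @param coral_tree,symbiont_tree [ape::phylo] trees (or NULL).
#' @return a `symbionet_validation` object: a data frame of issues with
#'   columns `level`, `category`, `taxon`.
#' @export
validate_dataset <- function(interactions, coral_traits = NULL,
                             symbiont_traits = NULL, coral_tree = NULL,
                             symbiont_tree = NULL) {
  corals <- sort(unique(interactions$coral))
  phylos <- sort(unique(interactions$phylotype))
  issues <- list()
  add <- function(level, category, taxa) {
    if (length(taxa)) {
      issues[[length(issues) + 1L]] <<- data.frame(
        level = level, category = category, taxon = taxa,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(coral_traits)) {
    add("warning", "coral_missing_traits", setdiff(corals, coral_traits$coral))
    with_bri <- coral_traits$coral[!is.na(coral_traits$taxon_BRI)]
    add("note", "excluded_from_BRI_analyses", setdiff(corals, with_bri))
  }
  if (!is.null(symbiont_traits)) {
    add("warning", "phylotype_missing_traits", setdiff(phylos, symbiont_traits$phylotype))
    with_tt <- symbiont_traits$phylotype[!is.na(symbiont_traits$TT)]
    add("note", "excluded_from_TT_analyses", setdiff(phylos, with_tt))
  }
  if (!is.null(coral_tree)) {
    add("warning", "coral_missing_from_tree", setdiff(corals, coral_tree$tip.label))
  }
  if (!is.null(symbiont_tree)) {
    add("warning", "phylotype_missing_from_tree", setdiff(phylos, symbiont_tree$tip.label))
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(level = character(), category = character(), taxon = character(),
               stringsAsFactors = FALSE)
  structure(out, class = c("symbionet_validation", "data.frame"),
            n_corals = length(corals), n_phylotypes = length(phylos))
}

#' @export
print.symbionet_validation <- function(x, ...) {
  cat(sprintf("dataset: %d corals, %d phylotypes\n",
              attr(x, "n_corals"), attr(x, "n_phylotypes")))
  if (!nrow(x)) {
    cat("no issues found\n")
  } else {
    tab <- table(x$category)
    for (nm in names(tab)) cat(sprintf("  %-32s %d taxa\n", nm, tab[[nm]]))
  }
  invisible(x)
}
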