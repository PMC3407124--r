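# Monophyly-based grouping effectiveness.
#
# "Grouped" is formalized on the unrooted tree: a leaf set forms a group iff
# removing a single edge bipartitions the leaves into exactly that set and its
# complement (a clade under some rooting). Both metrics are therefore
# invariant to rerooting.

# canonical key of a tip subset: the side not containing tip 1
.bip_key <- function(members, n) {
  if (members[1L] == 1L) members <- setdiff(seq_len(n), members)
  paste(members, collapse = ",")
}

#' Edge bipartitions of an unrooted tree
#'
#' One canonical key per edge (the tip set on the child side, complemented so
#' that tip 1 is never in the stored side). Used by [is_cluster()]; exposed so
#' that many group queries can share one traversal.
#'
#' @param tree an [ape::phylo] object.
#' @return environment mapping bipartition keys to `TRUE`.
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  tipsets <- vector("list", nn)
  tipsets[seq_len(n)] <- as.list(seq_len(n))
  edge <- tree$edge
  # postorder over edges: process children before parents
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1L]; ch <- po[e, 2L]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }
  env <- new.env(parent = emptyenv(), size = nrow(edge))
  for (e in seq_len(nrow(edge))) {
    members <- sort(unlist(tipsets[[edge[e, 2L]]], use.names = FALSE))
    assign(.bip_key(members, n), TRUE, envir = env)
  }
  env
}

#' Does a leaf set form an exclusive cluster?
#'
#' `TRUE` iff some edge of the unrooted tree separates exactly `leafset` from
#' all other leaves. Singletons and the full leaf set are trivially clusters.
#'
#' @param tree an [ape::phylo] object.
#' @param leafset character vector of tip labels.
#' @param bip optional precomputed [tree_bipartitions()] index.
#' @return logical flag.
#' @export
is_cluster <- function(tree, leafset, bip = NULL) {
  stopifnot(inherits(tree, "phylo"))
  idx <- match(leafset, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown leaf label(s): ",
         paste(leafset[is.na(idx)], collapse = ", "))
  }
  if (!length(idx)) stop("empty leaf set")
  n <- length(tree$tip.label)
  idx <- sort(unique(idx))
  if (length(idx) <= 1L || length(idx) >= n) return(TRUE)
  if (is.null(bip)) bip <- tree_bipartitions(tree)
  exists(.bip_key(idx, n), envir = bip, inherits = FALSE)
}

#' Grouping-effectiveness report for a tree
#'
#' Scores how well the tree groups sequences by taxonomy, with two metrics:
#'
#' * **sequence level** — denominator `N1` counts the leaves whose genus has
#'   at least two species in the dataset or whose species has at least two
#'   sequences. A leaf succeeds when every applicable condition holds: if its
#'   genus has >= 2 species, all sequences of that genus form an exclusive
#'   cluster; and if its species has >= 2 sequences, that species' sequences
#'   form an exclusive cluster (`semantics = "or"` gives the lenient reading:
#'   either applicable condition suffices). `pct_sequences = 100 *
#'   successes / N1`.
#' * **species level** — denominator `N2` counts species with >= 2 sequences;
#'   such a species succeeds when its sequences form an exclusive cluster.
#'   `pct_species = 100 * successes / N2`.
#'
#' Singleton sequences (only species of their genus and only sequence of
#' their species) are excluded from `N1` but remain in the tree, where they
#' can still break other groups' monophyly.
#'
#' @param tree an [ape::phylo] object whose tip labels are sequence ids.
#' @param taxonomy data frame with columns `sequence_id`, `genus`, `species`
#'   covering every tip (e.g. `dataset$taxa`).
#' @param semantics `"and"` (default) or `"or"`, see above; affects only the
#'   sequence-level metric.
#' @return object of class `grouping_report`: list with `N1`, `N2`,
#'   `pct_sequences`, `pct_species` (NA when the denominator is 0), and a
#'   `details` data frame (group, type, size, monophyletic).
#' @export
grouping_report <- function(tree, taxonomy, semantics = c("and", "or")) {
  semantics <- match.arg(semantics)
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  i <- match(tips, taxonomy$sequence_id)
  if (anyNA(i)) {
    stop("no taxonomy for leaf/leaves: ", paste(tips[is.na(i)], collapse = ", "))
  }
  genus <- taxonomy$genus[i]
  spkey <- paste(genus, taxonomy$species[i], sep = " ")

  bip <- tree_bipartitions(tree)
  sp_of_genus <- tapply(spkey, genus, function(s) length(unique(s)))
  seqs_of_sp <- table(spkey)

  multi_sp <- names(seqs_of_sp)[seqs_of_sp >= 2L]
  multi_gen <- names(sp_of_genus)[sp_of_genus >= 2L]

  sp_mono <- vapply(multi_sp, function(s)
    is_cluster(tree, tips[spkey == s], bip), TRUE)
  gen_mono <- vapply(multi_gen, function(g)
    is_cluster(tree, tips[genus == g], bip), TRUE)

  details <- rbind(
    if (length(multi_gen)) data.frame(
      group = multi_gen, type = "genus",
      size = as.integer(table(genus)[multi_gen]),
      monophyletic = unname(gen_mono), stringsAsFactors = FALSE),
    if (length(multi_sp)) data.frame(
      group = multi_sp, type = "species",
      size = as.integer(seqs_of_sp[multi_sp]),
      monophyletic = unname(sp_mono), stringsAsFactors = FALSE))

  gen_applies <- genus %in% multi_gen
  sp_applies <- spkey %in% multi_sp
  eligible <- gen_applies | sp_applies
  gen_ok <- !gen_applies | gen_mono[match(genus, multi_gen)]
  sp_ok <- !sp_applies | sp_mono[match(spkey, multi_sp)]
  gen_ok[is.na(gen_ok)] <- TRUE
  sp_ok[is.na(sp_ok)] <- TRUE
  success <- if (semantics == "and") {
    gen_ok & sp_ok
  } else {
    (!eligible) | (gen_applies & gen_ok) | (sp_applies & sp_ok)
  }

  N1 <- sum(eligible)
  N2 <- length(multi_sp)
  structure(list(
    N1 = N1,
    N2 = N2,
    pct_sequences = if (N1 > 0) 100 * sum(success & eligible) / N1 else NA_real_,
    pct_species = if (N2 > 0) 100 * sum(sp_mono) / N2 else NA_real_,
    details = details,
    semantics = semantics
  ), class = "grouping_report")
}

#' Sequence-level grouping success
#'
#' Convenience accessor for the sequence-level part of [grouping_report()].
#'
#' @inheritParams grouping_report
#' @return the report, with the sequence-level percentage in
#'   `$pct_sequences`.
#' @export
sequence_grouping_success <- function(tree, taxonomy,
                                      semantics = c("and", "or")) {
  grouping_report(tree, taxonomy, semantics)
}

#' Species-level grouping success
#'
#' Convenience accessor for the species-level part of [grouping_report()].
#'
#' @inheritParams grouping_report
#' @return the report, with the species-level percentage in `$pct_species`.
#' @export
species_grouping_success <- function(tree, taxonomy) {
  grouping_report(tree, taxonomy)
}

#' @export
print.grouping_report <- function(x, ...) {
  cat("Grouping effectiveness\n")
  cat(sprintf("  sequences grouped to genus/species: %s%%  (N1 = %d)\n",
              if (is.na(x$pct_sequences)) "NA" else
                formatC(x$pct_sequences, format = "f", digits = 1), x$N1))
  cat(sprintf("  multi-sequence species grouped:     %s%%  (N2 = %d)\n",
              if (is.na(x$pct_species)) "NA" else
                formatC(x$pct_species, format = "f", digits = 1), x$N2))
  invisible(x)
}

#' Write a grouping report as TSV + JSON summary
#'
#' @param report a `grouping_report`.
#' @param tsv_path per-group detail table (group, type, size, monophyletic).
#' @param json_path summary `{N1, N2, pct_sequences, pct_species}`.
#' @return `report`, invisibly.
#' @export
write_grouping_report <- function(report, tsv_path, json_path = NULL) {
  stopifnot(inherits(report, "grouping_report"))
  write.table(report$details, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(N1 = report$N1, N2 = report$N2,
           pct_sequences = report$pct_sequences,
           pct_species = report$pct_species),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}
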