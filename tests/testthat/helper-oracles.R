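# Independent brute-force oracles used to cross-check the sparse/packed
# implementation paths. They work on character k-mers and dense 4^K vectors
# and share no code with the package internals.

random_seq <- function(L, bases = c("A", "C", "G", "T")) {
  paste0(sample(bases, L, replace = TRUE), collapse = "")
}

all_kmers <- function(K) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), K),
                              stringsAsFactors = FALSE)[, K:1, drop = FALSE])
}

# dense frequency vector over all 4^K coordinates, ambiguity windows skipped,
# denominator L - K + 1
dense_freq <- function(seq, K) {
  L <- nchar(seq)
  wins <- substring(toupper(seq), 1:(L - K + 1), K:L)
  wins <- wins[!grepl("[^ACGT]", wins)]
  as.vector(table(factor(wins, levels = all_kmers(K)))) / (L - K + 1)
}

dense_cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

dense_cv_distance <- function(a, b, K) {
  (1 - dense_cosine(dense_freq(a, K), dense_freq(b, K))) / 2
}

# dense background-normalized vector (p - p0)/p0 over all 4^K strings
dense_background <- function(seq, K) {
  p <- dense_freq(seq, K)
  p1 <- dense_freq(seq, K - 1)
  p2 <- dense_freq(seq, K - 2)
  km <- all_kmers(K)
  pref <- match(substr(km, 1, K - 1), all_kmers(K - 1))
  suff <- match(substr(km, 2, K), all_kmers(K - 1))
  mid <- match(substr(km, 2, K - 1), all_kmers(K - 2))
  p0 <- ifelse(p2[mid] > 0, p1[pref] * p1[suff] / p2[mid], 0)
  ifelse(p0 > 0, (p - p0) / p0, 0)
}

# all edge bipartitions of an unrooted tree via igraph component splitting
bipartitions_oracle <- function(tree) {
  n <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    g2 <- igraph::delete_edges(g, e)
    comp <- igraph::components(g2)$membership
    side <- as.integer(names(comp)[comp == comp[[as.character(tree$edge[e, 2])]]])
    side <- sort(side[side <= n])
    if (1 %in% side) side <- setdiff(seq_len(n), side)
    keys <- c(keys, paste(side, collapse = ","))
  }
  unique(keys)
}

cluster_oracle <- function(tree, leafset, keys = bipartitions_oracle(tree)) {
  n <- length(tree$tip.label)
  idx <- sort(match(leafset, tree$tip.label))
  if (length(idx) <= 1 || length(idx) >= n) return(TRUE)
  if (1 %in% idx) idx <- setdiff(seq_len(n), idx)
  paste(idx, collapse = ",") %in% keys
}

# independent recomputation of both grouping metrics straight from the rule
grouping_oracle <- function(tree, taxonomy, semantics = "and") {
  tips <- tree$tip.label
  i <- match(tips, taxonomy$sequence_id)
  genus <- taxonomy$genus[i]
  spkey <- paste(genus, taxonomy$species[i])
  keys <- bipartitions_oracle(tree)
  n_sp_in_gen <- sapply(unique(genus), function(g)
    length(unique(spkey[genus == g])))
  n_seq_in_sp <- table(spkey)
  succ <- eligible <- logical(length(tips))
  for (t in seq_along(tips)) {
    g_applies <- n_sp_in_gen[[genus[t]]] >= 2
    s_applies <- n_seq_in_sp[[spkey[t]]] >= 2
    eligible[t] <- g_applies || s_applies
    g_ok <- !g_applies || cluster_oracle(tree, tips[genus == genus[t]], keys)
    s_ok <- !s_applies || cluster_oracle(tree, tips[spkey == spkey[t]], keys)
    succ[t] <- if (semantics == "and") g_ok && s_ok else
      (g_applies && g_ok) || (s_applies && s_ok) || !eligible[t]
  }
  multi_sp <- names(n_seq_in_sp)[n_seq_in_sp >= 2]
  sp_ok <- sapply(multi_sp, function(s)
    cluster_oracle(tree, tips[spkey == s], keys))
  list(N1 = sum(eligible),
       N2 = length(multi_sp),
       pct_sequences = if (sum(eligible)) 100 * sum(succ & eligible) / sum(eligible) else NA,
       pct_species = if (length(multi_sp)) 100 * sum(sp_ok) / length(multi_sp) else NA)
}

# random taxonomy over the tips of a tree: ng genera, up to sg species each
random_taxonomy <- function(tips, ng = 3, sg = 2) {
  genus <- sprintf("G%d", sample.int(ng, length(tips), replace = TRUE))
  species <- sprintf("s%d", sample.int(sg, length(tips), replace = TRUE))
  data.frame(sequence_id = tips, genus = genus, species = species,
             individual = as.character(seq_along(tips)),
             stringsAsFactors = FALSE)
}

# small in-memory dataset builder for distance/kscan tests
make_dataset <- function(seqs_per_locus) {
  recs <- lapply(names(seqs_per_locus), function(g) {
    s <- seqs_per_locus[[g]]
    labs <- parse_taxon_labels(names(s))
    cbind(labs, data.frame(locus = g, residues = unname(toupper(s)),
                           length_L = nchar(unname(s)),
                           stringsAsFactors = FALSE))
  })
  names(recs) <- names(seqs_per_locus)
  assemble_dataset(recs)
}
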