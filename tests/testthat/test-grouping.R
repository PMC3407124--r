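balanced_tree <- function(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);") {
  ape::unroot(ape::read.tree(text = text))
}

test_that("is_cluster recognises exact bipartitions only", {
  tr <- balanced_tree()
  expect_true(is_cluster(tr, c("a1", "a2")))
  expect_false(is_cluster(tr, c("a1", "b1")))
  expect_true(is_cluster(tr, "a1"))                       # singleton
  expect_true(is_cluster(tr, c("a1", "a2", "b1", "b2")))  # full set
  expect_error(is_cluster(tr, c("a1", "zz")), "zz")
})

test_that("is_cluster agrees with edge-deletion enumeration on all subsets", {
  set.seed(12)
  tr <- ape::unroot(ape::rtree(9))
  keys <- bipartitions_oracle(tr)
  bip <- tree_bipartitions(tr)
  tips <- tr$tip.label
  for (mask in 1:(2^9 - 1)) {
    subset <- tips[as.logical(bitwAnd(mask, 2^(0:8)))]
    expect_equal(is_cluster(tr, subset, bip),
                 cluster_oracle(tr, subset, keys))
  }
})

test_that("fully concordant and fully discordant trees hit 100% and 0%", {
  # every species and genus a clade
  tr <- ape::read.tree(text = paste0(
    "(((A_x_1:1,A_x_2:1):1,(A_y_1:1,A_y_2:1):1):1,",
    "((B_x_1:1,B_x_2:1):1,(B_y_1:1,B_y_2:1):1):1);"))
  tax <- parse_taxon_labels(tr$tip.label)
  rep_ <- grouping_report(tr, tax)
  expect_equal(rep_$pct_sequences, 100)
  expect_equal(rep_$pct_species, 100)
  expect_equal(rep_$N1, 8L)
  expect_equal(rep_$N2, 4L)

  # interleaved genera: nothing groups
  tr2 <- ape::read.tree(text = "((g1s1a:1,g2s1a:1):1,(g1s2a:1,g2s2a:1):1);")
  tax2 <- data.frame(sequence_id = tr2$tip.label,
                     genus = c("g1", "g2", "g1", "g2"),
                     species = c("s1", "s1", "s2", "s2"),
                     stringsAsFactors = FALSE)
  rep2 <- grouping_report(tr2, tax2)
  expect_equal(rep2$N1, 4L)
  expect_equal(rep2$pct_sequences, 0)
})

test_that("one broken species out of two scores 50% at the species level", {
  tr <- ape::read.tree(
    text = "((A_x_1:1,A_x_2:1):1,((A_y_1:1,B_z_1:1):1,A_y_2:1):1);")
  tax <- parse_taxon_labels(tr$tip.label)
  rep_ <- grouping_report(tr, tax)
  expect_equal(rep_$N2, 2L)
  expect_equal(rep_$pct_species, 50)
})

test_that("grouping metrics match the brute-force oracle on random instances", {
  set.seed(99)
  for (rep in 1:25) {
    tr <- ape::unroot(ape::rtree(sample(8:14, 1)))
    tr$tip.label <- sprintf("L%02d", seq_along(tr$tip.label))
    tax <- random_taxonomy(tr$tip.label)
    for (sem in c("and", "or")) {
      got <- grouping_report(tr, tax, sem)
      want <- grouping_oracle(tr, tax, sem)
      expect_equal(got$N1, want$N1)
      expect_equal(got$N2, want$N2)
      expect_equal(got$pct_sequences, want$pct_sequences)
      expect_equal(got$pct_species, want$pct_species)
    }
  }
})

test_that("metrics are invariant under rerooting", {
  set.seed(31)
  tr <- ape::unroot(ape::rtree(12))
  tr$tip.label <- sprintf("L%02d", 1:12)
  tax <- random_taxonomy(tr$tip.label)
  base <- grouping_report(tr, tax)
  for (out in sample(tr$tip.label, 4)) {
    rr <- ape::root(tr, outgroup = out, resolve.root = TRUE)
    got <- grouping_report(rr, tax)
    expect_equal(got$pct_sequences, base$pct_sequences)
    expect_equal(got$pct_species, base$pct_species)
  }
})

test_that("an outgroup singleton species changes neither percentage", {
  set.seed(32)
  tr <- ape::unroot(ape::rtree(10))
  tr$tip.label <- sprintf("L%02d", 1:10)
  tax <- random_taxonomy(tr$tip.label)
  base <- grouping_report(tr, tax)
  # attach the new leaf at the basal trifurcation: outside every group
  plus <- ape::bind.tree(tr, ape::read.tree(text = "(Znew:1);"),
                         where = ape::Ntip(tr) + 1L)
  tax_plus <- rbind(tax, data.frame(sequence_id = "Znew", genus = "Zg",
                                    species = "Zs", individual = "1"))
  got <- grouping_report(plus, tax_plus)
  expect_equal(got$N1, base$N1)
  expect_equal(got$pct_sequences, base$pct_sequences)
  expect_equal(got$pct_species, base$pct_species)
})

test_that("singletons are excluded from N1 and undefined metrics are NA", {
  tr <- ape::read.tree(text = "((A_x_1:1,A_x_2:1):1,(B_y_1:1,C_z_1:1):1);")
  tax <- parse_taxon_labels(tr$tip.label)
  rep_ <- grouping_report(tr, tax)
  # B_y_1 and C_z_1 are single-species genera with single-sequence species
  expect_equal(rep_$N1, 2L)
  expect_equal(rep_$N2, 1L)

  solo <- ape::read.tree(text = "((A_x_1:1,B_y_1:1):1,C_z_1:1);")
  rep0 <- grouping_report(solo, parse_taxon_labels(solo$tip.label))
  expect_equal(rep0$N1, 0L)
  expect_true(is.na(rep0$pct_sequences))
  expect_true(is.na(rep0$pct_species))
})

test_that("or-semantics is at least as lenient as and-semantics", {
  set.seed(44)
  for (rep in 1:10) {
    tr <- ape::unroot(ape::rtree(10))
    tr$tip.label <- sprintf("L%02d", 1:10)
    tax <- random_taxonomy(tr$tip.label)
    a <- grouping_report(tr, tax, "and")$pct_sequences
    o <- grouping_report(tr, tax, "or")$pct_sequences
    if (!is.na(a) && !is.na(o)) expect_gte(o, a)
  }
})

test_that("report files carry the detail table and JSON summary", {
  tr <- balanced_tree("((A_x_1:1,A_x_2:1):1,(A_y_1:1,A_y_2:1):1);")
  tax <- parse_taxon_labels(tr$tip.label)
  rep_ <- grouping_report(tr, tax)
  tsv <- withr::local_tempfile()
  js <- withr::local_tempfile()
  write_grouping_report(rep_, tsv, js)
  tab <- read.delim(tsv)
  expect_setequal(tab$type, c("genus", "species"))
  summ <- jsonlite::read_json(js)
  expect_equal(summ$N1, rep_$N1)
  expect_equal(summ$pct_species, rep_$pct_species)
})
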