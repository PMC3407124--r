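two_locus_ds <- function() {
  make_dataset(list(
    matK = c(A_a_1 = "AAAA", B_b_1 = "CCCC"),
    rbcL = c(A_a_1 = "ACGTACGT", B_b_1 = "ACGTACGA")))
}

test_that("per-locus distance matrix matches the pairwise CV distance", {
  ds <- two_locus_ds()
  D <- locus_distance_matrix(ds, "matK", 2)
  expect_equal(D["A_a_1", "B_b_1"], 0.5) # orthogonal key sets
  expect_equal(diag(D), c(A_a_1 = 0, B_b_1 = 0))
  expect_equal(attr(D, "locus"), "matK")

  # identical sequences -> zero matrix
  same <- make_dataset(list(matK = c(A_a_1 = "ACGTACGT", A_a_2 = "ACGTACGT",
                                     B_b_1 = "ACGTACGT")))
  expect_equal(max(locus_distance_matrix(same, "matK", 3)), 0)

  expect_error(locus_distance_matrix(ds, "matK", 5), "shorter than K")
  expect_error(locus_distance_matrix(ds, "nope", 2), "unknown locus")
})

test_that("matrix entries equal dense-oracle distances on random taxa", {
  set.seed(42)
  ids <- sprintf("G%d_s%d_1", 1:5, rep(1, 5))
  seqs <- setNames(vapply(1:5, function(i) random_seq(40), ""), ids)
  ds <- make_dataset(list(matK = seqs))
  D <- locus_distance_matrix(ds, "matK", 4)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(D[i, j], dense_cv_distance(seqs[[i]], seqs[[j]], 4),
                 tolerance = 1e-12)
  }
})

test_that("pair weights follow the summed-length share and sum to one", {
  ds <- make_dataset(list(
    g1 = c(A_a_1 = strrep("ACGT", 25), B_b_1 = strrep("ACGT", 25)),   # 100
    g2 = c(A_a_1 = strrep("ACCGGT", 50), B_b_1 = strrep("ACCGGT", 50)))) # 300
  w <- pair_weights(ds, "A_a_1", "B_b_1")
  expect_equal(unname(w), c(0.25, 0.75))
  expect_equal(sum(w), 1, tolerance = 1e-12)

  # equal lengths at every locus -> equal weights
  eq <- make_dataset(list(g1 = c(A_a_1 = "ACGTACGT", B_b_1 = "ACGGACGT"),
                          g2 = c(A_a_1 = "TTGCAGCA", B_b_1 = "TTGCAACA")))
  expect_equal(unname(pair_weights(eq, 1, 2)), c(0.5, 0.5))

  # three loci, lengths (800,800), (550,550), (450,450)
  ds3 <- simulate_dataset(sim_config(n_genera = 1L, species_per_genus = 2L,
    individuals_per_species = 1L,
    locus_specs = data.frame(name = c("matK", "rbcL", "trnH-psbA"),
                             mean_length = c(800L, 550L, 450L),
                             length_sd = c(0, 0, 0), indel_rate = c(0, 0, 0)),
    seed = 9))
  w3 <- pair_weights(ds3, 1, 2)
  expect_equal(unname(w3), c(1600, 1100, 900) / 3600, tolerance = 1e-12)
})

test_that("combination is a per-pair convex combination of locus distances", {
  set.seed(7)
  ids <- sprintf("G%d_s%d_%d", rep(1:3, each = 2), rep(1:2, 3), rep(1:2, 3))[1:6]
  mk <- function(L) setNames(vapply(seq_along(ids), function(i)
    random_seq(L + sample(0:20, 1)), ""), ids)
  ds <- make_dataset(list(g1 = mk(60), g2 = mk(80), g3 = mk(40)))
  per <- lapply(setNames(ds$loci, ds$loci), function(g)
    locus_distance_matrix(ds, g, 3))
  comb <- combine_matrices(per, ds)

  # brute-force per-pair weighted sum recomputed independently
  for (i in 1:5) for (j in (i + 1):6) {
    w <- vapply(ds$loci, function(g) {
      Ls <- ds$lengths[i, g] + ds$lengths[j, g]
      Ls / sum(ds$lengths[i, ] + ds$lengths[j, ])
    }, 0)
    expected <- sum(w * vapply(ds$loci, function(g) per[[g]][i, j], 0))
    expect_equal(comb[i, j], expected, tolerance = 1e-12)
    ds_ij <- vapply(ds$loci, function(g) per[[g]][i, j], 0)
    expect_gte(comb[i, j], min(ds_ij) - 1e-12)
    expect_lte(comb[i, j], max(ds_ij) + 1e-12)
  }
  expect_equal(comb, t(comb))
  expect_equal(unname(diag(comb)), rep(0, 6))
})

test_that("combining identical matrices is the identity; equal lengths average", {
  ds <- make_dataset(list(g1 = c(A_a_1 = "ACGTACGTAA", B_b_1 = "ACGGACGTAA"),
                          g2 = c(A_a_1 = "ACGTACGTAA", B_b_1 = "ACGGACGTAA")))
  D <- locus_distance_matrix(ds, "g1", 3)
  comb <- combine_matrices(list(g1 = D, g2 = D), ds)
  expect_equal(as.vector(comb), as.vector(D))

  # distinct matrices, equal lengths -> plain mean
  D2 <- locus_distance_matrix(ds, "g2", 4)
  comb2 <- combine_matrices(list(g1 = D, g2 = D2), ds)
  expect_equal(comb2[1, 2], (D[1, 2] + D2[1, 2]) / 2, tolerance = 1e-12)
})

test_that("weights ignore K and permutation commutes with combination", {
  ds <- two_locus_ds()
  pl_a <- list(matK = locus_distance_matrix(ds, "matK", 2),
               rbcL = locus_distance_matrix(ds, "rbcL", 2))
  pl_b <- list(matK = locus_distance_matrix(ds, "matK", 3),
               rbcL = locus_distance_matrix(ds, "rbcL", 4))
  # same weights regardless of the K used for the distances: recombining the
  # SAME matrices labelled with different K must give identical results
  attr_swap <- pl_a
  attr(attr_swap$matK, "K") <- 20L
  attr(attr_swap$rbcL, "K") <- 6L
  expect_identical(as.vector(combine_matrices(pl_a, ds)),
                   as.vector(combine_matrices(attr_swap, ds)))
  # per-locus K genuinely differing is supported
  comb <- combine_matrices(pl_b, ds)
  expect_equal(attr(comb, "K"), c(matK = 3L, rbcL = 4L))

  # permute taxa then combine == combine then permute
  set.seed(11)
  ids <- sprintf("G%d_s1_%d", rep(1:2, each = 2), rep(1:2, 2))
  seqs1 <- setNames(vapply(1:4, function(i) random_seq(30), ""), ids)
  seqs2 <- setNames(vapply(1:4, function(i) random_seq(50), ""), ids)
  ds1 <- make_dataset(list(g1 = seqs1, g2 = seqs2))
  perm <- c(3, 1, 4, 2)
  ds2 <- make_dataset(list(g1 = seqs1[perm], g2 = seqs2[perm]))
  c1 <- combine_matrices(lapply(setNames(ds1$loci, ds1$loci), function(g)
    locus_distance_matrix(ds1, g, 3)), ds1)
  c2 <- combine_matrices(lapply(setNames(ds2$loci, ds2$loci), function(g)
    locus_distance_matrix(ds2, g, 3)), ds2)
  expect_equal(unclass(c1)[ids[perm], ids[perm]], unclass(c2)[, ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("missing loci error in strict use and renormalize when allowed", {
  f1 <- withr::local_tempfile(lines = c(">A_b_1", "ACGTACGT", ">C_d_1", "ACGGACGT"))
  f2 <- withr::local_tempfile(lines = c(">A_b_1", "TTTTGGGG"))
  ds <- assemble_dataset(list(g1 = read_locus_fasta(f1, "g1"),
                              g2 = read_locus_fasta(f2, "g2")), strict = FALSE)
  expect_error(pair_weights(ds, "A_b_1", "C_d_1"), "missing")
  w <- pair_weights(ds, "A_b_1", "C_d_1", renormalize_missing = TRUE)
  expect_equal(unname(w), c(1, 0))
})
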