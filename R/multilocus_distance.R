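# Per-locus CV distance matrices and the pairwise length-weighted combination.
#
# The weight of locus g for the taxon pair (i, j) is
#   w_g(i, j) = (L_g^i + L_g^j) / sum_h (L_h^i + L_h^j),
# i.e. each locus gets its share of the pair's summed sequence length. The
# weights are pairwise, sum to 1 over loci, and do not depend on the string
# length K, so per-locus matrices computed at different K can be combined.
# NOTE: the defining equations of the source method are only described in
# prose; this form is the natural reading consistent with every stated
# property and is isolated in pair_weights()/.weight_matrices() so an
# alternative reading is a one-line change.

#' Per-locus CV distance matrix
#'
#' Computes the `D = (1 - C)/2` composition-vector distance between every
#' pair of sequences of one locus. Internally the sparse frequency vectors of
#' all sequences are assembled into one row-normalized sparse matrix and the
#' full correlation matrix is obtained by a single sparse cross-product, so
#' no 4^K dense vector is ever allocated.
#'
#' @param dataset a `multilocus_dataset`.
#' @param locus locus name.
#' @param K string length for this locus.
#' @param mode `"raw"` frequencies (default) or `"background"`-normalized.
#' @return symmetric distance matrix (taxa x taxa, dimnames = sequence ids)
#'   with zero diagonal and attributes `locus` and `K`.
#' @export
locus_distance_matrix <- function(dataset, locus, K,
                                  mode = c("raw", "background")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "multilocus_dataset"))
  if (!locus %in% dataset$loci) stop("unknown locus: ", locus)
  seqs <- dataset$sequences[[locus]]
  if (anyNA(seqs)) {
    stop("locus ", locus, " missing for taxa: ",
         paste(names(seqs)[is.na(seqs)], collapse = ", "))
  }
  short <- nchar(seqs) < K
  if (any(short)) {
    stop("sequences shorter than K = ", K, " at locus ", locus, ": ",
         paste(names(seqs)[short], collapse = ", "))
  }
  cvs <- lapply(seqs, composition_vector, K = K, mode = mode)
  zero <- vapply(cvs, function(cv) cv$norm == 0, TRUE)
  if (any(zero)) {
    stop("zero-norm composition vector (locus ", locus, ", K = ", K, ") for: ",
         paste(names(seqs)[zero], collapse = ", "))
  }
  keys <- sort(unique(unlist(lapply(cvs, `[[`, "keys"), use.names = FALSE)))
  i <- rep(seq_along(cvs), vapply(cvs, function(cv) length(cv$keys), 0L))
  j <- unlist(lapply(cvs, function(cv) match(cv$keys, keys)), use.names = FALSE)
  x <- unlist(lapply(cvs, function(cv) cv$entries / cv$norm), use.names = FALSE)
  X <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(cvs), length(keys)))
  C <- as.matrix(Matrix::tcrossprod(X))
  C <- pmin(pmax(C, -1), 1)
  D <- (1 - C) / 2
  D[D < 0] <- 0
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(names(seqs), names(seqs))
  attr(D, "locus") <- locus
  attr(D, "K") <- as.integer(K)
  attr(D, "mode") <- mode
  D
}

#' Pairwise locus weights for one taxon pair
#'
#' @param dataset a `multilocus_dataset`.
#' @param i,j sequence ids (or row indices) of the two taxa.
#' @param renormalize_missing in non-strict datasets, give weight 0 to a locus
#'   absent for either taxon and renormalize over the rest; with the default
#'   `FALSE`, missing loci are an error.
#' @return named numeric vector of weights `w_g(i, j)`, one per locus,
#'   summing to 1. Independent of any K.
#' @export
pair_weights <- function(dataset, i, j, renormalize_missing = FALSE) {
  stopifnot(inherits(dataset, "multilocus_dataset"))
  L <- dataset$lengths
  if (is.character(i)) i <- match(i, rownames(L))
  if (is.character(j)) j <- match(j, rownames(L))
  if (anyNA(c(i, j))) stop("unknown taxon")
  s <- L[i, ] + L[j, ]
  if (anyNA(s)) {
    if (!renormalize_missing) {
      stop("locus missing for pair (",
           rownames(L)[i], ", ", rownames(L)[j], "): ",
           paste(colnames(L)[is.na(s)], collapse = ", "))
    }
    s[is.na(s)] <- 0
  }
  tot <- sum(s)
  if (tot == 0) stop("all sequence lengths are zero for this pair")
  s / tot
}

# full n x n weight matrix per locus; W[[g]][i, j] = w_g(i, j)
.weight_matrices <- function(dataset, renormalize_missing = FALSE) {
  L <- dataset$lengths
  if (anyNA(L) && !renormalize_missing) {
    stop("dataset has missing loci; use renormalize_missing = TRUE")
  }
  L0 <- L
  L0[is.na(L0)] <- 0
  S <- lapply(seq_along(dataset$loci), function(g) outer(L0[, g], L0[, g], "+"))
  tot <- Reduce(`+`, S)
  W <- lapply(S, function(s) s / tot)
  names(W) <- dataset$loci
  W
}

#' Combine per-locus distance matrices with pairwise length weights
#'
#' `combined(i, j) = sum_g w_g(i, j) * D_g(i, j)` — a per-pair convex
#' combination of the per-locus CV distances, so every combined entry lies
#' between the smallest and largest per-locus distance for that pair. The
#' per-locus matrices may have been computed at different K.
#'
#' @param per_locus named list (locus -> distance matrix from
#'   [locus_distance_matrix()]); all matrices must share taxon order.
#' @param dataset the `multilocus_dataset` providing sequence lengths.
#' @param renormalize_missing see [pair_weights()].
#' @return combined symmetric distance matrix with attribute `K` carrying the
#'   per-locus K map and `locus = "combined"`.
#' @export
combine_matrices <- function(per_locus, dataset, renormalize_missing = FALSE) {
  stopifnot(inherits(dataset, "multilocus_dataset"), length(per_locus) >= 1L)
  if (is.null(names(per_locus))) {
    names(per_locus) <- vapply(per_locus, attr, "", "locus")
  }
  if (!setequal(names(per_locus), dataset$loci)) {
    stop("need exactly one matrix per dataset locus")
  }
  per_locus <- per_locus[dataset$loci]
  ids <- rownames(dataset$lengths)
  for (g in dataset$loci) {
    if (!identical(rownames(per_locus[[g]]), ids)) {
      stop("taxon order of matrix ", g, " does not match the dataset")
    }
  }
  W <- .weight_matrices(dataset, renormalize_missing)
  combined <- Reduce(`+`, Map(`*`, W, per_locus))
  combined <- (combined + t(combined)) / 2
  diag(combined) <- 0
  stopifnot(all(combined >= 0 & combined <= 1))
  dimnames(combined) <- list(ids, ids)
  attr(combined, "locus") <- "combined"
  attr(combined, "K") <- vapply(per_locus, function(m)
    as.integer(attr(m, "K")), 0L)
  combined
}
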