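# End-to-end pipeline: per-locus CV distances -> weighted combination ->
# NJ tree -> grouping report.

#' Run the full multi-locus CV/NJ analysis
#'
#' Builds the per-locus composition-vector distance matrices at the given
#' per-locus K, combines them with pairwise sequence-length weights, builds
#' the neighbor-joining tree from the combined matrix, and scores grouping
#' effectiveness against the dataset's taxonomy.
#'
#' @param dataset a `multilocus_dataset`.
#' @param K per-locus string lengths: a single integer (used for every
#'   locus), a named vector, or `NULL` to use [preset_K()] for known loci
#'   (error for loci without a preset).
#' @param mode `"raw"` or `"background"` composition vectors.
#' @param semantics sequence-level success semantics, see
#'   [grouping_report()].
#' @return object of class `cv_barcode`: list with `dataset`, `K` (named
#'   per-locus vector), `per_locus` (distance matrices), `combined`, `tree`
#'   (an [ape::phylo]) and `report` (a `grouping_report`).
#' @examples
#' ds <- simulate_dataset(sim_preset("easy", seed = 7))
#' fit <- cv_barcode(ds, K = 8)
#' fit
#' @export
cv_barcode <- function(dataset, K = NULL, mode = c("raw", "background"),
                       semantics = c("and", "or")) {
  mode <- match.arg(mode)
  semantics <- match.arg(semantics)
  stopifnot(inherits(dataset, "multilocus_dataset"))
  K <- resolve_K(dataset$loci, K)
  per_locus <- lapply(dataset$loci, function(g)
    locus_distance_matrix(dataset, g, K[[g]], mode))
  names(per_locus) <- dataset$loci
  combined <- combine_matrices(per_locus, dataset)
  tree <- neighbor_joining(combined)
  report <- grouping_report(tree, dataset$taxa, semantics)
  structure(list(dataset = dataset, K = K, mode = mode,
                 per_locus = per_locus, combined = combined,
                 tree = tree, report = report),
            class = "cv_barcode")
}

#' Resolve a per-locus K specification
#'
#' @param loci character vector of locus names.
#' @param K single integer, named vector, or `NULL` for [preset_K()].
#' @return named integer vector over `loci`.
#' @export
resolve_K <- function(loci, K = NULL) {
  if (is.null(K)) {
    K <- preset_K()[loci]
    if (anyNA(K)) {
      stop("no preset K for locus/loci: ",
           paste(loci[is.na(K)], collapse = ", "),
           "; give K explicitly or run best_k_scan()")
    }
    names(K) <- loci
  } else if (is.null(names(K))) {
    if (length(K) == 1L) K <- setNames(rep(as.integer(K), length(loci)), loci)
    else if (length(K) == length(loci)) K <- setNames(as.integer(K), loci)
    else stop("K must be length 1, one per locus, or named")
  } else {
    if (!all(loci %in% names(K))) {
      stop("K missing for locus/loci: ",
           paste(setdiff(loci, names(K)), collapse = ", "))
    }
    K <- as.integer(K[loci])
    names(K) <- loci
  }
  storage.mode(K) <- "integer"
  K
}

#' @export
print.cv_barcode <- function(x, ...) {
  cat("Multi-locus CV/NJ analysis\n")
  cat(sprintf("  loci: %s\n",
              paste(sprintf("%s (K = %d)", names(x$K), x$K), collapse = ", ")))
  cat(sprintf("  taxa: %d; mode: %s\n", n_taxa(x$dataset), x$mode))
  print(x$report)
  invisible(x)
}

#' @export
summary.cv_barcode <- function(object, ...) {
  print(object)
  off <- object$combined[upper.tri(object$combined)]
  cat(sprintf("  combined distances: min %.4f, median %.4f, max %.4f\n",
              min(off), stats::median(off), max(off)))
  if (!is.null(object$report$details)) {
    bad <- object$report$details[!object$report$details$monophyletic, ,
                                 drop = FALSE]
    if (nrow(bad)) {
      cat("  non-monophyletic groups:\n")
      for (r in seq_len(nrow(bad))) {
        cat(sprintf("    %s (%s, %d sequences)\n", bad$group[r], bad$type[r],
                    bad$size[r]))
      }
    }
  }
  invisible(object)
}

#' @export
plot.cv_barcode <- function(x, ...) {
  ape::plot.phylo(x$tree, type = "unrooted", ...)
  invisible(x)
}
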