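# Best-K selection: scan K over a range, score each single-locus CV/NJ tree
# by grouping effectiveness, and pick the argmax (smallest K on ties).

#' Advisory per-locus K presets
#'
#' Best-K values reported for the three core plant barcoding regions
#' (matK = 14, rbcL = 14, trnH-psbA = 8), offered as preset defaults for
#' these loci; for any other locus the best K should be determined with
#' [best_k_scan()].
#'
#' @return named integer vector.
#' @export
preset_K <- function() {
  c(matK = 14L, rbcL = 14L, `trnH-psbA` = 8L)
}

#' Scan string lengths K for one locus
#'
#' For each K in the range, builds the single-locus CV distance matrix, the
#' NJ tree, and the grouping report, and scores it with the requested metric
#' (sequence-level by default, matching the selection protocol). K values
#' exceeding `min sequence length - 1` are skipped with a warning and
#' reported as `NA` rows. The best K is the smallest K attaining the maximal
#' score.
#'
#' @param dataset a `multilocus_dataset`.
#' @param locus locus name.
#' @param k_range integer vector `c(k_min, k_max)`; default `c(6, 20)`.
#' @param metric `"sequence"` (default) or `"species"`.
#' @param mode passed to [locus_distance_matrix()].
#' @return list with `best_K` and `table` (data frame: K, N1, N2, pct).
#' @export
best_k_scan <- function(dataset, locus, k_range = c(6L, 20L),
                        metric = c("sequence", "species"),
                        mode = c("raw", "background")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "multilocus_dataset"))
  ks <- seq.int(k_range[1L], k_range[2L])
  if (any(ks < 1L)) stop("K must be >= 1")
  min_L <- min(dataset$lengths[, locus], na.rm = TRUE)
  tab <- data.frame(K = ks, N1 = NA_integer_, N2 = NA_integer_,
                    pct = NA_real_)
  for (r in seq_along(ks)) {
    K <- ks[r]
    if (K > min_L - 1L) {
      warning("skipping K = ", K, " for locus ", locus,
              " (shortest sequence has length ", min_L, ")")
      next
    }
    D <- locus_distance_matrix(dataset, locus, K, mode)
    tr <- neighbor_joining(D)
    rep_ <- grouping_report(tr, dataset$taxa)
    tab$N1[r] <- rep_$N1
    tab$N2[r] <- rep_$N2
    tab$pct[r] <- if (metric == "sequence") rep_$pct_sequences else
      rep_$pct_species
  }
  if (all(is.na(tab$pct))) stop("no valid K in range for locus ", locus)
  best <- tab$K[which.max(tab$pct)] # which.max: first (smallest K) on ties
  list(best_K = best, table = tab)
}
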