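# Sparse K-string composition vectors and the CV correlation/distance.
#
# Keys are 2-bit-packed integers stored as doubles (A=0, C=1, G=2, T=3, most
# significant base first), exact up to K = 26; numeric key order equals
# lexicographic k-mer order. A dense 4^K vector is never allocated.

.DNA_CODE <- c(A = 0, C = 1, G = 2, T = 3)

# integer codes 0..3, NA for anything outside ACGT (N, IUPAC ambiguity, gaps)
.dna_codes <- function(residues) {
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  unname(.DNA_CODE[chars])
}

# packed keys for all L-K+1 windows; NA where a window touches an ambiguous base
.window_keys <- function(codes, K) {
  if (K == 1L) return(as.numeric(codes))
  m <- embed(as.numeric(codes), K) # row i = codes[(i+K-1):i]
  drop(m %*% 4^(0:(K - 1L)))
}

.decode_kstring <- function(keys, K) {
  bases <- c("A", "C", "G", "T")
  out <- character(length(keys))
  mat <- matrix("", nrow = length(keys), ncol = K)
  rest <- keys
  for (pos in K:1) {
    mat[, pos] <- bases[rest %% 4 + 1]
    rest <- rest %/% 4
  }
  apply(mat, 1L, paste0, collapse = "")
}

#' Count K-strings of a DNA sequence
#'
#' Slides a window of length `K` one position at a time over `residues` and
#' counts each distinct K-string. Windows containing any non-ACGT symbol
#' (N, IUPAC ambiguity codes, gaps) are skipped; the window total used as the
#' frequency denominator remains `L - K + 1` regardless.
#'
#' @param residues single DNA string (case-insensitive).
#' @param K string length, `>= 1`; the sequence must satisfy `L >= K`.
#' @return an object of class `composition_vector`: a list with `K`, sorted
#'   packed `keys`, integer `counts`, frequency `entries`
#'   (`counts / total_windows`), `total_windows = L - K + 1`, sequence length
#'   `L`, the Euclidean `norm` of the frequency vector, and `mode = "raw"`.
#' @examples
#' count_kstrings("ACGT", 2)
#' @seealso [frequencies()], [cv_correlation()], [composition_vector()]
#' @export
count_kstrings <- function(residues, K) {
  stopifnot(is.character(residues), length(residues) == 1L)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  L <- nchar(residues)
  if (L < K) {
    stop(sprintf("sequence of length %d is shorter than K = %d", L, K))
  }
  codes <- .dna_codes(residues)
  keys <- .window_keys(codes, K)
  keys <- keys[!is.na(keys)]
  total <- L - K + 1L
  if (length(keys)) {
    keys <- sort(keys)
    r <- rle(keys)
    keys <- r$values
    counts <- r$lengths
  } else {
    counts <- integer(0)
  }
  entries <- counts / total
  structure(
    list(K = K, keys = keys, counts = counts, entries = entries,
         total_windows = total, L = L,
         norm = sqrt(sum(entries^2)), mode = "raw"),
    class = "composition_vector"
  )
}

#' Observed K-string frequencies
#'
#' Returns the sparse map of observed frequencies `p = n / (L - K + 1)`,
#' named by k-mer in lexicographic order. The denominator is always
#' `L - K + 1`, even when ambiguous windows were skipped, so frequencies sum
#' to at most 1.
#'
#' @param cv a `composition_vector` from [count_kstrings()].
#' @return named numeric vector of frequencies.
#' @export
frequencies <- function(cv) {
  stopifnot(inherits(cv, "composition_vector"))
  if (cv$total_windows <= 0) stop("composition vector has no windows")
  setNames(cv$counts / cv$total_windows, .decode_kstring(cv$keys, cv$K))
}

#' Composition vector of a sequence
#'
#' Convenience constructor: raw frequency vector, or the background-normalized
#' (Markov-subtracted) variant which also computes the required (K-1)- and
#' (K-2)-string counts from the same sequence.
#'
#' @inheritParams count_kstrings
#' @param mode `"raw"` (default) or `"background"`.
#' @return a `composition_vector`.
#' @export
composition_vector <- function(residues, K, mode = c("raw", "background")) {
  mode <- match.arg(mode)
  if (mode == "background" && K < 3) {
    stop("background normalization requires K >= 3")
  }
  cv <- count_kstrings(residues, K)
  if (mode == "raw") return(cv)
  normalize_background(cv,
                       count_kstrings(residues, K - 1L),
                       count_kstrings(residues, K - 2L))
}

#' Background-normalized composition vector
#'
#' Replaces each observed frequency by its relative deviation
#' `a(s) = (p(s) - p0(s)) / p0(s)` from the (K-2)-order Markov expectation
#' `p0(a1..aK) = p(a1..a(K-1)) * p(a2..aK) / p(a2..a(K-1))`, the classic
#' composition-vector normalization. Entries with `p0 = 0` are set to 0. The
#' support is enumerated sparsely: every string with `p0 > 0` is an observed
#' (K-1)-mer extended by one base whose suffix (K-1)-mer is also observed, so
#' strings forced to `-1` (observed count 0, `p0 > 0`) are retained without a
#' dense 4^K allocation.
#'
#' @param cv `composition_vector` at K (raw mode).
#' @param cv_km1,cv_km2 `composition_vector`s at K-1 and K-2 computed from the
#'   same sequence.
#' @return a `composition_vector` with signed `entries` and `mode =
#'   "background"`; `counts` are the observed counts on the enumerated support.
#' @export
normalize_background <- function(cv, cv_km1, cv_km2) {
  stopifnot(inherits(cv, "composition_vector"),
            inherits(cv_km1, "composition_vector"),
            inherits(cv_km2, "composition_vector"))
  K <- cv$K
  if (K < 3L) stop("background normalization requires K >= 3")
  if (cv_km1$K != K - 1L || cv_km2$K != K - 2L) {
    stop("neighbor counts must be at K - 1 and K - 2")
  }
  if (cv_km1$L != cv$L || cv_km2$L != cv$L) {
    stop("neighbor counts must come from the same sequence")
  }
  p1 <- setNames(cv_km1$entries, NULL)
  # candidate strings s = u + c with u an observed (K-1)-mer and the suffix
  # (K-1)-mer v = (u mod 4^(K-2)) * 4 + c also observed
  u <- rep(cv_km1$keys, each = 4L)
  cc <- rep(0:3, times = length(cv_km1$keys))
  s <- u * 4 + cc
  v <- (u %% 4^(K - 2L)) * 4 + cc
  w <- u %% 4^(K - 2L)
  iv <- match(v, cv_km1$keys)
  keep <- !is.na(iv)
  s <- s[keep]
  ord <- order(s)
  s <- s[ord]
  pu <- p1[rep(seq_along(cv_km1$keys), each = 4L)][keep][ord]
  pv <- p1[iv[keep]][ord]
  pw <- cv_km2$entries[match(w[keep], cv_km2$keys)][ord]
  p0 <- pu * pv / pw
  obs <- match(s, cv$keys)
  hit <- !is.na(obs)
  p <- numeric(length(s))
  p[hit] <- cv$entries[obs[hit]]
  counts <- integer(length(s))
  counts[hit] <- cv$counts[obs[hit]]
  entries <- ifelse(p0 > 0, (p - p0) / p0, 0)
  structure(
    list(K = K, keys = s, counts = as.integer(counts), entries = entries,
         total_windows = cv$total_windows, L = cv$L,
         norm = sqrt(sum(entries^2)), mode = "background"),
    class = "composition_vector"
  )
}

#' Projection correlation and CV distance between two composition vectors
#'
#' The correlation `C` is the cosine of the angle between the two (sparse)
#' 4^K-dimensional vectors, accumulated over the canonically sorted key union
#' so that `C(a, b) == C(b, a)` to the last bit; the distance is
#' `D = (1 - C)/2`. With raw frequencies all entries are nonnegative, so
#' `C` is in `[0, 1]` and `D` in `[0, 0.5]`; background-normalized vectors may
#' have negative correlation and `D` in `[0, 1]`.
#'
#' @param a,b `composition_vector`s at the same `K` and mode.
#' @return list with `correlation_C` and `distance_D`.
#' @examples
#' a <- count_kstrings("AAAA", 2)
#' b <- count_kstrings("CCCC", 2)
#' cv_correlation(a, b) # orthogonal: C = 0, D = 0.5
#' @export
cv_correlation <- function(a, b) {
  stopifnot(inherits(a, "composition_vector"),
            inherits(b, "composition_vector"))
  if (a$K != b$K) stop("composition vectors have different K")
  if (!identical(a$mode, b$mode)) stop("composition vectors have different mode")
  if (a$norm == 0 || b$norm == 0) {
    stop("zero-norm composition vector: correlation undefined")
  }
  idx <- match(a$keys, b$keys)
  ai <- which(!is.na(idx))
  # a$keys is sorted, so the common keys are visited in sorted order from
  # either argument and the accumulation is exactly symmetric
  C <- sum(a$entries[ai] * b$entries[idx[ai]]) / (a$norm * b$norm)
  C <- min(1, max(-1, C))
  list(correlation_C = C, distance_D = (1 - C) / 2)
}

#' CV distance between two sequences
#'
#' Shorthand for `cv_correlation(composition_vector(x, K, mode),
#' composition_vector(y, K, mode))$distance_D`.
#'
#' @param x,y DNA strings.
#' @inheritParams composition_vector
#' @return the distance `D = (1 - C)/2`.
#' @export
cv_distance <- function(x, y, K, mode = c("raw", "background")) {
  mode <- match.arg(mode)
  cv_correlation(composition_vector(x, K, mode),
                 composition_vector(y, K, mode))$distance_D
}

#' @export
print.composition_vector <- function(x, ...) {
  cat(sprintf(
    "Composition vector: K = %d (%s), L = %d, %d distinct k-mers, %d/%d windows\n",
    x$K, x$mode, x$L, length(x$keys), sum(x$counts), x$total_windows))
  invisible(x)
}

#' Dump a composition vector as TSV
#'
#' Writes columns `kstring`, `count`, `frequency` (or the signed entry in
#' background mode), sorted lexicographically.
#'
#' @param cv a `composition_vector`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cv_tsv <- function(cv, path) {
  stopifnot(inherits(cv, "composition_vector"))
  df <- data.frame(kstring = .decode_kstring(cv$keys, cv$K),
                   count = cv$counts,
                   frequency = cv$entries)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
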