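# Neighbor joining (Saitou-Nei) with a deterministic lexicographic tie-break,
# returning an ape "phylo" object. Textbook O(n^3): fast enough for a few
# thousand taxa, which covers barcoding datasets.

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step join the pair (i, j)
#' minimizing `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)`;
#' ties are broken by the smallest (row, column) index pair in the current
#' matrix, so runs are exactly reproducible. Limb lengths use the standard
#' formulas and may be negative; `clamp_negative = TRUE` sets a negative limb
#' to zero and moves the deficit to its sister branch (the PHYLIP-compatible
#' alternative). The result is unrooted with a trifurcation at the final
#' join.
#'
#' @param D symmetric distance matrix with zero diagonal and row names
#'   (asymmetry beyond 1e-9 is an error); at least 3 taxa.
#' @param clamp_negative clamp negative branch lengths (default keeps them,
#'   as stock PHYLIP neighbor reports them).
#' @return an [ape::phylo] object with tip labels taken from `rownames(D)`.
#' @examples
#' d <- matrix(c(0, 2, 4, 4, 2, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' tr <- neighbor_joining(d)
#' @export
neighbor_joining <- function(D, clamp_negative = FALSE) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (ncol(D) != n) stop("matrix is not square")
  if (max(abs(D - t(D))) > 1e-9) stop("matrix is asymmetric beyond 1e-9")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (anyDuplicated(labels)) stop("duplicate taxon labels")
  D <- (D + t(D)) / 2
  diag(D) <- 0

  ids <- seq_len(n)           # node id of each current matrix row
  next_id <- n + 1L           # temporary internal ids n+1, n+2, ...
  parent <- child <- integer(0)
  blen <- numeric(0)
  cur <- D

  while (nrow(cur) > 3L) {
    m <- nrow(cur)
    r <- rowSums(cur)
    Q <- (m - 2) * cur - outer(r, r, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    dij <- cur[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (clamp_negative) {
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- li + lj; lj <- 0 }
    }
    parent <- c(parent, next_id, next_id)
    child <- c(child, ids[i], ids[j])
    blen <- c(blen, li, lj)
    dnew <- (cur[i, ] + cur[j, ] - dij) / 2
    cur[i, ] <- dnew
    cur[, i] <- dnew
    cur[i, i] <- 0
    keep <- setdiff(seq_len(m), j)
    cur <- cur[keep, keep, drop = FALSE]
    ids[i] <- next_id
    ids <- ids[keep]
    next_id <- next_id + 1L
  }

  # final trifurcation: closed-form limbs l_a = (d_ab + d_ac - d_bc) / 2 etc.
  d12 <- cur[1L, 2L]; d13 <- cur[1L, 3L]; d23 <- cur[2L, 3L]
  limbs <- c((d12 + d13 - d23) / 2,
             (d12 + d23 - d13) / 2,
             (d13 + d23 - d12) / 2)
  if (clamp_negative) limbs <- pmax(limbs, 0)
  parent <- c(parent, rep(next_id, 3L))
  child <- c(child, ids)
  blen <- c(blen, limbs)

  .build_phylo(parent, child, blen, n, labels, root = next_id)
}

# renumber internal nodes to ape convention (tips 1..n, root n+1, internals
# in preorder) and emit edges in cladewise order
.build_phylo <- function(parent, child, blen, n, labels, root) {
  kids <- split(seq_along(parent), parent)    # edge indices by parent id
  n_internal <- length(kids)
  new_id <- integer(max(parent))
  edge <- matrix(0L, length(parent), 2L)
  len <- numeric(length(parent))
  cnt_node <- n
  cnt_edge <- 0L
  stack <- list(root)
  # iterative preorder; assign internal ids on first visit
  visit <- function(node) {
    cnt_node <<- cnt_node + 1L
    new_id[node] <<- cnt_node
    for (e in kids[[as.character(node)]]) {
      ch <- child[e]
      cnt_edge <<- cnt_edge + 1L
      row <- cnt_edge
      len[row] <<- blen[e]
      if (ch <= n) {
        edge[row, ] <<- c(new_id[node], ch)
      } else {
        edge[row, 1L] <<- new_id[node]
        visit(ch)
        edge[row, 2L] <<- new_id[ch]
      }
    }
  }
  visit(root)
  tr <- list(edge = edge, edge.length = len, tip.label = labels,
             Nnode = n_internal)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Write a tree as Newick
#'
#' Serializes with branch lengths at 10 significant digits and a terminating
#' `;`. Labels containing Newick metacharacters (parentheses, commas, colons,
#' semicolons, brackets, quotes or whitespace) are single-quoted.
#'
#' @param tree an [ape::phylo] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  writeLines(.newick_string(tree), path)
  invisible(path)
}

# serialized by hand (rather than ape::write.tree) so labels with Newick
# metacharacters are quoted, not rewritten
.newick_string <- function(tree, digits = 10L) {
  n <- length(tree$tip.label)
  lab <- tree$tip.label
  bad <- grepl("[\\s(),:;\\[\\]']", lab, perl = TRUE)
  lab[bad] <- paste0("'", gsub("'", "''", lab[bad]), "'")
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  has_len <- !is.null(tree$edge.length)
  rec <- function(node) {
    parts <- vapply(kids[[as.character(node)]], function(e) {
      ch <- tree$edge[e, 2L]
      s <- if (ch <= n) lab[ch] else rec(ch)
      if (has_len) {
        paste0(s, ":", formatC(tree$edge.length[e], digits = digits,
                               format = "g"))
      } else s
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Read a Newick tree
#'
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  # ape keeps the single quotes around quoted labels; strip them back off
  q <- grepl("^'.*'$", tr$tip.label)
  tr$tip.label[q] <- gsub("''", "'",
                          substr(tr$tip.label[q], 2L,
                                 nchar(tr$tip.label[q]) - 1L))
  tr
}
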