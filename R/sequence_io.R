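# FASTA / taxonomy / PHYLIP-distance I/O and multi-locus dataset assembly.
#
# Taxon identity defaults to the underscore header grammar
# "Genus_species_individual" (first token genus, second species, remainder
# individual); a TSV taxonomy map (sequence_id, genus, species[, individual])
# overrides it. Residues are upper-cased on ingestion; labels keep their case.

#' Parse taxon labels from sequence identifiers
#'
#' @param ids character vector of sequence identifiers.
#' @param scheme `"underscore"` splits each id on `_` into
#'   genus / species / individual (individual may be empty); `"map"` looks ids
#'   up in `taxonomy`.
#' @param taxonomy data frame with columns `sequence_id`, `genus`, `species`
#'   and optionally `individual`, e.g. from [read_taxonomy_map()].
#' @return data frame with columns `sequence_id`, `genus`, `species`,
#'   `individual`.
#' @export
parse_taxon_labels <- function(ids, scheme = c("underscore", "map"),
                               taxonomy = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "map") {
    if (is.null(taxonomy)) stop("scheme = \"map\" requires a taxonomy table")
    i <- match(ids, taxonomy$sequence_id)
    if (anyNA(i)) {
      stop("sequence ids missing from taxonomy map: ",
           paste(ids[is.na(i)], collapse = ", "))
    }
    ind <- if ("individual" %in% names(taxonomy)) taxonomy$individual[i] else ""
    out <- data.frame(sequence_id = ids, genus = taxonomy$genus[i],
                      species = taxonomy$species[i],
                      individual = as.character(ind),
                      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(ids, "_", fixed = TRUE)
    bad <- lengths(parts) < 2L
    if (any(bad)) {
      stop("cannot parse Genus_species[_individual] from: ",
           paste(ids[bad], collapse = ", "))
    }
    out <- data.frame(
      sequence_id = ids,
      genus = vapply(parts, `[[`, "", 1L),
      species = vapply(parts, `[[`, "", 2L),
      individual = vapply(parts, function(p)
        paste(p[-(1:2)], collapse = "_"), ""),
      stringsAsFactors = FALSE)
  }
  if (any(!nzchar(out$genus) | !nzchar(out$species))) {
    stop("empty genus or species name after parsing")
  }
  out
}

#' Read a taxonomy map
#'
#' Tab-separated file with header columns `sequence_id`, `genus`, `species`
#' and optionally `individual`.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_taxonomy_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "genus", "species")
  if (!all(need %in% names(tab))) {
    stop("taxonomy map must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$sequence_id)) {
    stop("duplicate sequence_id in taxonomy map")
  }
  tab
}

#' Read one locus from a FASTA file
#'
#' @param path FASTA file (one record per specimen at this locus).
#' @param locus locus name, e.g. `"matK"`.
#' @param scheme,taxonomy see [parse_taxon_labels()].
#' @return data frame of locus records: `sequence_id`, `genus`, `species`,
#'   `individual`, `locus`, `residues` (upper-cased), `length_L`.
#' @export
read_locus_fasta <- function(path, locus, scheme = c("underscore", "map"),
                             taxonomy = NULL) {
  scheme <- match.arg(scheme)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (!length(nonblank)) {
    warning("empty FASTA file: ", path)
    return(data.frame(sequence_id = character(0), genus = character(0),
                      species = character(0), individual = character(0),
                      locus = character(0), residues = character(0),
                      length_L = integer(0), stringsAsFactors = FALSE))
  }
  if (!startsWith(nonblank[[1L]], ">")) {
    stop("not a FASTA file (first record does not start with '>'): ", path)
  }
  hdr <- grepl("^>", lines)
  ids <- trimws(sub("^>\\s*", "", lines[hdr]))
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, "", 1L) # description dropped
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  seqs <- toupper(gsub("\\s", "", unname(seqs)))
  if (length(seqs) < length(ids)) seqs <- c(seqs, rep("", length(ids) - length(seqs)))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  }
  bad <- grepl("[^ACGTURYSWKMBDHVN.-]", seqs)
  if (any(bad)) {
    stop("non-nucleotide characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  labels <- parse_taxon_labels(ids, scheme, taxonomy)
  cbind(labels,
        data.frame(locus = locus, residues = seqs, length_L = nchar(seqs),
                   stringsAsFactors = FALSE))
}

#' Write locus records as FASTA
#'
#' @param records data frame as returned by [read_locus_fasta()].
#' @param path output file.
#' @param width line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$sequence_id[i]), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Assemble a multi-locus dataset
#'
#' Groups per-locus records by specimen. In strict mode (the default) every
#' taxon must have exactly one record per locus, matching the assumption of
#' the pairwise length-weighted distance combination; in non-strict mode taxa
#' are the union across loci and missing loci are recorded as `NA`.
#'
#' @param per_locus_records named list (locus -> record data frame from
#'   [read_locus_fasta()]).
#' @param strict require every taxon to be present at every locus.
#' @return object of class `multilocus_dataset`: list with `loci`, `taxa`
#'   (data frame of labels, one row per specimen), `sequences` (list locus ->
#'   character vector aligned with `taxa`, `NA` when absent), `lengths`
#'   (taxa x loci matrix of sequence lengths, `NA` when absent) and `strict`.
#' @export
assemble_dataset <- function(per_locus_records, strict = TRUE) {
  if (!length(per_locus_records)) stop("need at least one locus")
  if (is.null(names(per_locus_records)) || any(!nzchar(names(per_locus_records)))) {
    names(per_locus_records) <- vapply(per_locus_records,
                                       function(r) r$locus[1L], "")
  }
  loci <- names(per_locus_records)
  if (anyDuplicated(loci)) stop("duplicate locus names")
  for (g in loci) {
    if (!nrow(per_locus_records[[g]])) stop("no records for locus ", g)
  }
  id_sets <- lapply(per_locus_records, `[[`, "sequence_id")
  all_ids <- unique(unlist(id_sets, use.names = FALSE))
  if (strict) {
    missing <- lapply(id_sets, function(s) setdiff(all_ids, s))
    n_miss <- lengths(missing)
    if (any(n_miss > 0L)) {
      stop("strict mode: locus missing for some taxa: ",
           paste(sprintf("%s absent for [%s]", loci[n_miss > 0L],
                         vapply(missing[n_miss > 0L], paste, "",
                                collapse = ", ")),
                 collapse = "; "))
    }
  }
  # labels must agree wherever a specimen occurs
  labs <- do.call(rbind, lapply(per_locus_records, function(r)
    r[c("sequence_id", "genus", "species", "individual")]))
  labs <- unique(labs)
  if (anyDuplicated(labs$sequence_id)) {
    stop("conflicting taxon labels across loci for: ",
         paste(unique(labs$sequence_id[duplicated(labs$sequence_id)]),
               collapse = ", "))
  }
  taxa <- labs[match(all_ids, labs$sequence_id), , drop = FALSE]
  rownames(taxa) <- NULL
  sequences <- lapply(per_locus_records, function(r) {
    setNames(r$residues[match(all_ids, r$sequence_id)], all_ids)
  })
  lengths_mat <- vapply(sequences, nchar, integer(length(all_ids)))
  if (is.null(dim(lengths_mat))) {
    lengths_mat <- matrix(lengths_mat, nrow = length(all_ids),
                          dimnames = list(all_ids, loci))
  }
  dimnames(lengths_mat) <- list(all_ids, loci)
  structure(list(loci = loci, taxa = taxa, sequences = sequences,
                 lengths = lengths_mat, strict = strict),
            class = "multilocus_dataset")
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  ns <- length(unique(paste(x$taxa$genus, x$taxa$species)))
  cat(sprintf("Multi-locus dataset: %d specimens, %d species, %d genera\n",
              nrow(x$taxa), ns, length(unique(x$taxa$genus))))
  for (g in x$loci) {
    L <- x$lengths[, g]
    cat(sprintf("  %s: %d sequences, lengths %d-%d\n", g, sum(!is.na(L)),
                min(L, na.rm = TRUE), max(L, na.rm = TRUE)))
  }
  invisible(x)
}

#' Number of specimens in a dataset
#' @param x a `multilocus_dataset`.
#' @export
n_taxa <- function(x) nrow(x$taxa)

#' Write a distance matrix in PHYLIP square format
#'
#' First line is the taxon count; each row is a name field followed by the
#' distances. By default names are truncated/padded to the strict 10-character
#' PHYLIP field; `relaxed = TRUE` writes full names (up to 50 characters)
#' followed by whitespace.
#'
#' @param m square symmetric matrix with row names.
#' @param path output file.
#' @param relaxed write full names instead of the 10-character field.
#' @return `path`, invisibly.
#' @export
write_phylip_distmatrix <- function(m, path, relaxed = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix is not square")
  if (max(abs(m - t(m))) > 1e-9) stop("matrix is not symmetric")
  nm <- rownames(m)
  if (is.null(nm)) stop("matrix has no taxon names")
  if (any(grepl("\\s", nm))) stop("taxon names must not contain whitespace")
  if (relaxed) {
    if (any(nchar(nm) > 50L)) stop("names longer than 50 characters")
    field <- formatC(nm, width = max(nchar(nm)) + 2L, flag = "-")
  } else {
    short <- substr(nm, 1L, 10L)
    if (anyDuplicated(short)) {
      stop("taxon names collide when truncated to 10 characters (",
           paste(unique(short[duplicated(short)]), collapse = ", "),
           "); relabel or use relaxed = TRUE")
    }
    field <- formatC(short, width = 10L, flag = "-")
  }
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste0(field[i], paste(sprintf("%.6f", m[i, ]), collapse = "  ")), "")
  writeLines(c(sprintf("%5d", nrow(m)), rows), path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Accepts both the strict 10-character name field (without embedded spaces)
#' and the relaxed dialect of names up to 50 characters followed by
#' whitespace.
#'
#' @param path PHYLIP distance file.
#' @return symmetric matrix with dimnames.
#' @export
read_phylip_distmatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[[1L]]))
  if (is.na(n) || n < 1L) stop("bad taxon count header in ", path)
  if (length(lines) < n + 1L) stop("truncated PHYLIP matrix in ", path)
  nm <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1L]]
    nm[i] <- tok[[1L]]
    vals <- suppressWarnings(as.numeric(tok[-1L]))
    if (length(vals) != n || anyNA(vals)) {
      stop("row ", i, " does not contain ", n, " distances")
    }
    m[i, ] <- vals
  }
  dimnames(m) <- list(trimws(nm), trimws(nm))
  m
}
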