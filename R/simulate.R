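# Synthetic multi-locus barcoding datasets with known
# genus/species/individual structure. Jukes-Cantor-style independent
# per-site substitution along a fixed genus -> species -> individual
# hierarchy; optional short indels (1-5 bp, geometric run length) emulate
# non-coding spacer loci.

#' Simulation configuration
#'
#' @param n_genera,species_per_genus,individuals_per_species hierarchy sizes.
#' @param locus_specs data frame with columns `name`, `mean_length`,
#'   `length_sd`, `indel_rate` (per-site probability of an indel event).
#' @param genus_divergence,species_divergence,individual_divergence per-site
#'   substitution probabilities applied on the branch leading to each genus
#'   ancestor, species ancestor, and individual respectively.
#' @param seed integer RNG seed; the generated dataset is a deterministic
#'   function of the configuration.
#' @return object of class `sim_config`.
#' @seealso [sim_preset()] for the calibrated presets.
#' @export
sim_config <- function(n_genera = 5L, species_per_genus = 3L,
                       individuals_per_species = 3L,
                       locus_specs = data.frame(
                         name = c("matK", "rbcL", "trnH-psbA"),
                         mean_length = c(800L, 550L, 450L),
                         length_sd = c(10, 8, 25),
                         indel_rate = c(0, 0, 0.002)),
                       genus_divergence = 0.10,
                       species_divergence = 0.02,
                       individual_divergence = 0.002,
                       seed = 1L) {
  stopifnot(n_genera >= 1L, species_per_genus >= 1L,
            individuals_per_species >= 1L, nrow(locus_specs) >= 1L,
            all(c("name", "mean_length", "length_sd", "indel_rate") %in%
                  names(locus_specs)),
            genus_divergence >= 0, genus_divergence <= 1,
            species_divergence >= 0, species_divergence <= 1,
            individual_divergence >= 0, individual_divergence <= 1)
  structure(list(n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 individuals_per_species = as.integer(individuals_per_species),
                 locus_specs = locus_specs,
                 genus_divergence = genus_divergence,
                 species_divergence = species_divergence,
                 individual_divergence = individual_divergence,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Calibrated simulation presets
#'
#' `"easy"` is the reference well-behaved dataset: 5 genera x 3 species x 3
#' individuals, three loci of 800/550/450 bp (the last with indels), and
#' clearly ordered divergences 0.10 / 0.02 / 0.002, so genus, species and
#' individual signal are separable. `"degraded"` keeps the same shape but
#' sets the species divergence equal to the individual divergence, removing
#' the species-level signal.
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @return a `sim_config`.
#' @export
sim_preset <- function(name = c("easy", "degraded"), seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    easy = sim_config(seed = seed),
    degraded = sim_config(species_divergence = 0.002,
                          individual_divergence = 0.002, seed = seed))
  if (name == "easy") {
    stopifnot(cfg$genus_divergence > cfg$species_divergence,
              cfg$species_divergence > cfg$individual_divergence)
  }
  cfg
}

.BASES <- c("A", "C", "G", "T")

# substitute each site independently with probability rate (uniform over the
# three alternative bases); x is a character vector of single bases
.mutate <- function(x, rate) {
  if (rate <= 0) return(x)
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    x[hit] <- .BASES[(match(x[hit], .BASES) - 1L + shift) %% 4L + 1L]
  }
  x
}

# short insertions/deletions: event count ~ Binomial(L, rate), run length
# 1 + Geom(0.5) truncated at 5
.apply_indels <- function(x, rate) {
  if (rate <= 0) return(x)
  n_events <- rbinom(1L, length(x), rate)
  for (e in seq_len(n_events)) {
    len <- min(1L + rgeom(1L, 0.5), 5L)
    pos <- sample.int(length(x), 1L)
    if (runif(1L) < 0.5 && length(x) > len + 1L) {
      x <- x[-(pos:min(pos + len - 1L, length(x)))]
    } else {
      x <- append(x, sample(.BASES, len, replace = TRUE), after = pos)
    }
  }
  x
}

#' Simulate a multi-locus barcoding dataset
#'
#' Per locus: draw a uniform random root sequence at the drawn length, derive
#' each genus ancestor from it at `genus_divergence`, each species ancestor
#' from its genus ancestor at `species_divergence`, and each individual from
#' its species ancestor at `individual_divergence`; loci with
#' `indel_rate > 0` then receive short indels per individual. Sequence ids
#' follow the `Genus_species_individual` grammar. The full genealogy (root,
#' genus and species ancestors per locus) is attached as attribute `"truth"`.
#'
#' @param config a `sim_config`.
#' @return a `multilocus_dataset` (strict: every taxon has every locus) with
#'   attributes `truth` and `config`. The caller's RNG state is preserved.
#' @examples
#' ds <- simulate_dataset(sim_preset("easy", seed = 42))
#' ds
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(config$seed)

  genera <- sprintf("Genus%02d", seq_len(config$n_genera))
  species <- sprintf("sp%02d", seq_len(config$species_per_genus))
  inds <- sprintf("%02d", seq_len(config$individuals_per_species))

  truth <- list()
  per_locus <- list()
  for (r in seq_len(nrow(config$locus_specs))) {
    spec <- config$locus_specs[r, ]
    L <- max(20L, as.integer(round(rnorm(1L, spec$mean_length, spec$length_sd))))
    root <- sample(.BASES, L, replace = TRUE)
    gen_anc <- lapply(genera, function(g) .mutate(root, config$genus_divergence))
    names(gen_anc) <- genera
    sp_anc <- list()
    ids <- character(0)
    seqs <- character(0)
    gcol <- scol <- icol <- character(0)
    for (g in genera) {
      for (s in species) {
        anc <- .mutate(gen_anc[[g]], config$species_divergence)
        sp_anc[[paste(g, s)]] <- anc
        for (k in inds) {
          x <- .mutate(anc, config$individual_divergence)
          x <- .apply_indels(x, spec$indel_rate)
          ids <- c(ids, paste(g, s, k, sep = "_"))
          seqs <- c(seqs, paste0(x, collapse = ""))
          gcol <- c(gcol, g); scol <- c(scol, s); icol <- c(icol, k)
        }
      }
    }
    per_locus[[spec$name]] <- data.frame(
      sequence_id = ids, genus = gcol, species = scol, individual = icol,
      locus = spec$name, residues = seqs, length_L = nchar(seqs),
      stringsAsFactors = FALSE)
    truth[[spec$name]] <- list(root = paste0(root, collapse = ""),
                               genus_ancestors = vapply(gen_anc, paste0, "",
                                                        collapse = ""),
                               species_ancestors = vapply(sp_anc, paste0, "",
                                                          collapse = ""))
  }
  ds <- assemble_dataset(per_locus, strict = TRUE)
  attr(ds, "truth") <- truth
  attr(ds, "config") <- config
  ds
}

#' Write a simulated dataset to disk
#'
#' One FASTA per locus, a taxonomy TSV, and the configuration as JSON for
#' provenance.
#'
#' @param dataset a `multilocus_dataset` (typically from
#'   [simulate_dataset()]).
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multilocus_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (g in dataset$loci) {
    rec <- data.frame(sequence_id = rownames(dataset$lengths),
                      residues = dataset$sequences[[g]],
                      stringsAsFactors = FALSE)
    rec <- rec[!is.na(rec$residues), , drop = FALSE]
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", g), ".fasta"))
    write_locus_fasta(rec, f)
    files <- c(files, f)
  }
  tf <- file.path(dir, "taxonomy.tsv")
  write.table(dataset$taxa, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, tf)
  cfg <- attr(dataset, "config")
  if (!is.null(cfg)) {
    cf <- file.path(dir, "sim_config.json")
    jsonlite::write_json(unclass(cfg), cf, auto_unbox = TRUE, digits = NA)
    files <- c(files, cf)
  }
  invisible(files)
}
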