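## Synthetic repertoire cohorts: constraint-true CDR3 sequences with
## Gaussian lengths, heavy-tailed clonal abundances and class-discriminative
## planted motifs, so that every pipeline stage is testable offline.

#' Synthetic cohort configuration
#'
#' The generator emulates the statistical structure the classifier assumes:
#' CDR3 lengths follow a rounded Gaussian truncated to the admissible
#' 10-24 residue range (mean 14.5, sd 2.0, putting most sequences at the
#' commonly observed 12-16 residues), every sequence carries the canonical
#' C/F anchors and no forbidden characters, clonal abundances are
#' Zipf-distributed (heavy-tailed), and "cancer" bags carry short peptide
#' motifs planted at a higher per-instance rate than control bags.
#'
#' @param n_per_class samples (bags) per class.
#' @param clones_per_sample clonotypes generated per sample; must be at
#'   least `k`.
#' @param k bag size used downstream (default 100).
#' @param length_mean,length_sd Gaussian length parameters (residues).
#' @param length_range inclusive truncation bounds (default 10-24).
#' @param zipf_exponent exponent of the rank-frequency law (default 1.2).
#' @param motif_set character vector of 3-4 residue motifs over the
#'   20-letter alphabet.
#' @param motif_rate_case per-instance planting probability in cancer bags
#'   (default 0.3).
#' @param motif_rate_control per-instance planting probability in control
#'   bags (default 0.02).
#' @param background_freqs length-20 residue sampling weights for interior
#'   positions (default uniform).
#' @param n_classes 2 for the binary task; for `n_classes > 2`, class `j`
#'   (`j >= 1`) plants only `motif_set[j]`.
#' @param total_reads sequencing depth used to draw clone counts.
#' @param seed RNG seed.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_per_class = 100L, clones_per_sample = 120L, k = 100L,
                       length_mean = 14.5, length_sd = 2.0,
                       length_range = c(10L, 24L), zipf_exponent = 1.2,
                       motif_set = c("WQDY", "PRGH", "NKTE"),
                       motif_rate_case = 0.3, motif_rate_control = 0.02,
                       background_freqs = NULL, n_classes = 2L,
                       total_reads = 10000L, seed = 2024L) {
  background_freqs <- background_freqs %||% rep(1 / 20, 20)
  stopifnot(is_count(n_per_class), n_per_class >= 1,
            is_count(clones_per_sample), is_count(k), clones_per_sample >= k,
            length_sd > 0, length_range[1] <= length_range[2],
            motif_rate_case >= 0, motif_rate_case <= 1,
            motif_rate_control >= 0, motif_rate_control <= 1,
            length(background_freqs) == 20L, all(background_freqs >= 0),
            is_count(n_classes), n_classes >= 2)
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), motif_set)
  if (any(bad)) stopf("motif '%s' uses characters outside the amino-acid alphabet",
                      motif_set[which(bad)[1]])
  if (any(nchar(motif_set) < 2 | nchar(motif_set) > length_range[1] - 2)) {
    stopf("motifs must fit the interior of the shortest admissible sequence")
  }
  if (n_classes > 2L && length(motif_set) < n_classes - 1L) {
    stopf("need one motif per non-control class")
  }
  if (motif_rate_case <= motif_rate_control) {
    warnf("signal may be unlearnable: motif_rate_case <= motif_rate_control")
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 clones_per_sample = as.integer(clones_per_sample),
                 k = as.integer(k), length_mean = length_mean,
                 length_sd = length_sd,
                 length_range = as.integer(length_range),
                 zipf_exponent = zipf_exponent, motif_set = motif_set,
                 motif_rate_case = motif_rate_case,
                 motif_rate_control = motif_rate_control,
                 background_freqs = background_freqs / sum(background_freqs),
                 n_classes = as.integer(n_classes),
                 total_reads = as.integer(total_reads),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw synthetic CDR3 sequences
#'
#' Lengths are rounded Gaussian draws redrawn until they fall inside the
#' truncation range; the first residue is the cysteine anchor, the last the
#' phenylalanine anchor, and interior residues are sampled from the
#' background frequencies. Uses the current RNG state.
#'
#' @param config a [sim_config()].
#' @param n number of sequences.
#' @return character vector of CDR3 sequences.
#' @export
sample_cdr3 <- function(config, n = 1L) {
  lo <- config$length_range[1]; hi <- config$length_range[2]
  lens <- integer(0)
  while (length(lens) < n) {
    cand <- as.integer(round(stats::rnorm(n, config$length_mean, config$length_sd)))
    lens <- c(lens, cand[cand >= lo & cand <= hi])
  }
  lens <- lens[seq_len(n)]
  interior_total <- sum(lens - 2L)
  interior <- sample(AA_ALPHABET, interior_total, replace = TRUE,
                     prob = config$background_freqs)
  stops <- cumsum(lens - 2L)
  starts <- c(1L, utils::head(stops, -1) + 1L)
  vapply(seq_len(n), function(i) {
    paste0("C", paste(interior[starts[i]:stops[i]], collapse = ""), "F")
  }, character(1))
}

#' Plant a motif into a CDR3 interior
#'
#' Overwrites a uniformly chosen interior span with the motif, never
#' touching the C/F anchor residues; sequence length is unchanged. Uses the
#' current RNG state.
#'
#' @param seq a CDR3 string.
#' @param motif motif string; must satisfy
#'   `nchar(motif) <= nchar(seq) - 2`.
#' @return the modified sequence.
#' @export
plant_motif <- function(seq, motif) {
  L <- nchar(seq); ml <- nchar(motif)
  if (ml > L - 2L) stopf("motif of length %d does not fit the interior of a length-%d sequence", ml, L)
  start <- sample.int(L - ml - 1L, 1L) + 1L  # uniform on [2, L - ml]
  paste0(substr(seq, 1L, start - 1L), motif, substr(seq, start + ml, L))
}

## Zipf rank-frequency clone counts: heavy-tailed, assigned in random order
## so abundance is independent of motif planting.
zipf_counts <- function(n, exponent, total_reads) {
  w <- (seq_len(n))^(-exponent)
  w <- w / sum(w)
  counts <- as.integer(stats::rmultinom(1, total_reads, w[sample.int(n)]))
  counts
}

#' Generate a labelled synthetic cohort
#'
#' Builds `n_per_class` bags per class through the standard ingestion path
#' ([build_bag()] on the generated clone tables), so every generated
#' instance passes the default quality filters by construction. Case bags
#' plant a motif (uniformly chosen from `motif_set`) into each instance
#' with probability `motif_rate_case`; control bags with
#' `motif_rate_control`. Ground-truth planting flags are retained per
#' instance.
#'
#' @param config a [sim_config()].
#' @return an object of class `"tcr_cohort"`: `bags` (list of
#'   `"repertoire_bag"`, each instance table carrying a logical `motif`
#'   column), `labels`, and the `config` echo.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_bags <- config$n_per_class * config$n_classes
    labels <- rep(seq_len(config$n_classes) - 1L, each = config$n_per_class)
    bags <- vector("list", n_bags)
    tables <- vector("list", n_bags)
    for (b in seq_len(n_bags)) {
      lab <- labels[b]
      n <- config$clones_per_sample
      seqs <- sample_cdr3(config, n)
      rate <- if (lab == 0L) config$motif_rate_control else config$motif_rate_case
      motifs <- if (config$n_classes == 2L || lab == 0L) config$motif_set
                else config$motif_set[lab]
      flag <- stats::runif(n) < rate
      for (i in which(flag)) {
        seqs[i] <- plant_motif(seqs[i], sample(motifs, 1L))
      }
      counts <- zipf_counts(n, config$zipf_exponent, config$total_reads)
      clones <- tcr_clones(seqs, v_gene = sprintf("TRBV%d-1*00(%d)", (seq_len(n) %% 30L) + 1L, 100L),
                           clone_count = counts,
                           clone_fraction = counts / sum(counts))
      clones$motif <- flag
      bag <- build_bag(clones, k = config$k, pad_policy = "zero-pad",
                       sample_id = sprintf("S%03d_c%d", b, lab), label = lab)
      bags[[b]] <- bag
      tables[[b]] <- clones
    }
    names(tables) <- vapply(bags, function(b) b$sample_id, character(1))
    structure(list(bags = bags, labels = labels, tables = tables,
                   config = config),
              class = "tcr_cohort")
  })
}

#' @export
print.tcr_cohort <- function(x, ...) {
  cat(sprintf("synthetic TCR cohort: %d bags (%s), k = %d\n",
              length(x$bags),
              paste(sprintf("class %s: %d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", "),
              x$config$k))
  invisible(x)
}

#' Write a cohort as clone tables
#'
#' One MiXCR-dialect TSV per sample (readable by
#' [read_repertoire_table()]) plus a ground-truth sidecar JSON with labels
#' and planted-motif flags.
#'
#' @param cohort a `"tcr_cohort"`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  for (b in seq_along(cohort$bags)) {
    bag <- cohort$bags[[b]]
    inst <- if (!is.null(cohort$tables)) cohort$tables[[b]]
            else bag$instances[bag$mask, , drop = FALSE]
    tab <- data.frame(aaSeqCDR3 = inst$cdr3_aa,
                      allVHitsWithScore = inst$v_gene,
                      cloneCount = inst$clone_count,
                      cloneFraction = inst$clone_fraction,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(dir, paste0(bag$sample_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth[[bag$sample_id]] <- list(label = bag$label,
                                   motif = as.logical(inst$motif))
  }
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
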