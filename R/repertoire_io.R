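## Reading clone tables, CDR3 quality filtering, and bag construction.

#' MiXCR-style column mapping for clone tables
#'
#' Describes which columns of a tab-separated clone export hold the CDR3
#' amino-acid sequence, the V-gene annotation and the clonal abundance.
#' Defaults follow the MiXCR `exportClones` dialect; remap to ingest other
#' pipelines' exports.
#'
#' @param cdr3_aa column holding the CDR3 amino-acid sequence.
#' @param v_gene column holding the V-gene hit(s); may be absent from the file.
#' @param clone_count column holding the integer read/UMI count.
#' @param clone_fraction column holding the within-sample clone fraction.
#' @return a named list of class `"repertoire_dialect"`.
#' @export
repertoire_dialect <- function(cdr3_aa = "aaSeqCDR3",
                               v_gene = "allVHitsWithScore",
                               clone_count = "cloneCount",
                               clone_fraction = "cloneFraction") {
  structure(list(cdr3_aa = cdr3_aa, v_gene = v_gene,
                 clone_count = clone_count, clone_fraction = clone_fraction),
            class = "repertoire_dialect")
}

#' Construct a clone table
#'
#' A clone table is a plain `data.frame` with one row per clonotype and
#' columns `cdr3_aa`, `v_gene`, `clone_count`, `clone_fraction`.
#'
#' @param cdr3_aa character vector of CDR3 amino-acid sequences (uppercase).
#' @param v_gene character vector of V-gene annotations (`NA` when missing).
#' @param clone_count non-negative integer abundances.
#' @param clone_fraction relative abundances in `[0, 1]`, or `NA`.
#' @return a `data.frame` of clones.
#' @export
tcr_clones <- function(cdr3_aa, v_gene = NA_character_,
                       clone_count = NA_integer_, clone_fraction = NA_real_) {
  if (length(cdr3_aa) == 0L) {
    return(data.frame(cdr3_aa = character(0), v_gene = character(0),
                      clone_count = double(0), clone_fraction = double(0),
                      stringsAsFactors = FALSE))
  }
  if (any(!nzchar(cdr3_aa) | is.na(cdr3_aa))) {
    stopf("cdr3_aa must be non-empty strings")
  }
  cf <- as.double(clone_fraction)
  if (any(!is.na(cf) & (cf < 0 | cf > 1))) {
    stopf("clone_fraction must lie in [0, 1]")
  }
  cc <- suppressWarnings(as.double(clone_count))
  if (any(!is.na(cc) & cc < 0)) stopf("clone_count must be non-negative")
  data.frame(cdr3_aa = as.character(cdr3_aa),
             v_gene = as.character(v_gene),
             clone_count = cc,
             clone_fraction = cf,
             stringsAsFactors = FALSE)
}

#' Read a per-sample clone table
#'
#' Parses a tab-separated clone export into a clone table. Rows whose
#' abundance does not parse as a number get `clone_count` 0; the original
#' row order is retained.
#'
#' @param path path to a TSV file with a header line.
#' @param dialect a [repertoire_dialect()] mapping column names.
#' @return a clone `data.frame` as from [tcr_clones()].
#' @export
read_repertoire_table <- function(path, dialect = repertoire_dialect()) {
  if (!file.exists(path)) stopf("clone table not found: %s", path)
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, colClasses = "character"),
    error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0L) {
    warnf("clone table is empty: %s", path)
    return(tcr_clones(character(0)))
  }
  if (!dialect$cdr3_aa %in% names(tab)) {
    stopf("missing mandatory column '%s' in %s", dialect$cdr3_aa, path)
  }
  has_count <- dialect$clone_count %in% names(tab)
  has_frac <- dialect$clone_fraction %in% names(tab)
  if (!has_count && !has_frac) {
    stopf("missing abundance column: need '%s' or '%s' in %s",
          dialect$clone_count, dialect$clone_fraction, path)
  }
  n <- nrow(tab)
  vg <- if (dialect$v_gene %in% names(tab)) tab[[dialect$v_gene]] else rep(NA_character_, n)
  cc <- if (has_count) suppressWarnings(as.double(tab[[dialect$clone_count]])) else rep(NA_real_, n)
  cc[has_count & is.na(cc)] <- 0
  cf <- if (has_frac) suppressWarnings(as.double(tab[[dialect$clone_fraction]])) else rep(NA_real_, n)
  out <- data.frame(cdr3_aa = as.character(tab[[dialect$cdr3_aa]]),
                    v_gene = as.character(vg),
                    clone_count = cc, clone_fraction = cf,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' CDR3 quality-filter criteria
#'
#' The four sequence-quality criteria applied to every clonotype, in the
#' order in which rejections are attributed: (i) resolved V-gene locus,
#' (ii) no special characters, (iii) canonical cysteine/phenylalanine
#' anchors, (iv) admissible length.
#'
#' @param min_len,max_len admissible CDR3 length range in residues.
#' @param forbidden_chars characters whose presence rejects a sequence.
#' @param required_start,required_end required first/last residue.
#' @param require_resolved_v reject clones whose V gene is ambiguous or absent.
#' @param strict_v when `TRUE`, any multi-hit V annotation is ambiguous;
#'   when `FALSE` (default) a multi-hit annotation with a unique top score
#'   counts as resolved.
#' @return an object of class `"filter_criteria"`.
#' @export
filter_criteria <- function(min_len = 10L, max_len = 24L,
                            forbidden_chars = c("X", "*", "_"),
                            required_start = "C", required_end = "F",
                            require_resolved_v = TRUE, strict_v = FALSE) {
  stopifnot(is_count(min_len), is_count(max_len), min_len <= max_len)
  if (any(forbidden_chars %in% c(required_start, required_end))) {
    stopf("forbidden characters must be disjoint from the anchor residues")
  }
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 forbidden_chars = forbidden_chars,
                 required_start = required_start, required_end = required_end,
                 require_resolved_v = isTRUE(require_resolved_v),
                 strict_v = isTRUE(strict_v)),
            class = "filter_criteria")
}

## A V annotation is resolved when present and unambiguous. MiXCR writes
## multi-hit annotations as "TRBV7-9*00(1200),TRBV7-8*00(1100)"; under the
## lenient policy a strictly best-scoring hit resolves the locus.
v_gene_resolved <- function(v_gene, strict = FALSE) {
  vapply(v_gene, function(v) {
    if (is.na(v) || !nzchar(v)) return(FALSE)
    hits <- strsplit(v, ",", fixed = TRUE)[[1]]
    hits <- hits[nzchar(hits)]
    if (length(hits) == 0L) return(FALSE)
    if (length(hits) == 1L) return(TRUE)
    if (strict) return(FALSE)
    scores <- suppressWarnings(as.double(sub(".*\\(([-0-9.eE+]+)\\)\\s*$", "\\1", hits)))
    if (any(is.na(scores))) return(FALSE)
    s <- sort(scores, decreasing = TRUE)
    s[1] > s[2]
  }, logical(1), USE.NAMES = FALSE)
}

#' Apply the CDR3 quality filters
#'
#' Retains clonotypes satisfying all criteria; every rejected clone is
#' attributed to the first criterion it fails, in the order
#' resolved-V, special characters, anchors, length. Filtering is pure and
#' idempotent.
#'
#' @param clones a clone `data.frame` ([tcr_clones()]).
#' @param criteria a [filter_criteria()] object.
#' @return a list with `survivors` (clone `data.frame`) and `report`
#'   (class `"filter_report"`: input/pass counts, per-criterion rejections,
#'   survivor length histogram).
#' @export
filter_clones <- function(clones, criteria = filter_criteria()) {
  n <- nrow(clones)
  crit_names <- c("unresolved_v", "forbidden_chars", "anchors", "length")
  rej <- stats::setNames(integer(4), crit_names)
  if (n == 0L) {
    report <- structure(list(n_input = 0L, n_pass = 0L, rejections = rej,
                             length_histogram = length_histogram(clones)),
                        class = "filter_report")
    return(list(survivors = clones, report = report))
  }
  seqs <- clones$cdr3_aa
  len <- nchar(seqs)
  ok_v <- if (criteria$require_resolved_v) {
    v_gene_resolved(clones$v_gene, strict = criteria$strict_v)
  } else rep(TRUE, n)
  cls <- vapply(criteria$forbidden_chars, function(ch) {
    if (ch %in% c("]", "\\", "^", "-")) paste0("\\", ch) else ch
  }, character(1))
  ok_chars <- !grepl(paste0("[", paste(cls, collapse = ""), "]"), seqs)
  ok_anchor <- startsWith(seqs, criteria$required_start) &
    endsWith(seqs, criteria$required_end)
  ok_len <- len >= criteria$min_len & len <= criteria$max_len
  first_fail <- rep(0L, n)
  first_fail[!ok_len] <- 4L
  first_fail[!ok_anchor] <- 3L
  first_fail[!ok_chars] <- 2L
  first_fail[!ok_v] <- 1L
  keep <- first_fail == 0L
  tab <- tabulate(first_fail, nbins = 4L)
  rej[] <- tab
  survivors <- clones[keep, , drop = FALSE]
  rownames(survivors) <- NULL
  report <- structure(list(n_input = n, n_pass = sum(keep), rejections = rej,
                           length_histogram = length_histogram(survivors)),
                      class = "filter_report")
  list(survivors = survivors, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("CDR3 filter report: %d of %d clones retained (%.1f%%)\n",
              x$n_pass, x$n_input, if (x$n_input) 100 * x$n_pass / x$n_input else 100))
  cat("rejections by first failing criterion:\n")
  for (nm in names(x$rejections)) cat(sprintf("  %-16s %d\n", nm, x$rejections[[nm]]))
  invisible(x)
}

#' CDR3 length histogram
#'
#' @param clones a clone `data.frame`.
#' @return a named integer vector, names are lengths; counts sum to `nrow(clones)`.
#' @export
length_histogram <- function(clones) {
  if (nrow(clones) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(nchar(clones$cdr3_aa))
  stats::setNames(as.integer(tab), names(tab))
}

## Abundance key: clone fraction when available, else clone count.
clone_abundance <- function(clones) {
  ab <- clones$clone_fraction
  use_count <- is.na(ab)
  ab[use_count] <- clones$clone_count[use_count]
  ab[is.na(ab)] <- 0
  ab
}

#' Build a fixed-size repertoire bag
#'
#' Selects the `k` most abundant surviving clonotypes of a sample as the
#' instances of a multiple-instance bag. Abundance ties are broken by
#' lexicographic CDR3, then input order, so the bag is a deterministic
#' function of the survivor multiset. Samples with fewer than `k`
#' survivors are completed according to `pad_policy`: `"zero-pad"` leaves
#' the trailing slots empty with a `FALSE` mask, `"resample"` recycles the
#' survivors cyclically with a `TRUE` mask.
#'
#' @param survivors filtered clone `data.frame`.
#' @param k bag size (default 100).
#' @param pad_policy `"zero-pad"` or `"resample"`.
#' @param sample_id sample identifier.
#' @param label class label: 0 = healthy, 1 = cancer (or a class index).
#' @param dedupe collapse rows sharing one CDR3 amino-acid sequence (distinct
#'   nucleotide clones converging on the same receptor) into a single
#'   clonotype with summed abundance before ranking. Off by default:
#'   convergent clones are genuine repeated evidence and the ranking already
#'   aggregates within each row.
#' @return an object of class `"repertoire_bag"` with fields `sample_id`,
#'   `label`, `instances` (a `k`-row clone `data.frame`; padded rows `NA`),
#'   `mask` (logical `k`-vector) and `k`.
#' @export
build_bag <- function(survivors, k = 100L, pad_policy = c("zero-pad", "resample"),
                      sample_id = "sample", label = NA_integer_, dedupe = FALSE) {
  pad_policy <- match.arg(pad_policy)
  stopifnot(is_count(k), k >= 1)
  k <- as.integer(k)
  if (isTRUE(dedupe) && nrow(survivors) > 0L) {
    first <- !duplicated(survivors$cdr3_aa)
    cc <- rowsum(ifelse(is.na(survivors$clone_count), 0, survivors$clone_count),
                 survivors$cdr3_aa, reorder = FALSE)
    cf <- rowsum(ifelse(is.na(survivors$clone_fraction), 0, survivors$clone_fraction),
                 survivors$cdr3_aa, reorder = FALSE)
    dd <- survivors[first, , drop = FALSE]
    dd$clone_count <- as.numeric(cc[match(dd$cdr3_aa, rownames(cc)), 1L])
    dd$clone_fraction <- if (all(is.na(survivors$clone_fraction))) NA_real_
                         else as.numeric(cf[match(dd$cdr3_aa, rownames(cf)), 1L])
    survivors <- dd
  }
  n <- nrow(survivors)
  if (n == 0L) stopf("empty repertoire after filtering")
  ab <- clone_abundance(survivors)
  ord <- order(-ab, survivors$cdr3_aa, seq_len(n))
  take <- ord[seq_len(min(k, n))]
  inst <- survivors[take, , drop = FALSE]
  inst$abundance <- ab[take]
  mask <- rep(TRUE, nrow(inst))
  if (nrow(inst) < k) {
    n_pad <- k - nrow(inst)
    if (pad_policy == "zero-pad") {
      pad <- inst[rep(NA_integer_, n_pad), , drop = FALSE]
      mask <- c(mask, rep(FALSE, n_pad))
    } else {
      idx <- rep(seq_len(nrow(inst)), length.out = n_pad)
      pad <- inst[idx, , drop = FALSE]
      mask <- c(mask, rep(TRUE, n_pad))
    }
    inst <- rbind(inst, pad)
  }
  rownames(inst) <- NULL
  structure(list(sample_id = as.character(sample_id), label = label,
                 instances = inst, mask = mask, k = k),
            class = "repertoire_bag")
}

#' @export
print.repertoire_bag <- function(x, ...) {
  cat(sprintf("repertoire bag '%s': %d/%d real instances, label %s\n",
              x$sample_id, sum(x$mask), x$k,
              if (is.na(x$label)) "unlabelled" else x$label))
  invisible(x)
}

#' Write a bag manifest
#'
#' One TSV row per slot: sample id, rank, CDR3, abundance, masked flag.
#'
#' @param bag a [build_bag()] result.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_bag_manifest <- function(bag, path) {
  man <- data.frame(sample_id = bag$sample_id, rank = seq_len(bag$k),
                    cdr3_aa = bag$instances$cdr3_aa,
                    abundance = bag$instances$abundance,
                    masked = !bag$mask, stringsAsFactors = FALSE)
  utils::write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a filter report as JSON
#'
#' @param report a `"filter_report"` object.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    list(n_input = report$n_input, n_pass = report$n_pass,
         rejections = as.list(report$rejections),
         length_histogram = as.list(report$length_histogram)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
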