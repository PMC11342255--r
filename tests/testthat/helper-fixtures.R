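# Shared fixtures, built in code at test time.

# random filter-clean CDR3 strings
random_cdr3 <- function(n, min_len = 10, max_len = 24) {
  vapply(seq_len(n), function(i) {
    l <- sample(min_len:max_len, 1)
    paste0("C", paste(sample(tcrmil:::AA_ALPHABET, l - 2, replace = TRUE),
                      collapse = ""), "F")
  }, character(1))
}

# clone table mixing clean and dirty rows
random_clone_table <- function(n, seed = NULL, dirty_frac = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- random_cdr3(n)
  dirty <- sample(n, round(dirty_frac * n))
  for (i in dirty) {
    seqs[i] <- switch(sample(4, 1),
      sub("^C", "A", seqs[i]),                        # bad start anchor
      paste0(substr(seqs[i], 1, 4), "*",
             substr(seqs[i], 6, nchar(seqs[i]))),     # forbidden char
      substr(seqs[i], 1, 8),                          # too short (still C...?)
      paste0(seqs[i], paste(rep("A", 20), collapse = ""), "F"))  # too long
  }
  vg <- sprintf("TRBV%d-1*00(%d)", sample(30, n, TRUE), sample(500:1500, n, TRUE))
  vg[sample(n, max(1, round(0.05 * n)))] <- NA
  tcr_clones(seqs, v_gene = vg, clone_count = sample(0:500, n, TRUE))
}

# a small embedded cohort for engine-level tests
tiny_embedded_cohort <- function(n_bags = 4, k = 5, d = 6, seed = 1) {
  set.seed(seed)
  bags <- lapply(seq_len(n_bags), function(b) {
    n_real <- sample(2:k, 1)
    ms <- lapply(seq_len(n_real), function(i) {
      matrix(rnorm(sample(10:14, 1) * d), ncol = d)
    })
    eb <- pad_and_stack(ms, k = k, Lmax = 24)
    eb$label <- (b - 1L) %% 2L
    eb$sample_id <- paste0("bag", b)
    eb
  })
  structure(list(bags = bags,
                 labels = vapply(bags, function(b) b$label, integer(1)),
                 sample_ids = vapply(bags, function(b) b$sample_id, character(1)),
                 fingerprint = list(name = "test")),
            class = "embedded_cohort")
}

# cache shared across acceptance tests (embedding the default cohort once)
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function(null_signal = FALSE) {
  key <- if (null_signal) "null" else "signal"
  if (is.null(.acceptance_cache[[key]])) {
    cfg <- if (null_signal) {
      suppressWarnings(sim_config(seed = 20260924, motif_rate_case = 0.02,
                                  motif_rate_control = 0.02))
    } else {
      sim_config(seed = 20260924)
    }
    cohort <- generate_cohort(cfg)
    backend <- mini_encoder(d_model = 32, seed = 101)
    .acceptance_cache[[key]] <- embed_cohort(cohort, backend)
  }
  .acceptance_cache[[key]]
}
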