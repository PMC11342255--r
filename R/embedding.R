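## Per-residue embedding of CDR3 sequences: tokenisation, scaled dot-product
## attention, and three pluggable backends.

TOKEN_CLS <- 21L
TOKEN_SEP <- 22L
TOKEN_PAD <- 23L
VOCAB_SIZE <- 23L

#' Tokenize a CDR3 amino-acid sequence
#'
#' Encodes each residue as an integer token over the 20-letter alphabet and
#' brackets the sequence with begin/end marker tokens.
#'
#' @param cdr3_aa a non-empty uppercase amino-acid string.
#' @return an object of class `"token_sequence"` with `tokens` (integer ids,
#'   including the begin/end markers) and `source_len` (number of residues).
#' @export
tokenize <- function(cdr3_aa) {
  if (!is.character(cdr3_aa) || length(cdr3_aa) != 1L || is.na(cdr3_aa) ||
      !nzchar(cdr3_aa)) {
    stopf("cdr3_aa must be a single non-empty string")
  }
  chars <- strsplit(cdr3_aa, "")[[1]]
  ids <- match(chars, AA_ALPHABET)
  if (anyNA(ids)) {
    stopf("unknown residue '%s' in sequence '%s'", chars[which(is.na(ids))[1]], cdr3_aa)
  }
  structure(list(tokens = c(TOKEN_CLS, ids, TOKEN_SEP),
                 source_len = length(ids)),
            class = "token_sequence")
}

#' Scaled dot-product attention scores
#'
#' Pairwise scores between query and key rows, scaled by the square root of
#' the key dimension to stabilise gradients: \eqn{QK^T / \sqrt{d_k}}.
#'
#' @param Q query matrix, `n x d_k`.
#' @param K key matrix, `n x d_k`.
#' @param d_k key dimension (defaults to `ncol(K)`).
#' @return the `n x n` score matrix.
#' @export
attention_scores <- function(Q, K, d_k = ncol(K)) {
  Q <- as.matrix(Q); K <- as.matrix(K)
  if (ncol(Q) != ncol(K)) stopf("Q and K must have the same column dimension")
  if (!is_count(d_k) || d_k < 1) stopf("d_k must be a positive integer")
  tcrossprod(Q, K) / sqrt(d_k)
}

#' Scaled dot-product attention
#'
#' Softmax-normalises the scaled scores row-wise and uses them as weights on
#' the value rows: \eqn{A(Q,K,V) = \mathrm{softmax}(QK^T/\sqrt{d_k})\,V}.
#'
#' @param Q,K matrices `n x d_k`.
#' @param V value matrix `n x d_v`.
#' @param d_k key dimension (defaults to `ncol(K)`).
#' @return the `n x d_v` attended output.
#' @export
attention <- function(Q, K, V, d_k = ncol(K)) {
  V <- as.matrix(V)
  s <- attention_scores(Q, K, d_k)
  if (nrow(V) != ncol(s)) stopf("V must have one row per key")
  row_softmax(s) %*% V
}

## Sinusoidal positional encodings, max_len x d.
positional_encoding <- function(max_len, d) {
  pos <- seq_len(max_len) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 1 / 10000^(2 * floor(i / 2) / d))
  pe <- matrix(0, max_len, d)
  even <- i %% 2 == 0
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

layer_norm <- function(x, eps = 1e-6) {
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  (x - mu) / sqrt(v + eps)
}

#' Self-contained attention encoder backend
#'
#' A small randomly-initialised multi-head self-attention stack (token
#' embeddings + sinusoidal positional encodings; per layer, multi-head
#' attention and a position-wise feed-forward sublayer, each with a residual
#' connection and layer normalisation). Weights are drawn once from a seeded
#' normal distribution and then frozen, so the encoder is a deterministic,
#' context-sensitive featuriser that exercises the attention arithmetic
#' without any pretrained checkpoint.
#'
#' @param d_model embedding width per residue (default 32).
#' @param n_layers number of attention layers (default 2).
#' @param n_heads attention heads per layer (default 4); must divide `d_model`.
#' @param seed RNG seed for the frozen weights.
#' @return an embedding backend of class `c("mini_encoder", "tcr_embedder")`.
#' @export
mini_encoder <- function(d_model = 32L, n_layers = 2L, n_heads = 4L, seed = 101L) {
  stopifnot(is_count(d_model), is_count(n_layers), is_count(n_heads))
  if (d_model %% n_heads != 0L) stopf("d_model must be divisible by n_heads")
  d_k <- d_model %/% n_heads
  rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  weights <- with_seed(seed, {
    list(
      tok = rmat(VOCAB_SIZE, d_model, 1),
      layers = lapply(seq_len(n_layers), function(l) {
        list(Wq = lapply(seq_len(n_heads), function(h) rmat(d_model, d_k, 1 / sqrt(d_model))),
             Wk = lapply(seq_len(n_heads), function(h) rmat(d_model, d_k, 1 / sqrt(d_model))),
             Wv = lapply(seq_len(n_heads), function(h) rmat(d_model, d_k, 1 / sqrt(d_model))),
             Wo = rmat(d_model, d_model, 1 / sqrt(d_model)),
             W1 = rmat(d_model, 2L * d_model, 1 / sqrt(d_model)),
             b1 = stats::rnorm(2L * d_model, sd = 0.1),
             W2 = rmat(2L * d_model, d_model, 1 / sqrt(2 * d_model)),
             b2 = stats::rnorm(d_model, sd = 0.1))
      }))
  })
  structure(list(name = "mini_encoder", d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d_k = d_k, seed = as.integer(seed),
                 pe = positional_encoding(64L, d_model),
                 weights = weights),
            class = c("mini_encoder", "tcr_embedder"))
}

#' Physicochemical lookup backend
#'
#' Embeds each residue as the corresponding row of a user-supplied
#' 20-row amino-acid property matrix (rows in the alphabetical residue
#' order `ACDEFGHIKLMNPQRSTVWY`).
#'
#' @param table numeric matrix with 20 rows (one per residue) and one column
#'   per property; conventionally 15 properties.
#' @return an embedding backend of class `c("physicochemical", "tcr_embedder")`.
#' @seealso [synthetic_property_table()] for a documented stand-in table.
#' @export
physicochemical_backend <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 20L) stopf("property table must have 20 rows (one per residue)")
  if (!all(is.finite(table))) stopf("property table must be finite")
  rownames(table) <- AA_ALPHABET
  structure(list(name = "physicochemical", d_model = ncol(table),
                 table = table, seed = NA_integer_),
            class = c("physicochemical", "tcr_embedder"))
}

#' Synthetic amino-acid property table
#'
#' A deterministic, seeded stand-in for a published 20 x 15 amino-acid
#' physicochemical property matrix. It is *synthetic*: the values are
#' standard-normal draws, not measured properties, and exist so the
#' physicochemical code path can be exercised without bundling third-party
#' data. Supply a real property matrix for scientific use.
#'
#' @param n_properties number of property columns (default 15).
#' @param seed RNG seed.
#' @return a 20 x `n_properties` numeric matrix with residue rownames.
#' @export
synthetic_property_table <- function(n_properties = 15L, seed = 7L) {
  tab <- with_seed(seed, matrix(stats::rnorm(20L * n_properties), 20L, n_properties))
  rownames(tab) <- AA_ALPHABET
  colnames(tab) <- paste0("prop", seq_len(n_properties))
  tab
}

#' Pretrained protein-language-model adapter
#'
#' Declares the architecture contract of the pretrained transformer protein
#' language model used for full-scale analyses: 12 self-attention layers of
#' 12 heads each, hidden width 768 (so each residue embeds as a 768-vector
#' and the per-head key dimension is 64). The checkpoint itself is not
#' bundled; embedding requires a user-supplied `loader` function mapping a
#' character vector of sequences to a list of `L x 768` matrices. Without a
#' loader, calling [embed_sequence()] on this backend fails with advice to
#' use [mini_encoder()] instead.
#'
#' @param loader optional function `character -> list of L x 768 matrices`.
#' @return an embedding backend of class `c("pretrained_plm", "tcr_embedder")`.
#' @export
pretrained_plm <- function(loader = NULL) {
  structure(list(name = "pretrained_plm", d_model = 768L, n_layers = 12L,
                 n_heads = 12L, d_k = 64L, loader = loader, seed = NA_integer_),
            class = c("pretrained_plm", "tcr_embedder"))
}

#' Embed one CDR3 sequence
#'
#' Maps a tokenised sequence to an `L x D` matrix of per-residue embeddings,
#' where `L` is the residue count and `D` the backend's width. Marker-token
#' rows emitted by transformer backends are stripped so that row `i`
#' corresponds to residue `i`.
#'
#' @param tokens a [tokenize()] result, or a character CDR3 to tokenize.
#' @param backend an embedding backend ([mini_encoder()],
#'   [physicochemical_backend()], [pretrained_plm()]).
#' @return a numeric `L x D` matrix.
#' @export
embed_sequence <- function(tokens, backend) {
  if (is.character(tokens)) tokens <- tokenize(tokens)
  stopifnot(inherits(tokens, "token_sequence"))
  embed_tokens(backend, tokens)
}

embed_tokens <- function(backend, tokens) UseMethod("embed_tokens")

#' @keywords internal
#' @export
embed_tokens.default <- function(backend, tokens) {
  stopf("unknown embedding backend")
}

#' @keywords internal
#' @export
embed_tokens.mini_encoder <- function(backend, tokens) {
  ids <- tokens$tokens
  n <- length(ids)
  w <- backend$weights
  x <- w$tok[ids, , drop = FALSE] + backend$pe[seq_len(n), , drop = FALSE]
  for (ly in w$layers) {
    heads <- lapply(seq_len(backend$n_heads), function(h) {
      attention(x %*% ly$Wq[[h]], x %*% ly$Wk[[h]], x %*% ly$Wv[[h]])
    })
    x <- layer_norm(x + do.call(cbind, heads) %*% ly$Wo)
    ff <- pmax(sweep(x %*% ly$W1, 2L, ly$b1, "+"), 0) %*% ly$W2
    x <- layer_norm(x + sweep(ff, 2L, ly$b2, "+"))
  }
  ## strip the begin/end marker rows: exactly L x D
  x[seq.int(2L, n - 1L), , drop = FALSE]
}

#' @keywords internal
#' @export
embed_tokens.physicochemical <- function(backend, tokens) {
  ids <- tokens$tokens
  ids <- ids[ids <= 20L]
  backend$table[ids, , drop = FALSE]
}

#' @keywords internal
#' @export
embed_tokens.pretrained_plm <- function(backend, tokens) {
  if (is.null(backend$loader)) {
    stopf(paste("pretrained protein-language-model weights are not available;",
                "supply a loader to pretrained_plm() or use the mini_encoder backend"))
  }
  seq <- paste(AA_ALPHABET[tokens$tokens[tokens$tokens <= 20L]], collapse = "")
  out <- backend$loader(seq)[[1]]
  if (nrow(out) == tokens$source_len + 2L) {
    out <- out[seq.int(2L, nrow(out) - 1L), , drop = FALSE]
  }
  if (nrow(out) != tokens$source_len) {
    stopf("loader returned %d rows for a %d-residue sequence", nrow(out), tokens$source_len)
  }
  out
}

## Backend fingerprint recorded in caches and model objects.
backend_fingerprint <- function(backend) {
  list(name = backend$name, d_model = backend$d_model,
       n_layers = backend$n_layers %||% NA_integer_,
       n_heads = backend$n_heads %||% NA_integer_,
       seed = backend$seed)
}

#' Pad per-sequence embeddings into a bag tensor
#'
#' Stacks up to `k` embedding matrices into a `k x Lmax x D` array, zero
#' padding rows beyond each instance's true length and whole slots beyond
#' the instance list. Padding is inert: the sum of absolute values of the
#' tensor equals the sum over the input matrices.
#'
#' @param embeddings list of `L x D` matrices (possibly empty).
#' @param k bag size.
#' @param Lmax padded sequence length (default 24, the maximum admissible
#'   CDR3 length).
#' @param d embedding width; inferred from the first matrix when omitted.
#' @return an object of class `"embedded_bag"`: `tensor` (`k x Lmax x D`),
#'   `lengths` (true residue counts, 0 for empty slots) and `mask`.
#' @export
pad_and_stack <- function(embeddings, k, Lmax = 24L, d = NULL) {
  stopifnot(is_count(k), k >= 1, is_count(Lmax))
  if (length(embeddings) > k) stopf("more embeddings (%d) than bag slots (%d)", length(embeddings), k)
  if (is.null(d)) {
    d <- if (length(embeddings)) ncol(embeddings[[1]]) else 1L
  }
  tensor <- array(0, dim = c(k, Lmax, d))
  lengths <- integer(k)
  for (i in seq_along(embeddings)) {
    e <- as.matrix(embeddings[[i]])
    if (nrow(e) > Lmax) stopf("sequence length %d exceeds Lmax %d", nrow(e), Lmax)
    tensor[i, seq_len(nrow(e)), ] <- e
    lengths[i] <- nrow(e)
  }
  structure(list(tensor = tensor, lengths = lengths,
                 mask = lengths > 0L, Lmax = as.integer(Lmax), d = d),
            class = "embedded_bag")
}

#' Recover the per-sequence matrices from a bag tensor
#'
#' Inverse of [pad_and_stack()] for the real (unmasked) slots.
#'
#' @param ebag an `"embedded_bag"`.
#' @return list of `L x D` matrices, one per real instance.
#' @export
unstack_bag <- function(ebag) {
  lapply(which(ebag$mask), function(i) {
    l <- ebag$lengths[i]
    matrix(ebag$tensor[i, seq_len(l), ], nrow = l, ncol = ebag$d)
  })
}

#' Embed a repertoire bag
#'
#' @param bag a [build_bag()] result.
#' @param backend an embedding backend.
#' @param Lmax padded length (default 24).
#' @param cache optional environment mapping CDR3 string -> embedding matrix,
#'   shared across bags to avoid recomputing repeated clonotypes.
#' @return an `"embedded_bag"` carrying the bag's `sample_id` and `label`.
#' @export
embed_bag <- function(bag, backend, Lmax = 24L, cache = NULL) {
  seqs <- bag$instances$cdr3_aa[bag$mask]
  embs <- lapply(seqs, function(s) {
    if (!is.null(cache)) {
      hit <- cache[[s]]
      if (!is.null(hit)) return(hit)
    }
    e <- embed_sequence(s, backend)
    if (!is.null(cache)) cache[[s]] <- e
    e
  })
  ## real instances occupy the leading slots of a bag by construction
  eb <- pad_and_stack(embs, k = bag$k, Lmax = Lmax, d = backend$d_model)
  eb$sample_id <- bag$sample_id
  eb$label <- bag$label
  eb
}

#' Embed every bag of a cohort
#'
#' @param cohort a `"tcr_cohort"` (see [generate_cohort()]) or a plain list
#'   of `"repertoire_bag"` objects.
#' @param backend an embedding backend.
#' @param Lmax padded length (default 24).
#' @return an object of class `"embedded_cohort"`: list `bags` of
#'   `"embedded_bag"`, integer `labels`, and the backend `fingerprint`.
#' @export
embed_cohort <- function(cohort, backend, Lmax = 24L) {
  bags <- if (inherits(cohort, "tcr_cohort")) cohort$bags else cohort
  cache <- new.env(parent = emptyenv())
  ebags <- lapply(bags, embed_bag, backend = backend, Lmax = Lmax, cache = cache)
  structure(list(bags = ebags,
                 labels = vapply(ebags, function(b) as.integer(b$label), integer(1)),
                 sample_ids = vapply(ebags, function(b) b$sample_id, character(1)),
                 fingerprint = backend_fingerprint(backend)),
            class = "embedded_cohort")
}

#' Save / load an embedded cohort cache
#'
#' Stores the embedded tensors together with the backend fingerprint so a
#' slow embedding pass can be reused across runs.
#'
#' @param x an `"embedded_cohort"`.
#' @param path file path for the cache.
#' @return `write_embedding_cache` returns the path invisibly;
#'   `read_embedding_cache` returns the `"embedded_cohort"`.
#' @export
write_embedding_cache <- function(x, path) {
  stopifnot(inherits(x, "embedded_cohort"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_embedding_cache
#' @export
read_embedding_cache <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "embedded_cohort")) stopf("not an embedding cache: %s", path)
  x
}
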