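## Internal vectorised compute engine. The atomic per-bag operations in
## cme.R define the model semantics; this engine reproduces them exactly
## (verified by the pipeline-vs-composition tests) at cohort scale, which is
## what makes CPU training of the network practical. Embeddings are fixed
## inputs, so all convolution windows are laid out flat once per cohort and
## every epoch reduces to a handful of dense matrix products plus
## per-instance max-pooling.

## Flatten an embedded cohort into contiguous residue rows plus index
## structures for each kernel size.
cme_compile <- function(ecohort, config) {
  bags <- if (inherits(ecohort, "embedded_cohort")) ecohort$bags else ecohort
  nb <- length(bags)
  if (nb == 0L) stopf("empty cohort")
  k <- config$bag_size
  D <- config$embed_dim
  labels <- vapply(bags, function(b) as.integer(b$label), integer(1))
  blocks <- vector("list", nb)
  inst_bag <- vector("list", nb)
  inst_slot <- vector("list", nb)
  inst_len <- vector("list", nb)
  for (b in seq_len(nb)) {
    eb <- bags[[b]]
    if (eb$d != D || dim(eb$tensor)[1] != k) {
      stopf("bag %d does not match config (k=%d, D=%d)", b, k, D)
    }
    real <- which(eb$mask)
    lens <- eb$lengths[real]
    keep <- lens > 0L
    real <- real[keep]; lens <- lens[keep]
    ii <- rep(real, lens)
    jj <- sequence(lens)
    ## row of the (k*Lmax) x D matrix view of the k x Lmax x D tensor
    rows <- ii + (jj - 1L) * k
    blocks[[b]] <- matrix(eb$tensor, k * eb$Lmax, D)[rows, , drop = FALSE]
    inst_bag[[b]] <- rep(b, length(real))
    inst_slot[[b]] <- real
    inst_len[[b]] <- lens
  }
  Eflat <- do.call(rbind, blocks)
  inst_bag <- unlist(inst_bag); inst_slot <- unlist(inst_slot)
  inst_len <- unlist(inst_len)
  n_inst <- length(inst_len)
  res_start <- cumsum(c(1L, inst_len))[seq_len(n_inst)]
  win <- lapply(seq_along(config$kernel_sizes), function(si) {
    s <- config$kernel_sizes[si]
    nw <- pmax(inst_len - s + 1L, 0L)
    nwin <- sum(nw)
    winstart <- rep(res_start, nw) + (sequence(nw) - 1L)
    win2inst <- rep(seq_len(n_inst), nw)
    maxpos <- max(nw, 1L)
    IDX <- matrix(NA_integer_, n_inst, maxpos)
    if (nwin > 0L) IDX[cbind(win2inst, sequence(nw))] <- seq_len(nwin)
    IDXa <- IDX
    IDXa[is.na(IDXa)] <- nwin + 1L
    list(s = s, nwin = nwin, winstart = winstart, maxpos = maxpos,
         IDX = IDX, IDXa = IDXa, haswin = nw > 0L)
  })
  real_counts <- tabulate(inst_bag, nbins = nb)
  structure(list(nb = nb, k = k, D = D, labels = labels,
                 n_inst = n_inst, inst_bag = inst_bag, inst_slot = inst_slot,
                 inst_len = inst_len, Eflat = Eflat, res_start = res_start,
                 win = win, yidx = cbind(inst_slot, inst_bag),
                 real_counts = real_counts),
            class = "cme_compiled")
}

## Forward pass over every bag of a compiled cohort.
cme_forward_all <- function(cmp, params, config, training = FALSE, drop_mask = NULL,
                            score_drop = NULL) {
  n_inst <- cmp$n_inst
  nfil <- config$n_filters
  binary <- config$task == "binary"
  pooled <- matrix(0, n_inst, nfil)
  am_res <- matrix(1L, n_inst, nfil)   # residue start row of the argmax window
  am_ok <- matrix(FALSE, n_inst, nfil)
  col0 <- 0L
  for (si in seq_along(config$kernel_sizes)) {
    s <- config$kernel_sizes[si]
    fs <- config$filters_per_size[si]
    S <- cmp$win[[si]]
    if (S$nwin == 0L) { col0 <- col0 + fs; next }
    W <- params$conv[[si]]$W
    Wmat <- do.call(cbind, lapply(seq_len(s), function(o) matrix(W[o, , ], cmp$D, fs)))
    P <- cmp$Eflat %*% Wmat
    conv <- matrix(params$conv[[si]]$b, S$nwin, fs, byrow = TRUE)
    for (o in seq_len(s)) {
      conv <- conv + P[S$winstart + (o - 1L), ((o - 1L) * fs + 1L):(o * fs), drop = FALSE]
    }
    H <- if (binary) sigmoid(conv) else pmax(conv, 0)
    seq_inst <- seq_len(n_inst)
    for (f in seq_len(fs)) {
      vals <- c(H[, f], -Inf)
      Hm <- matrix(vals[S$IDXa], n_inst, S$maxpos)
      am <- max.col(Hm, ties.method = "first")
      colj <- col0 + f
      hw <- S$haswin
      pooled[hw, colj] <- Hm[cbind(seq_inst, am)][hw]
      widx <- S$IDX[cbind(seq_inst, am)]
      am_res[hw, colj] <- S$winstart[widx[hw]]
      am_ok[hw, colj] <- TRUE
    }
    col0 <- col0 + fs
  }
  pooled_in <- pooled
  if (training && config$dropout_where %in% c("pooled", "both") && config$dropout_rate > 0) {
    if (is.null(drop_mask)) stopf("internal: dropout mask missing in training mode")
    pooled_in <- pooled * drop_mask / (1 - config$dropout_rate)
  }
  out <- list(pooled = pooled, pooled_in = pooled_in,
              am_res = am_res, am_ok = am_ok)
  if (binary) {
    l <- as.numeric(pooled_in %*% params$w_seq[, 1L] + params$b_seq[1L])
    yhat <- sigmoid(l)
    yhat_in <- yhat
    if (training && config$dropout_where %in% c("scores", "both") && config$dropout_rate > 0) {
      yhat_in <- yhat * score_drop / (1 - config$dropout_rate)
    }
    Ymat <- matrix(0, cmp$k, cmp$nb)
    Ymat[cmp$yidx] <- yhat_in
    out$yhat <- yhat
    out$Ymat <- Ymat
    if (config$aggregation == "mean") {
      out$Ybag <- colSums(Ymat) / cmp$real_counts
    } else {
      Z <- crossprod(params$w_bag[, , 1L], Ymat) + params$b_bag[, 1L]
      out$Z <- Z
      out$U <- colMeans(Z)
      out$Ybag <- sigmoid(out$U)
    }
  } else {
    C <- config$n_out
    seq_scores <- pooled_in %*% params$w_seq +
      matrix(params$b_seq, n_inst, C, byrow = TRUE)
    seq_scores_in <- seq_scores
    if (training && config$dropout_where %in% c("scores", "both") && config$dropout_rate > 0) {
      seq_scores_in <- seq_scores * score_drop / (1 - config$dropout_rate)
    }
    Ymats <- vector("list", C)
    scores <- matrix(0, cmp$nb, C)
    for (c in seq_len(C)) {
      Yc <- matrix(0, cmp$k, cmp$nb)
      Yc[cmp$yidx] <- seq_scores_in[, c]
      Ymats[[c]] <- Yc
      Zc <- crossprod(params$w_bag[, , c], Yc) + params$b_bag[, c]
      scores[, c] <- colMeans(Zc)
    }
    out$seq_scores <- seq_scores
    out$Ymats <- Ymats
    out$scores <- scores
    out$probs <- row_softmax(scores)
    out$class <- max.col(scores, ties.method = "first") - 1L
  }
  out
}

## Backward pass. `wb` is the per-bag loss weight (1/batch size for bags in
## the current batch, 0 otherwise), so the gradient equals the mean bag-loss
## gradient over the batch.
cme_backward_all <- function(cmp, params, config, fw, wb, drop_mask = NULL,
                             aux_weight = 0, score_drop = NULL) {
  binary <- config$task == "binary"
  g <- list(conv = lapply(params$conv, function(cc) {
    list(W = array(0, dim(cc$W)), b = numeric(length(cc$b)))
  }),
  w_seq = matrix(0, nrow(params$w_seq), ncol(params$w_seq)),
  b_seq = numeric(length(params$b_seq)),
  w_bag = array(0, dim(params$w_bag)),
  b_bag = matrix(0, nrow(params$b_bag), ncol(params$b_bag)))
  m <- config$n_heads
  if (binary) {
    y <- cmp$labels
    if (config$aggregation == "mean") {
      p <- pmin(pmax(fw$Ybag, 1e-7), 1 - 1e-7)
      dY <- wb * (p - y) / (p * (1 - p))
      dyhat <- dY[cmp$inst_bag] / cmp$real_counts[cmp$inst_bag]
    } else {
      dU <- (fw$Ybag - y) * wb
      dZ <- matrix(dU / m, m, cmp$nb, byrow = TRUE)
      g$w_bag[, , 1L] <- fw$Ymat %*% t(dZ)
      g$b_bag[, 1L] <- rowSums(dZ)
      dYmat <- params$w_bag[, , 1L] %*% dZ
      dyhat <- dYmat[cmp$yidx]
      if (!is.null(score_drop) && config$dropout_where %in% c("scores", "both") &&
          config$dropout_rate > 0) {
        dyhat <- dyhat * score_drop / (1 - config$dropout_rate)
      }
    }
    dl <- dyhat * fw$yhat * (1 - fw$yhat)
    if (aux_weight > 0) {
      ## per-sequence cross-entropy against the bag label (weak instance
      ## supervision); d/dlogit of BCE through the sigmoid is (yhat - y)
      dl <- dl + aux_weight * (fw$yhat - y[cmp$inst_bag]) *
        wb[cmp$inst_bag] / cmp$real_counts[cmp$inst_bag]
    }
    g$w_seq[, 1L] <- as.numeric(crossprod(fw$pooled_in, dl))
    g$b_seq[1L] <- sum(dl)
    dP <- tcrossprod(dl, params$w_seq[, 1L])
  } else {
    C <- config$n_out
    onehot <- matrix(0, cmp$nb, C)
    onehot[cbind(seq_len(cmp$nb), cmp$labels + 1L)] <- 1
    dS <- (fw$probs - onehot) * wb
    dseq <- matrix(0, cmp$n_inst, C)
    for (c in seq_len(C)) {
      dZc <- matrix(dS[, c] / m, m, cmp$nb, byrow = TRUE)
      g$w_bag[, , c] <- fw$Ymats[[c]] %*% t(dZc)
      g$b_bag[, c] <- rowSums(dZc)
      dYc <- params$w_bag[, , c] %*% dZc
      dseq[, c] <- dYc[cmp$yidx]
    }
    if (!is.null(score_drop) && config$dropout_where %in% c("scores", "both") &&
        config$dropout_rate > 0) {
      dseq <- dseq * score_drop / (1 - config$dropout_rate)
    }
    g$w_seq <- crossprod(fw$pooled_in, dseq)
    g$b_seq <- colSums(dseq)
    dP <- dseq %*% t(params$w_seq)
  }
  if (!is.null(drop_mask) && config$dropout_where %in% c("pooled", "both") &&
      config$dropout_rate > 0) {
    dP <- dP * drop_mask / (1 - config$dropout_rate)
  }
  col0 <- 0L
  for (si in seq_along(config$kernel_sizes)) {
    s <- config$kernel_sizes[si]
    fs <- config$filters_per_size[si]
    for (f in seq_len(fs)) {
      colj <- col0 + f
      h <- fw$pooled[, colj]
      da <- dP[, colj] * (if (binary) h * (1 - h) else as.numeric(h > 0))
      da[!fw$am_ok[, colj]] <- 0
      idx <- which(da != 0)
      if (length(idx) == 0L) next
      r <- fw$am_res[idx, colj]
      dai <- da[idx]
      for (o in seq_len(s)) {
        g$conv[[si]]$W[o, , f] <- as.numeric(
          crossprod(cmp$Eflat[r + (o - 1L), , drop = FALSE], dai))
      }
      g$conv[[si]]$b[f] <- sum(dai)
    }
    col0 <- col0 + fs
  }
  g
}

## Flatten parameters (or gradients of the same shape) to a numeric vector
## and back; ordering is fixed by the shape template.
params_flatten <- function(params) {
  unlist(list(conv = lapply(params$conv, function(cc) list(W = as.numeric(cc$W), b = cc$b)),
              w_seq = as.numeric(params$w_seq), b_seq = params$b_seq,
              w_bag = as.numeric(params$w_bag), b_bag = as.numeric(params$b_bag)),
         use.names = FALSE)
}

params_unflatten <- function(vec, template) {
  out <- template
  pos <- 0L
  take <- function(n) {
    v <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    v
  }
  for (si in seq_along(template$conv)) {
    dW <- dim(template$conv[[si]]$W)
    out$conv[[si]]$W <- array(take(prod(dW)), dW)
    out$conv[[si]]$b <- take(length(template$conv[[si]]$b))
  }
  out$w_seq <- matrix(take(length(template$w_seq)), nrow(template$w_seq))
  out$b_seq <- take(length(template$b_seq))
  out$w_bag <- array(take(length(template$w_bag)), dim(template$w_bag))
  out$b_bag <- matrix(take(length(template$b_bag)), nrow(template$b_bag))
  stopifnot(pos == length(vec))
  out
}

## Mean loss and per-bag scores on a compiled cohort (evaluation mode).
## `objective` is the quantity training minimises (bag loss plus the
## weighted auxiliary per-sequence loss), used for early stopping.
cme_eval <- function(cmp, params, config, aux_weight = 0) {
  fw <- cme_forward_all(cmp, params, config, training = FALSE)
  if (config$task == "binary") {
    loss <- mean(bag_loss(fw$Ybag, cmp$labels))
    objective <- loss
    if (aux_weight > 0) {
      inst_bce <- sequence_loss(fw$yhat, cmp$labels[cmp$inst_bag])
      per_bag <- rowsum(inst_bce, cmp$inst_bag) / cmp$real_counts
      objective <- loss + aux_weight * mean(per_bag)
    }
    auc <- if (length(unique(cmp$labels)) == 2L) auc_rank(cmp$labels, fw$Ybag) else NA_real_
    list(scores = fw$Ybag, loss = loss, objective = objective, auc = auc,
         accuracy = mean((fw$Ybag > config$decision_threshold) == (cmp$labels == 1L)))
  } else {
    ll <- vapply(seq_len(cmp$nb), function(b) {
      multiclass_loss(fw$scores[b, ], cmp$labels[b])
    }, numeric(1))
    list(scores = fw$scores, probs = fw$probs, class = fw$class,
         loss = mean(ll), objective = mean(ll), auc = NA_real_,
         accuracy = mean(fw$class == cmp$labels))
  }
}
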