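test_that("valid convolution yields span - s + 1 positions (worked example 9/8/7)", {
  be <- mini_encoder(d_model = 16, n_layers = 1, n_heads = 2, seed = 8)
  cfg <- cme_config(embed_dim = 16)
  par <- cme_params_init(cfg, seed = 1)
  E <- embed_sequence("CASSGTEQFF", be)   # length 10
  maps <- conv_feature_maps(E, cfg, par)
  lens <- vapply(maps, length, integer(1))
  expect_equal(lens, c(9L, 9L, 9L, 8L, 8L, 7L))
  ## padded input with true_len behaves identically
  Ep <- rbind(E, matrix(0, 14, 16))
  maps_p <- conv_feature_maps(Ep, cfg, par, true_len = 10)
  expect_equal(maps_p, maps)
  ## general law against a sliding-window count for random spans
  set.seed(5)
  for (L in c(10, 13, 17, 24)) {
    EL <- matrix(rnorm(L * 16), L, 16)
    lensL <- vapply(conv_feature_maps(EL, cfg, par), length, integer(1))
    expect_equal(lensL, rep(L - c(2L, 3L, 4L) + 1L, times = c(3L, 2L, 1L)))
  }
})

test_that("convolution values match a direct sliding-window oracle", {
  cfg <- cme_config(embed_dim = 5)
  par <- cme_params_init(cfg, seed = 3)
  set.seed(6)
  E <- matrix(rnorm(12 * 5), 12, 5)
  maps <- conv_feature_maps(E, cfg, par)
  ## oracle: explicit elementwise loop for the first filter of each size
  fidx <- c(1L, 4L, 6L)  # first filter at sizes 2, 3, 4
  for (si in 1:3) {
    s <- cfg$kernel_sizes[si]
    W <- par$conv[[si]]$W[, , 1]
    b <- par$conv[[si]]$b[1]
    oracle <- sapply(1:(12 - s + 1), function(p) {
      acc <- 0
      for (r in 0:(s - 1)) for (d in 1:5) acc <- acc + E[p + r, d] * W[r + 1, d]
      1 / (1 + exp(-(acc + b)))
    })
    expect_equal(maps[[fidx[si]]], oracle, tolerance = 1e-12)
  }
  ## all-zero input with zero bias gives sigmoid(0) = 0.5 everywhere
  par0 <- par
  for (si in 1:3) par0$conv[[si]]$b[] <- 0
  maps0 <- conv_feature_maps(matrix(0, 10, 5), cfg, par0)
  expect_true(all(unlist(maps0) == 0.5))
})

test_that("sigmoid satisfies its defining identities", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1) + sigmoid(-1), 1, tolerance = 1e-14)
  x <- seq(-30, 30, by = 0.5)
  expect_true(all(diff(sigmoid(x)) > 0))          # strictly increasing
  expect_true(all(sigmoid(x) > 0 & sigmoid(x) < 1))
  expect_equal(sigmoid(700), 1)                   # saturates without NaN
  expect_equal(sigmoid(-700), 0)
})

test_that("1-max pooling returns the maximum and concatenates to 6 features", {
  expect_equal(one_max_pool(c(0.1, 0.9, 0.4)), 0.9)
  expect_equal(one_max_pool(rep(0.3, 7)), 0.3)
  expect_error(one_max_pool(numeric(0)), "empty")
  set.seed(7)
  for (i in 1:100) {
    v <- runif(sample(1:30, 1))
    mx <- v[1]
    for (u in v) if (u > mx) mx <- u  # linear-scan oracle
    expect_identical(one_max_pool(v), mx)
  }
  cfg <- cme_config(embed_dim = 4)
  par <- cme_params_init(cfg, seed = 2)
  pooled <- tcrmil:::pooled_features(conv_feature_maps(matrix(rnorm(40), 10, 4), cfg, par))
  expect_length(pooled, 6L)
})

test_that("sequence scores apply the linear-sigmoid head exactly", {
  cfg <- cme_config(embed_dim = 4)
  par <- cme_params_init(cfg, seed = 4)
  par$w_seq[] <- 0; par$b_seq[] <- 0
  expect_equal(sequence_score(runif(6), par), 0.5)
  set.seed(8)
  for (i in 1:100) {
    par2 <- cme_params_init(cfg, seed = i)
    p <- rnorm(6)
    oracle <- 1 / (1 + exp(-(sum(par2$w_seq[, 1] * p) + par2$b_seq[1])))
    expect_equal(sequence_score(p, par2), oracle, tolerance = 1e-12)
  }
})

test_that("cross-entropy losses match the elementwise formula and clamp at 0/1", {
  expect_equal(sequence_loss(0.5, 1), log(2))
  expect_equal(bag_loss(0.5, 0), log(2))
  expect_lt(sequence_loss(1 - 1e-9, 1), 1e-6)
  expect_lt(bag_loss(1e-9, 0), 1e-6)
  expect_true(is.finite(sequence_loss(0, 1)) && is.finite(sequence_loss(1, 0)))
  set.seed(9)
  for (i in 1:100) {
    p <- runif(1, 0.01, 0.99); y <- rbinom(1, 1, 0.5)
    expect_equal(sequence_loss(p, y), -(y * log(p) + (1 - y) * log(1 - p)),
                 tolerance = 1e-12)
    expect_gte(sequence_loss(p, y), 0)
  }
})

test_that("bag scores average the ensemble heads inside a sigmoid", {
  cfg <- cme_config(embed_dim = 4, bag_size = 10, n_heads = 5)
  par <- cme_params_init(cfg, seed = 5)
  mask <- rep(TRUE, 10)
  y <- runif(10)
  ## zero heads -> sigmoid(0)
  par0 <- par; par0$w_bag[] <- 0; par0$b_bag[] <- 0
  expect_equal(bag_score(y, mask, par0, cfg), 0.5)
  ## m identical heads equal the single-head score
  par1 <- par
  for (j in 2:5) { par1$w_bag[, j, 1] <- par1$w_bag[, 1, 1]; par1$b_bag[j, 1] <- par1$b_bag[1, 1] }
  cfg1 <- cme_config(embed_dim = 4, bag_size = 10, aggregation = "single")
  ps <- cme_params_init(cfg1, seed = 1)
  ps$w_bag[, 1, 1] <- par1$w_bag[, 1, 1]; ps$b_bag[1, 1] <- par1$b_bag[1, 1]
  expect_equal(bag_score(y, mask, par1, cfg), bag_score(y, mask, ps, cfg1),
               tolerance = 1e-12)
  ## explicit loop-and-average oracle on random heads
  set.seed(10)
  for (i in 1:100) {
    pr <- cme_params_init(cfg, seed = 1000 + i)
    yv <- runif(10)
    z <- numeric(5)
    for (j in 1:5) z[j] <- sum(pr$w_bag[, j, 1] * yv) + pr$b_bag[j, 1]
    expect_equal(bag_score(yv, mask, pr, cfg), 1 / (1 + exp(-mean(z))),
                 tolerance = 1e-12)
  }
})

test_that("the mean-aggregation arm equals the hand-computed mean of real scores", {
  cfg <- cme_config(embed_dim = 4, bag_size = 6, aggregation = "mean")
  par <- cme_params_init(cfg, seed = 6)
  y <- c(0.9, 0.2, 0.4, 0.7, 0, 0)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(bag_score(y, mask, par, cfg), mean(y[1:4]))
})

test_that("monotonicity: raising a sequence score never lowers a non-negative-head bag score", {
  cfg <- cme_config(embed_dim = 4, bag_size = 8)
  par <- cme_params_init(cfg, seed = 7)
  par$w_bag[] <- abs(par$w_bag)
  mask <- rep(TRUE, 8)
  set.seed(11)
  for (i in 1:50) {
    y <- runif(8)
    j <- sample(8, 1)
    y2 <- y; y2[j] <- min(1, y[j] + runif(1, 0, 0.3))
    expect_gte(bag_score(y2, mask, par, cfg), bag_score(y, mask, par, cfg))
  }
})

test_that("forward_binary compose the atomic operations and respects masking", {
  set.seed(12)
  cfg <- cme_config(embed_dim = 6, bag_size = 4)
  par <- cme_params_init(cfg, seed = 8)
  ms <- lapply(c(10, 12), function(l) matrix(rnorm(l * 6), l, 6))
  eb <- pad_and_stack(ms, k = 4, Lmax = 24)
  fw <- forward_binary(eb, par, cfg)
  ## composition identity
  oracle <- vapply(1:2, function(i) {
    fm <- conv_feature_maps(ms[[i]], cfg, par)
    sequence_score(tcrmil:::pooled_features(fm), par)
  }, numeric(1))
  expect_equal(fw$sequence_scores[1:2], oracle, tolerance = 1e-12)
  expect_equal(fw$bag_score,
               bag_score(c(oracle, 0, 0), eb$mask, par, cfg), tolerance = 1e-12)
  expect_true(fw$bag_score > 0 && fw$bag_score < 1)
  ## identical instances give identical scores
  eb2 <- pad_and_stack(list(ms[[1]], ms[[1]], ms[[1]]), k = 3, Lmax = 24)
  cfg3 <- cme_config(embed_dim = 6, bag_size = 3)
  fw2 <- forward_binary(eb2, cme_params_init(cfg3, seed = 9), cfg3)
  expect_equal(length(unique(round(fw2$sequence_scores, 12))), 1L)
  ## altering a masked slot's embedding never changes the bag score
  ebm <- eb
  ebm$tensor[4, , ] <- rnorm(24 * 6)   # slot 4 is masked
  fwm <- forward_binary(ebm, par, cfg)
  expect_equal(fwm$bag_score, fw$bag_score)
})

test_that("widening the embedding with zero-weight channels leaves scores unchanged", {
  set.seed(13)
  cfg <- cme_config(embed_dim = 6, bag_size = 2)
  par <- cme_params_init(cfg, seed = 10)
  cfg2 <- cme_config(embed_dim = 12, bag_size = 2)
  par2 <- cme_params_init(cfg2, seed = 11)
  for (si in 1:3) {
    par2$conv[[si]]$W[, 1:6, ] <- par$conv[[si]]$W
    par2$conv[[si]]$W[, 7:12, ] <- 0
    par2$conv[[si]]$b <- par$conv[[si]]$b
  }
  par2$w_seq <- par$w_seq; par2$b_seq <- par$b_seq
  par2$w_bag <- par$w_bag; par2$b_bag <- par$b_bag
  m <- matrix(rnorm(10 * 6), 10, 6)
  eb <- pad_and_stack(list(m), k = 2, Lmax = 24)
  eb2 <- pad_and_stack(list(cbind(m, matrix(rnorm(10 * 6), 10, 6))), k = 2, Lmax = 24)
  expect_equal(forward_binary(eb2, par2, cfg2)$bag_score,
               forward_binary(eb, par, cfg)$bag_score, tolerance = 1e-12)
})

test_that("multiclass forward uses ReLU, raw scores and lowest-index tie-breaks", {
  set.seed(14)
  cfg <- cme_config(embed_dim = 5, bag_size = 3, task = "multiclass", n_classes = 3)
  par <- cme_params_init(cfg, seed = 12)
  eb <- pad_and_stack(lapply(c(10, 11), function(l) matrix(rnorm(l * 5), l, 5)),
                      k = 3, Lmax = 24)
  fw <- forward_multiclass(eb, par, cfg)
  expect_length(fw$scores, 3L)
  ## argmax agrees with exhaustive comparison
  expect_equal(fw$class, which(fw$scores == max(fw$scores))[1] - 1L)
  ## identical per-class heads tie; tie goes to class 0
  part <- par
  for (c in 2:3) {
    part$w_seq[, c] <- part$w_seq[, 1]; part$b_seq[c] <- part$b_seq[1]
    part$w_bag[, , c] <- part$w_bag[, , 1]; part$b_bag[, c] <- part$b_bag[, 1]
  }
  expect_equal(forward_multiclass(eb, part, cfg)$class, 0L)
  ## a dominant head wins
  pard <- par
  pard$b_bag[, 3] <- pard$b_bag[, 3] + 100
  expect_equal(forward_multiclass(eb, pard, cfg)$class, 2L)
  ## mismatched class count errors
  expect_error(forward_multiclass(eb, par, cfg, n_classes = 4), "mismatch")
  ## multiclass loss decreases in the true-class score
  l0 <- multiclass_loss(c(0, 0, 0), 1L)
  expect_equal(l0, log(3), tolerance = 1e-12)
  expect_lt(multiclass_loss(c(0, 2, 0), 1L), l0)
})

test_that("probabilities stay strictly inside (0,1) under finite parameters", {
  set.seed(15)
  cfg <- cme_config(embed_dim = 4, bag_size = 3)
  for (i in 1:10) {
    par <- cme_params_init(cfg, seed = i)
    ## inflate weights to probe saturation
    par$w_seq <- par$w_seq * 5
    eb <- pad_and_stack(lapply(1:2, function(j) matrix(rnorm(40, sd = 3), 10, 4)),
                        k = 3, Lmax = 24)
    fw <- forward_binary(eb, par, cfg)
    expect_true(all(fw$sequence_scores[1:2] > 0 & fw$sequence_scores[1:2] < 1))
    expect_true(fw$bag_score > 0 && fw$bag_score < 1)
  }
})
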